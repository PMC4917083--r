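#' Define a binary design factor
#'
#' All design factors in the factorial cohorts are dichotomous; the second
#' level is the "active" one used when coding additive effect shifts.
#'
#' @param name factor name (unique within a design).
#' @param levels character vector of exactly two level labels.
#' @return a `factor_spec` list with elements `name` and `levels`.
#' @export
#' @examples
#' factor_spec("piano", c("non-player", "player"))
factor_spec <- function(name, levels) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_arg("factor name must be a single non-empty string")
  if (length(levels) != 2L || anyDuplicated(levels))
    stop_arg("factor '%s' must have exactly two distinct levels", name)
  structure(list(name = name, levels = as.character(levels)),
            class = "factor_spec")
}

#' The four canonical cohort factors
#'
#' Piano experience, dichotomized age group (below 30 vs 30 and above),
#' intelligence group and gender -- the 2x2x2x2 design of the main cohort.
#'
#' @return list of four [factor_spec()] objects.
#' @export
canonical_factors <- function() {
  list(
    factor_spec("piano",        c("non-player", "player")),
    factor_spec("age_group",    c("younger", "older")),
    factor_spec("intelligence", c("control", "high")),
    factor_spec("gender",       c("female", "male"))
  )
}

check_factors <- function(factors) {
  if (!length(factors)) stop_arg("at least one design factor is required")
  for (f in factors) {
    if (!inherits(f, "factor_spec")) {
      if (is.list(f) && length(f$levels %||% NULL) == 2L) next
      stop_arg("design factors must be factor_spec objects with 2 levels")
    }
  }
  nm <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop_arg("factor names must be unique")
  invisible(factors)
}

factor_names <- function(factors) vapply(factors, `[[`, "", "name")

#' Design-cell label of a subject
#'
#' Concatenates the subject's factor levels (in factor order) with `"|"`,
#' giving the unique label of the subject's cell in the factorial design.
#'
#' @param subjects a subject-factor data frame (one row per subject).
#' @param factors list of [factor_spec()] objects.
#' @return character vector of cell labels.
#' @export
cell_id <- function(subjects, factors) {
  nm <- factor_names(factors)
  missing <- setdiff(nm, names(subjects))
  if (length(missing))
    stop_arg("subject table lacks factor column(s): %s",
             paste(missing, collapse = ", "))
  do.call(paste, c(unname(subjects[nm]), sep = "|"))
}

#' Enumerate all design cells
#'
#' @param factors list of [factor_spec()] objects.
#' @return data frame with one row per cell, one column per factor, plus a
#'   `cell` label column.
#' @export
design_cells <- function(factors) {
  check_factors(factors)
  lv <- lapply(factors, `[[`, "levels")
  names(lv) <- factor_names(factors)
  cells <- rev(expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE))
  cells$cell <- do.call(paste, c(unname(cells[factor_names(factors)]),
                                 sep = "|"))
  cells
}
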