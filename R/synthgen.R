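#' Generate a balanced factorial cohort of subjects
#'
#' Builds `n_per_cell * 2^k` subjects over `k` binary factors, with exactly
#' `n_per_cell` subjects in every design cell. Continuous covariates are drawn
#' per subject from a deterministic substream of the master seed, so enlarging
#' the design never changes the covariates of existing subjects.
#'
#' Age in years is drawn uniformly within the cell's age band when an
#' `age_group` factor is present (younger: 18 to just below 30; older: 30-70,
#' age 30 belongs to "older"), otherwise uniformly on 18-70. Lifetime piano
#' hours are drawn uniformly on 500-5000 for players and 0-50 for non-players
#' when a `piano` factor is present, otherwise set to 0.
#'
#' @param n_per_cell subjects per design cell (>= 1).
#' @param factors list of [factor_spec()] objects (each with two levels).
#' @param seed master integer seed.
#' @param delay retest delay label for all subjects, `"24h"` or `"30min"`.
#' @return data frame with columns `subject_id`, one column per factor,
#'   `age_years`, `piano_hours`, `delay`.
#' @export
#' @examples
#' d <- generate_design(2, canonical_factors(), seed = 1)
#' table(d$piano, d$age_group)
generate_design <- function(n_per_cell, factors = canonical_factors(),
                            seed = 1L, delay = "24h") {
  if (!is.numeric(n_per_cell) || length(n_per_cell) != 1L ||
      n_per_cell < 1 || n_per_cell != round(n_per_cell))
    stop_arg("n_per_cell must be a positive integer")
  check_factors(factors)
  if (!delay %in% c("24h", "30min"))
    stop_arg("delay must be '24h' or '30min'")

  cells <- design_cells(factors)
  nm <- factor_names(factors)
  idx <- rep(seq_len(nrow(cells)), each = n_per_cell)
  subjects <- cells[idx, nm, drop = FALSE]
  n <- nrow(subjects)
  rownames(subjects) <- NULL
  subjects <- cbind(
    subject_id = sprintf("S%03d", seq_len(n)),
    subjects,
    stringsAsFactors = FALSE
  )
  subjects$age_years <- NA_real_
  subjects$piano_hours <- NA_real_
  for (i in seq_len(n)) {
    cov <- with_seed(substream_seed(seed, i), {
      ag <- if ("age_group" %in% nm) subjects$age_group[i] else NA
      age <- if (identical(ag, "younger")) stats::runif(1, 18, 30) else
             if (identical(ag, "older"))   stats::runif(1, 30, 70) else
                                           stats::runif(1, 18, 70)
      pf <- if ("piano" %in% nm) subjects$piano[i] else NA
      hrs <- if (identical(pf, "player")) stats::runif(1, 500, 5000) else
             if (identical(pf, "non-player")) stats::runif(1, 0, 50) else 0
      c(age, hrs)
    })
    subjects$age_years[i] <- round(cov[1], 1)
    subjects$piano_hours[i] <- round(cov[2])
  }
  # band edges: round-to-decimal must not push a younger subject to 30
  if ("age_group" %in% nm)
    subjects$age_years <- ifelse(
      subjects$age_group == "younger" & subjects$age_years >= 30,
      29.9, subjects$age_years)
  subjects$delay <- delay
  subjects
}

# ---------------------------------------------------------------------------
# consolidation-gain specification

#' Specify mean overnight consolidation gains over the design cells
#'
#' The mean gain of a cell is `baseline_gain` plus additive shifts. Each
#' element of `effects` is named either by a single factor (`"age_group"`) or
#' by a two-way pair (`"piano:age_group"`); its value is added to the cell
#' mean when the subject sits at the *active* (second) level of every factor
#' named. This indicator coding can represent any pattern over the cells of
#' up to two-way structure, e.g. lowering only one cell.
#'
#' @param baseline_gain mean gain (sequences/trial) of the all-reference cell.
#' @param effects named numeric list/vector of additive shifts (may be empty).
#' @param gain_noise_sd subject-level SD of the gain around its cell mean
#'   (>= 0, sequences/trial); one draw per subject, shared by the retest
#'   trials.
#' @return a `consolidation_spec` list.
#' @export
#' @examples
#' # older non-players 2 sequences lower, everyone else at baseline:
#' consolidation_spec(3, list(age_group = -2, "piano:age_group" = 2), 2)
consolidation_spec <- function(baseline_gain = 0, effects = list(),
                               gain_noise_sd = 0) {
  effects <- as.list(effects)
  if (length(effects) && (is.null(names(effects)) || any(!nzchar(names(effects)))))
    stop_arg("every gain effect must be named by a factor or factor pair")
  for (nm in names(effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!length(parts) %in% 1:2)
      stop_arg("gain effect '%s' must name one factor or a two-way pair", nm)
  }
  if (gain_noise_sd < 0) stop_arg("gain_noise_sd must be >= 0")
  structure(list(baseline_gain = baseline_gain,
                 effects = lapply(effects, as.numeric),
                 gain_noise_sd = gain_noise_sd),
            class = "consolidation_spec")
}

#' Mean consolidation gain for given subjects
#'
#' Reconstructs each subject's cell mean gain from the additive terms of a
#' [consolidation_spec()].
#'
#' @param spec a `consolidation_spec`.
#' @param subjects subject-factor data frame.
#' @param factors list of [factor_spec()] objects describing the design.
#' @return numeric vector of mean gains, one per row of `subjects`.
#' @export
gain_lookup <- function(spec, subjects, factors) {
  stopifnot(inherits(spec, "consolidation_spec"))
  nm <- factor_names(factors)
  active <- lapply(factors, function(f) f$levels[2])
  names(active) <- nm
  g <- rep(spec$baseline_gain, nrow(subjects))
  for (eff in names(spec$effects)) {
    parts <- strsplit(eff, ":", fixed = TRUE)[[1]]
    unknown <- setdiff(parts, nm)
    if (length(unknown))
      stop_arg("gain effect '%s' refers to unknown factor(s): %s",
               eff, paste(unknown, collapse = ", "))
    on <- Reduce(`&`, lapply(parts, function(p)
      subjects[[p]] == active[[p]]))
    g <- g + ifelse(on, spec$effects[[eff]], 0)
  }
  g
}

#' Mean-gain table over all design cells
#'
#' @inheritParams gain_lookup
#' @return [design_cells()] table with a `mean_gain` column.
#' @export
gain_table <- function(spec, factors) {
  cells <- design_cells(factors)
  cells$mean_gain <- gain_lookup(spec, cells, factors)
  cells
}

# ---------------------------------------------------------------------------
# subject-level learning-curve parameters

#' Group-level hyperparameter table constructor
#'
#' @param cells data frame of design cells (with a `cell` column).
#' @param mu_I,mu_C,mu_R group means of the curve parameters (recycled).
#' @param sigma_I,sigma_C,sigma_R group SDs (recycled, >= 0).
#' @param sigma_obs within-trial observation noise SD per group (>= 0).
#' @return data frame, one row per group, class `group_hypers`.
#' @export
group_hypers <- function(cells, mu_I, mu_C, mu_R,
                         sigma_I, sigma_C, sigma_R, sigma_obs) {
  out <- data.frame(group = cells$cell,
                    mu_I = mu_I, mu_C = mu_C, mu_R = mu_R,
                    sigma_I = sigma_I, sigma_C = sigma_C, sigma_R = sigma_R,
                    sigma_obs = sigma_obs,
                    stringsAsFactors = FALSE)
  if (any(out$sigma_I < 0 | out$sigma_C < 0 | out$sigma_R < 0 |
          out$sigma_obs < 0))
    stop_arg("hyperparameter standard deviations must be >= 0")
  if (any(out$mu_R <= 0 | out$mu_R >= 1))
    stop_arg("mu_R must lie strictly in (0, 1)")
  class(out) <- c("group_hypers", "data.frame")
  out
}

rtrunc_norm1 <- function(mu, sd, lo, hi, what) {
  if (sd == 0) {
    if (mu < lo || mu > hi)
      stop_arg("degenerate %s distribution has mean %g outside [%g, %g]",
               what, mu, lo, hi)
    return(mu)
  }
  for (i in 1:100000) {
    x <- stats::rnorm(1, mu, sd)
    if (x > lo && x < hi) return(x)
  }
  stop_arg("truncated-normal rejection sampling failed for %s", what)
}

#' Draw one subject's learning-curve parameters from its group
#'
#' Samples (I, C, R) from the group's normal distributions, truncating R to
#' (0, 1) and I and C to be non-negative by rejection. With all SDs zero the
#' group means are returned exactly.
#'
#' @param hypers a [group_hypers()] table.
#' @param group group (cell) label; must match a row of `hypers`.
#' @param seed integer seed.
#' @return list with elements `I`, `C`, `R`.
#' @export
draw_subject_params <- function(hypers, group, seed) {
  row <- match(group, hypers$group)
  if (is.na(row)) stop_arg("no hyperparameters defined for group '%s'", group)
  h <- hypers[row, ]
  with_seed(seed, list(
    I = rtrunc_norm1(h$mu_I, h$sigma_I, 0, Inf, "I"),
    C = rtrunc_norm1(h$mu_C, h$sigma_C, 0, Inf, "C"),
    R = rtrunc_norm1(h$mu_R, h$sigma_R, 0, 1, "R")
  ))
}

# ---------------------------------------------------------------------------
# trial simulation

#' Simulate a subject's day-1 training trials
#'
#' Trial `t` equals the power-law curve value plus additive Gaussian noise,
#' clipped at zero (performance counts are treated as continuous).
#'
#' @param params list with `I`, `C`, `R` (see [draw_subject_params()]).
#' @param n_train number of training trials (>= 3 for identifiability).
#' @param noise_sd observation noise SD (>= 0).
#' @param seed integer seed.
#' @return numeric vector of length `n_train` (trials 1..n_train).
#' @export
simulate_day1 <- function(params, n_train, noise_sd, seed) {
  if (n_train < 3) stop_arg("n_train must be >= 3 (three curve parameters)")
  if (noise_sd < 0) stop_arg("noise_sd must be >= 0")
  mu <- learning_curve(params$I, params$C, params$R, seq_len(n_train))
  with_seed(seed, pmax(0, mu + stats::rnorm(n_train, 0, noise_sd)))
}

#' Simulate a subject's delayed retest trials
#'
#' Each of the three retest trials is the day-1 plateau `I + C` plus the
#' subject's cell mean gain, a subject-level gain perturbation (one draw of
#' SD `gain_noise_sd`, shared by the three trials), and per-trial observation
#' noise; clipped at zero.
#'
#' @param params list with `I`, `C`, `R`.
#' @param gain a [consolidation_spec()].
#' @param subject one-row subject-factor data frame.
#' @param factors design factors (for the gain lookup).
#' @param noise_sd per-trial observation noise SD (>= 0).
#' @param seed integer seed.
#' @param n_test number of retest trials (default 3).
#' @return numeric vector of length `n_test`.
#' @export
simulate_day2 <- function(params, gain, subject, factors, noise_sd, seed,
                          n_test = 3L) {
  cell_gain <- gain_lookup(gain, subject, factors)
  with_seed(seed, {
    subj_shift <- stats::rnorm(1, 0, gain$gain_noise_sd)
    pmax(0, params$I + params$C + cell_gain + subj_shift +
              stats::rnorm(n_test, 0, noise_sd))
  })
}

# ---------------------------------------------------------------------------
# scenario cohorts

default_scenario_config <- function(name) {
  base <- list(
    n_per_cell = 8L, n_train = 12L, n_test = 3L,
    noise_sd = 1.0, delay = "24h",
    # additive construction of the per-cell curve hyper-means
    curve = list(I_base = 8, I_piano = 6, I_intelligence = 3,
                 C_base = 8,
                 R_base = 0.55, R_piano = -0.20,
                 sigma_I = 2, sigma_C = 2, sigma_R = 0.08),
    gain = consolidation_spec(
      baseline_gain = 3,
      effects = list(age_group = -2, "piano:age_group" = 2),
      gain_noise_sd = 2)
  )
  cfg <- switch(name,
    main = base,
    null = {
      base$curve[c("I_piano", "I_intelligence", "R_piano")] <- 0
      base$gain <- consolidation_spec(baseline_gain = 3, effects = list(),
                                      gain_noise_sd = 2)
      base
    },
    control1 = {
      base$delay <- "30min"
      base$gain <- consolidation_spec(baseline_gain = 3,
                                      effects = list(age_group = -2),
                                      gain_noise_sd = 2)
      base
    },
    control2 = {
      base$n_train <- 6L
      base$curve$I_intelligence <- 0
      base$gain <- consolidation_spec(baseline_gain = 3, effects = list(),
                                      gain_noise_sd = 2)
      base
    },
    stop_arg("unknown scenario '%s'", name)
  )
  cfg
}

scenario_hypers <- function(cfg, factors) {
  cells <- design_cells(factors)
  cv <- cfg$curve
  nm <- factor_names(factors)
  ind <- function(fac, lev) if (fac %in% nm) as.numeric(cells[[fac]] == lev) else 0
  mu_I <- cv$I_base + cv$I_piano * ind("piano", "player") +
    cv$I_intelligence * ind("intelligence", "high")
  mu_R <- cv$R_base + cv$R_piano * ind("piano", "player")
  group_hypers(cells, mu_I = mu_I, mu_C = cv$C_base, mu_R = mu_R,
               sigma_I = cv$sigma_I, sigma_C = cv$sigma_C,
               sigma_R = cv$sigma_R, sigma_obs = cfg$noise_sd)
}

# unbalanced recruited groups of the 30-minute control experiment
control1_subjects <- function(seed) {
  grp <- data.frame(
    piano = rep(c("player", "non-player", "player", "non-player"),
                c(20, 20, 14, 13)),
    age_group = rep(c("younger", "younger", "older", "older"),
                    c(20, 20, 14, 13)),
    stringsAsFactors = FALSE)
  n_f <- c(10, 10, 5, 5) # females per recruited group
  gender <- unlist(mapply(function(n, f)
    c(rep("female", f), rep("male", n - f)),
    c(20, 20, 14, 13), n_f, SIMPLIFY = FALSE))
  grp$gender <- gender
  # intelligence by alternation emulates a median split (about half "high")
  grp$intelligence <- rep_len(c("high", "control"), nrow(grp))
  grp <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(grp))), grp,
               stringsAsFactors = FALSE)
  grp$age_years <- NA_real_
  grp$piano_hours <- NA_real_
  for (i in seq_len(nrow(grp))) {
    cov <- with_seed(substream_seed(seed, i), {
      age <- if (grp$age_group[i] == "younger") stats::runif(1, 18, 28) else
        stats::runif(1, 55, 70)
      hrs <- if (grp$piano[i] == "player") stats::runif(1, 500, 5000) else
        stats::runif(1, 0, 50)
      c(age, hrs)
    })
    grp$age_years[i] <- round(cov[1], 1)
    grp$piano_hours[i] <- round(cov[2])
  }
  grp$delay <- "30min"
  grp
}

# young-only short-training control: piano x retest-delay recruitment
control2_subjects <- function(seed) {
  counts <- data.frame(
    piano = c("player", "non-player", "player", "non-player"),
    delay = c("30min", "30min", "24h", "24h"),
    n = c(12, 18, 17, 20), stringsAsFactors = FALSE)
  grp <- counts[rep(seq_len(4), counts$n), c("piano", "delay")]
  rownames(grp) <- NULL
  grp$age_group <- "younger"
  grp$gender <- unlist(lapply(counts$n, function(n)
    rep_len(c("female", "male"), n)))
  # period-4 pattern keeps the median-split intelligence factor balanced
  # against the alternating gender assignment within each recruited group
  grp$intelligence <- unlist(lapply(counts$n, function(n)
    rep_len(c("high", "high", "control", "control"), n)))
  grp <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(grp))), grp,
               stringsAsFactors = FALSE)
  grp$age_years <- NA_real_
  grp$piano_hours <- NA_real_
  for (i in seq_len(nrow(grp))) {
    cov <- with_seed(substream_seed(seed, i), {
      c(stats::runif(1, 18, 32),
        if (grp$piano[i] == "player") stats::runif(1, 500, 5000) else
          stats::runif(1, 0, 50))
    })
    grp$age_years[i] <- round(cov[1], 1)
    grp$piano_hours[i] <- round(cov[2])
  }
  grp[, c("subject_id", "piano", "age_group", "gender", "intelligence",
          "age_years", "piano_hours", "delay")]
}

#' Simulate a complete study cohort under a named scenario
#'
#' Scenarios:
#' \describe{
#'   \item{main}{128 subjects (8 per cell of the 2^4 design), 12 training +
#'     3 retest trials, 24 h delay; mean gain lowered by 2 sequences/trial for
#'     older non-players only (piano experience compensates the age effect).}
#'   \item{control1}{four recruited groups of 20/20/14/13 subjects
#'     (young/old x piano/non-piano), 30 min delay; age lowers the gain, piano
#'     has no effect.}
#'   \item{control2}{67 young subjects, 6 training trials, both delays; no
#'     factor affects the gain.}
#'   \item{null}{as main but with every factor effect (gain and curve) zero.}
#' }
#'
#' @param name scenario name: `"main"`, `"control1"`, `"control2"`, `"null"`.
#' @param overrides named list merged over the scenario defaults (e.g.
#'   `list(noise_sd = 0)` or `list(gain = consolidation_spec(...))`).
#' @param seed master integer seed; all subject-level draws use deterministic
#'   substreams of it.
#' @return list with `factors` (subject table), `trials` (long trial table),
#'   `truth` (ground-truth record: config echo, hyperparameter table, per-cell
#'   mean gains, per-subject true parameters and gains, seed).
#' @export
#' @examples
#' cohort <- scenario_cohort("main", seed = 7)
#' nrow(cohort$factors) # 128
scenario_cohort <- function(name, overrides = list(), seed = 1L) {
  cfg <- default_scenario_config(name)
  if (length(overrides)) {
    # classed specs replace wholesale; plain sublists (e.g. curve) merge
    gain <- overrides$gain
    overrides$gain <- NULL
    cfg <- utils::modifyList(cfg, overrides)
    if (!is.null(gain)) {
      stopifnot(inherits(gain, "consolidation_spec"))
      cfg$gain <- gain
    }
  }
  fspecs <- canonical_factors()

  subjects <- switch(name,
    main = ,
    null = generate_design(cfg$n_per_cell, fspecs, seed = seed,
                           delay = cfg$delay),
    control1 = control1_subjects(seed),
    control2 = control2_subjects(seed))

  hypers <- scenario_hypers(cfg, fspecs)
  cells <- cell_id(subjects, fspecs)
  n <- nrow(subjects)

  params <- data.frame(subject_id = subjects$subject_id, cell = cells,
                       I = NA_real_, C = NA_real_, R = NA_real_,
                       mean_gain = gain_lookup(cfg$gain, subjects, fspecs),
                       true_gain = NA_real_, stringsAsFactors = FALSE)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    s_par <- substream_seed(seed, 4L * i)
    s_d1 <- substream_seed(seed, 4L * i + 1L)
    s_d2 <- substream_seed(seed, 4L * i + 2L)
    p <- draw_subject_params(hypers, cells[i], s_par)
    params$I[i] <- p$I; params$C[i] <- p$C; params$R[i] <- p$R
    d1 <- simulate_day1(p, cfg$n_train, cfg$noise_sd, s_d1)
    d2 <- simulate_day2(p, cfg$gain, subjects[i, , drop = FALSE], fspecs,
                        cfg$noise_sd, s_d2, n_test = cfg$n_test)
    # realized subject-level gain (cell mean + subject perturbation)
    params$true_gain[i] <- params$mean_gain[i] +
      with_seed(s_d2, stats::rnorm(1, 0, cfg$gain$gain_noise_sd))
    trials[[i]] <- data.frame(
      subject_id = subjects$subject_id[i],
      session = rep(c("day1", "day2"), c(cfg$n_train, cfg$n_test)),
      trial = c(seq_len(cfg$n_train), seq_len(cfg$n_test)),
      correct_sequences = c(d1, d2), stringsAsFactors = FALSE)
  }

  list(
    factors = subjects,
    trials = do.call(rbind, trials),
    truth = list(
      scenario = name,
      seed = seed,
      config = cfg,
      hypers = hypers,
      gain_table = gain_table(cfg$gain, fspecs),
      gain_effects = c(baseline_gain = cfg$gain$baseline_gain,
                       unlist(cfg$gain$effects)),
      subject_params = params
    )
  )
}
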