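#' Configuration of a full analysis run
#'
#' Either `scenario` (simulate a cohort) or both `trials_path` and
#' `factors_path` (read data from disk) must be given.
#'
#' @param scenario scenario name for [scenario_cohort()], or `NULL`.
#' @param trials_path,factors_path CSV inputs when not simulating.
#' @param overrides scenario overrides (see [scenario_cohort()]).
#' @param selection_mode `"last3"` or `"best3"` day-1 endpoint for the
#'   primary analysis.
#' @param interaction_order interaction order of the factorial models.
#' @param mcmc an [mcmc_config()].
#' @param group_by factor columns defining the hyperparameter groups of the
#'   curve fit (default: all 16 design cells).
#' @param seed master seed of the run (simulation and fit substreams derive
#'   from it).
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @param skip_fit skip the MCMC curve fit (consolidation analyses only).
#' @param best3_control,group_ttests,correlation_panel report toggles.
#' @return validated list, class `analysis_config`.
#' @export
analysis_config <- function(scenario = NULL, trials_path = NULL,
                            factors_path = NULL, overrides = list(),
                            selection_mode = c("last3", "best3"),
                            interaction_order = 2L,
                            mcmc = mcmc_config(),
                            group_by = c("piano", "age_group",
                                         "intelligence", "gender"),
                            seed = 1L, out_dir = NULL, skip_fit = FALSE,
                            best3_control = TRUE, group_ttests = TRUE,
                            correlation_panel = TRUE) {
  selection_mode <- match.arg(selection_mode)
  if (is.null(scenario) && (is.null(trials_path) || is.null(factors_path)))
    stop_arg("either a scenario or both input paths must be given")
  if (!is.null(scenario))
    default_scenario_config(scenario) # validates the name
  stopifnot(inherits(mcmc, "mcmc_config"))
  structure(list(scenario = scenario, trials_path = trials_path,
                 factors_path = factors_path, overrides = overrides,
                 selection_mode = selection_mode,
                 interaction_order = as.integer(interaction_order),
                 mcmc = mcmc, group_by = group_by, seed = as.integer(seed),
                 out_dir = out_dir, skip_fit = isTRUE(skip_fit),
                 best3_control = isTRUE(best3_control),
                 group_ttests = isTRUE(group_ttests),
                 correlation_panel = isTRUE(correlation_panel)),
            class = "analysis_config")
}

# factors with two observed levels enter the ANOVA; constants (e.g. delay in
# a single-delay cohort) are dropped
active_factors <- function(subjects) {
  cand <- c("piano", "age_group", "intelligence", "gender", "delay")
  cand[vapply(cand, function(nm)
    nm %in% names(subjects) && length(unique(subjects[[nm]])) == 2, TRUE)]
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop_arg("[stage %s] %s", label, conditionMessage(e)))
}

#' Run the complete simulate/fit/analyze chain
#'
#' Executes, per the configuration: cohort acquisition (simulation or disk),
#' consolidation scoring (primary mode plus the best-3 control), the
#' factorial ANOVA with the piano-by-age and piano-by-gender simple effects,
#' per-group one-sample t-tests, the correlation panel with the Fisher
#' r-to-z comparison, and (unless skipped) the hierarchical curve fit with
#' its per-parameter factorial ANOVAs. Deterministic given the seed.
#'
#' @param config an [analysis_config()].
#' @return list of results, class `taplearn_results`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  bundle <- list(config = config)

  if (!is.null(config$scenario)) {
    cohort <- stage("simulate", scenario_cohort(config$scenario,
                                                config$overrides,
                                                seed = config$seed))
    trials <- cohort$trials
    subjects <- cohort$factors
    bundle$truth <- cohort$truth
  } else {
    trials <- stage("read", read_trials(config$trials_path))
    subjects <- stage("read", read_factors(config$factors_path))
    stage("read", check_referential(trials, subjects))
  }
  bundle$subjects <- subjects
  bundle$trials <- trials

  fac <- active_factors(subjects)
  bundle$anova_factors <- fac

  scores <- stage("score", score_table(trials, mode = config$selection_mode))
  scores <- scores[match(subjects$subject_id, scores$subject_id), ]
  bundle$scores <- scores

  bundle$consolidation_anova <- stage("anova",
    factorial_anova(scores$transformed, subjects, fac,
                    config$interaction_order))

  if (config$best3_control) {
    best3 <- stage("score", score_table(trials, mode = "best3"))
    best3 <- best3[match(subjects$subject_id, best3$subject_id), ]
    bundle$scores_best3 <- best3
    bundle$consolidation_anova_best3 <- stage("anova",
      factorial_anova(best3$transformed, subjects, fac,
                      config$interaction_order))
  }

  se_pairs <- list(c("piano", "age_group"), c("age_group", "piano"),
                   c("piano", "gender"))
  bundle$simple_effects <- list()
  for (pr in se_pairs) {
    if (!all(pr %in% fac)) next
    lbl <- sprintf("%s_within_%s", pr[1], pr[2])
    bundle$simple_effects[[lbl]] <- stage("simple-effects",
      simple_effects(scores$transformed, subjects, pr[1], pr[2], fac,
                     config$interaction_order))
  }

  if (config$group_ttests && all(c("piano", "age_group") %in% fac)) {
    grp <- interaction(subjects$age_group, subjects$piano, sep = " ")
    bundle$group_ttests <- lapply(split(scores$raw, grp), one_sample_t)
  }

  if (config$correlation_panel && "piano" %in% names(subjects)) {
    player <- subjects$piano == "player"
    panel <- list()
    if (length(unique(subjects$age_years[!player])) > 2 &&
        length(unique(subjects$age_years[player])) > 2) {
      r_non <- pearson_r(subjects$age_years[!player], scores$raw[!player])
      r_pl <- pearson_r(subjects$age_years[player], scores$raw[player])
      panel$age_nonplayer <- r_non
      panel$age_player <- r_pl
      # non-players first: a stronger age-related decline in the non-piano
      # group shows up as z < 0
      panel$age_fisher <- fisher_z_compare(r_non$statistic, sum(!player),
                                           r_pl$statistic, sum(player),
                                           tail = "one")
    }
    if (stats::sd(subjects$piano_hours[player]) > 0)
      panel$hours_player <- pearson_r(subjects$piano_hours[player],
                                      scores$raw[player])
    if ("age_group" %in% names(subjects)) {
      for (lv in c("non-player", "player")) {
        sel <- subjects$piano == lv & subjects$age_group == "older"
        if (sum(sel) >= 3 && stats::sd(scores$day1_mean[sel]) > 0)
          panel[[paste0("day1mean_older_", gsub("-", "", lv))]] <-
            pearson_r(scores$day1_mean[sel], scores$raw[sel])
      }
    }
    bundle$correlations <- panel
  }

  if (!config$skip_fit) {
    grouping <- fit_grouping(subjects, config$group_by)
    fit_cfg <- config$mcmc
    fit_cfg$seed <- substream_seed(config$seed, 999L)
    bundle$fit <- stage("fit", mcmc_fit(trials, grouping, fit_cfg))
    sm <- stage("fit", summarize_fit(bundle$fit))
    bundle$fit_summary <- sm$summary
    bundle$estimates <- sm$estimates
    bundle$curve_anovas <- stage("anova",
      curve_param_anovas(sm$estimates, subjects, fac,
                         config$interaction_order,
                         n_train = max(trials$trial[trials$session == "day1"])))
  }

  if (!is.null(bundle$truth)) {
    # estimated vs configured mean gain per piano x age cell
    grp <- interaction(subjects$age_group, subjects$piano, sep = " ")
    est <- tapply(scores$raw, grp, mean)
    tru <- tapply(bundle$truth$subject_params$mean_gain, grp, mean)
    bundle$gain_recovery <- data.frame(group = names(est),
                                       mean_raw_score = as.numeric(est),
                                       true_mean_gain = as.numeric(tru))
  }

  class(bundle) <- "taplearn_results"
  if (!is.null(config$out_dir)) persist_bundle(bundle, config$out_dir)
  bundle
}

anova_csv <- function(tab) as.data.frame(tab)[c("effect", "ss", "df_num",
                                                "df_den", "F", "p")]

persist_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$subjects, file.path(dir, "factors.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(subject_id = bundle$subjects$subject_id,
                         bundle$scores[c("raw", "transformed")]),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(anova_csv(bundle$consolidation_anova),
                   file.path(dir, "consolidation_anova.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$consolidation_anova_best3))
    utils::write.csv(anova_csv(bundle$consolidation_anova_best3),
                     file.path(dir, "consolidation_anova_best3.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$fit_summary))
    utils::write.csv(bundle$fit_summary, file.path(dir, "fit_summary.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$estimates))
    utils::write.csv(bundle$estimates, file.path(dir, "estimates.csv"),
                     row.names = FALSE)
  cfg <- bundle$config
  cfg$mcmc <- unclass(cfg$mcmc)
  cfg$mcmc$priors <- unclass(cfg$mcmc$priors)
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, TRUE)],
                   file.path(dir, "config.yaml"))
  writeLines(c(sprintf("taplearn run: %s", format(Sys.time())),
               sprintf("seed: %d", bundle$config$seed),
               sprintf("scenario: %s", bundle$config$scenario %||% "<files>"),
               sprintf("subjects: %d", nrow(bundle$subjects)),
               sprintf("R version: %s", R.version.string)),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

fmt_anova <- function(tab, title) {
  rows <- anova_csv(tab)
  c(sprintf("### %s", title), "",
    "| effect | SS | df | F | p |", "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %s | %s | %s |", rows$effect, rows$ss,
            ifelse(is.na(rows$df_den), sprintf("%d", rows$df_num),
                   sprintf("%d, %d", rows$df_num, rows$df_den)),
            ifelse(is.na(rows$F), "", sprintf("%.3f", rows$F)),
            ifelse(is.na(rows$p), "", sprintf("%.4g", rows$p))), "")
}

#' Write a human-readable summary of a results bundle
#'
#' @param bundle a `taplearn_results` from [run_full()].
#' @param path output file (markdown).
#' @return `path`, invisibly.
#' @export
report <- function(bundle, path) {
  stopifnot(inherits(bundle, "taplearn_results"))
  required <- c("subjects", "scores", "consolidation_anova")
  missing <- required[vapply(required, function(nm) is.null(bundle[[nm]]),
                             TRUE)]
  if (length(missing))
    stop_arg("bundle is incomplete; missing section(s): %s",
             paste(missing, collapse = ", "))
  lines <- c("# Finger-tapping consolidation analysis", "",
             sprintf("Subjects: %d; factors in the model: %s",
                     nrow(bundle$subjects),
                     paste(bundle$anova_factors, collapse = ", ")), "")
  lines <- c(lines, fmt_anova(bundle$consolidation_anova,
                              "Consolidation ANOVA (transformed scores)"))
  if (!is.null(bundle$consolidation_anova_best3))
    lines <- c(lines, fmt_anova(bundle$consolidation_anova_best3,
                                "Best-3 control ANOVA"))
  for (nm in names(bundle$simple_effects)) {
    se <- bundle$simple_effects[[nm]]
    lines <- c(lines, sprintf("### Simple effects: %s", nm), "",
               sprintf("- %s: F(%d, %d) = %.3f, p = %.4g",
                       se$within_level, se$df_num, se$df_den, se$F, se$p), "")
  }
  if (!is.null(bundle$group_ttests)) {
    lines <- c(lines, "### Per-group consolidation t-tests", "",
               vapply(names(bundle$group_ttests), function(g) {
                 tt <- bundle$group_ttests[[g]]
                 sprintf("- %s: mean gain %.3f, t(%d) = %.3f, p = %.4g",
                         g, tt$estimate, tt$df, tt$statistic, tt$p)
               }, ""), "")
  }
  if (!is.null(bundle$correlations)) {
    lines <- c(lines, "### Correlation panel", "",
               vapply(names(bundle$correlations), function(nm) {
                 r <- bundle$correlations[[nm]]
                 sprintf("- %s: %s = %.3f, p = %.4g (%s-tailed)", nm,
                         r$type, r$statistic, r$p, r$tail)
               }, ""), "")
  }
  if (!is.null(bundle$curve_anovas))
    for (nm in names(bundle$curve_anovas))
      lines <- c(lines, fmt_anova(bundle$curve_anovas[[nm]],
                                  sprintf("Curve-parameter ANOVA: %s", nm)))
  if (!is.null(bundle$gain_recovery)) {
    gr <- bundle$gain_recovery
    lines <- c(lines, "### Estimated vs configured mean gains", "",
               "| group | mean raw score | true mean gain |", "|---|---|---|",
               sprintf("| %s | %.3f | %.3f |", gr$group, gr$mean_raw_score,
                       gr$true_mean_gain), "")
  }
  writeLines(lines, path)
  invisible(path)
}
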