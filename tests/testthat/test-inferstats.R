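test_that("consolidation scores follow the last3/best3 contracts", {
  sc <- consolidation_score(c(5, 6, 7, 10, 11, 12), c(13, 14, 15))
  expect_equal(sc$raw, 3)
  expect_equal(sc$transformed, sqrt(3))

  same <- consolidation_score(c(1, 13, 14, 15), c(13, 14, 15))
  expect_equal(same$raw, 0)
  expect_equal(same$transformed, 0)

  d1 <- c(2, 9, 4, 8, 3, 10, 1, 2, 3, 5, 5, 5)
  best <- consolidation_score(d1, c(10, 10, 10), mode = "best3")
  last <- consolidation_score(d1, c(10, 10, 10), mode = "last3")
  expect_equal(best$raw, 10 - 9)
  expect_equal(last$raw, 10 - 5)

  neg <- consolidation_score(c(1, 8, 8, 8), c(4, 4, 4))
  expect_equal(neg$raw, -4)
  expect_equal(neg$transformed, -2)

  expect_error(consolidation_score(c(1, 2), c(1, 2, 3)), "at least 3")
  expect_error(consolidation_score(1:5, c(1, 2)), "exactly 3")
})

test_that("signed-root transform reduces positive skewness", {
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  set.seed(2)
  raw <- rgamma(500, shape = 2, rate = 1) - 0.5
  expect_lt(abs(skew(signed_sqrt(raw))), abs(skew(raw)))
  expect_equal(signed_sqrt(-4), -2)
  expect_equal(signed_sqrt(c(-9, 0, 9)), c(-3, 0, 3))
})

test_that("factorial ANOVA reproduces the hand-computed 2x2 table", {
  subjects <- data.frame(
    A = rep(c("a0", "a1"), each = 4),
    B = rep(c("b0", "b0", "b1", "b1"), 2))
  y <- c(1, 3, 2, 4, 5, 7, 6, 8)
  tab <- factorial_anova(y, subjects, c("A", "B"), 2)
  get <- function(eff, col) tab[tab$effect == eff, col]
  expect_equal(get("A", "ss"), 32)
  expect_equal(get("B", "ss"), 2)
  expect_equal(get("A:B", "ss"), 0)
  expect_equal(get("Residuals", "ss"), 8)
  expect_equal(get("Residuals", "df_num"), 4)
  expect_equal(get("A", "F"), 16)
  expect_equal(get("B", "F"), 1)
  expect_equal(get("A", "df_den"), 4)
})

test_that("F statistics agree with the cell-mean projection oracle", {
  set.seed(42)
  for (rep in 1:25) {
    d <- random_balanced_design()
    tab <- factorial_anova(d$response, d$subjects, d$factor_names, 2)
    ora <- oracle_anova_F(d$response, d$subjects, d$factor_names, 2)
    for (eff in names(ora$F)) {
      got <- tab$F[tab$effect == eff]
      expect_equal(got, unname(ora$F[eff]), tolerance = 1e-9)
    }
    expect_equal(tab$ss[tab$effect == "Residuals"], ora$ss_res,
                 tolerance = 1e-9)
  }
})

test_that("balanced effect sums of squares partition the total", {
  set.seed(7)
  d <- random_balanced_design()
  tab <- factorial_anova(d$response, d$subjects, d$factor_names,
                         length(d$factor_names))
  total <- sum((d$response - mean(d$response))^2)
  expect_equal(sum(tab$ss), total, tolerance = 1e-9 * total)
})

test_that("constant responses give zero effect sums of squares", {
  subjects <- generate_design(2, canonical_factors(), seed = 3)
  tab <- factorial_anova(rep(4.2, nrow(subjects)), subjects)
  expect_true(all(tab$ss[tab$effect != "Residuals"] < 1e-20))
})

test_that("unbalanced designs use effect-coded partial SS", {
  # dropping one subject must not error and must keep df bookkeeping right
  subjects <- generate_design(2, canonical_factors(), seed = 5)[-1, ]
  y <- rnorm(nrow(subjects))
  tab <- factorial_anova(y, subjects)
  expect_equal(tab$df_num[tab$effect == "Residuals"], 31 - 11)
  expect_true(all(is.finite(tab$F[tab$effect != "Residuals"])))
  # the control-1 cohort's 20/20/14/13 recruitment (67 subjects) is
  # analyzable and lands on the reported denominator df of 56
  c1 <- scenario_cohort("control1", seed = 5)
  sc <- score_table(c1$trials)
  sc <- sc[match(c1$factors$subject_id, sc$subject_id), ]
  tab1 <- factorial_anova(sc$transformed, c1$factors)
  expect_equal(tab1$df_num[tab1$effect == "Residuals"], 67 - 11)
  expect_true(all(tab1$df_den[tab1$effect != "Residuals"] == 56))
})

test_that("simple effects use the pooled residual mean square", {
  subjects <- data.frame(
    A = rep(c("a0", "a1"), each = 4),
    B = rep(c("b0", "b0", "b1", "b1"), 2))
  y <- c(1, 3, 2, 4, 5, 7, 6, 8)
  se <- simple_effects(y, subjects, "A", "B", c("A", "B"), 2)
  b0 <- se[se$within_level == "b0", ]
  expect_equal(b0$estimate, 4)
  expect_equal(b0$F, 8)
  expect_equal(b0$df_den, 4)
  expect_equal(b0$p, pf(8, 1, 4, lower.tail = FALSE))
  expect_error(simple_effects(y, subjects, "A", "A", c("A", "B")),
               "different")

  # identical cell means within a level give F = 0
  y2 <- c(1, 3, 2, 4, 1, 3, 6, 8)
  se2 <- simple_effects(y2, subjects, "A", "B", c("A", "B"), 2)
  expect_equal(se2$F[se2$within_level == "b0"], 0)
})

test_that("simple effects keep the full model's denominator df at scale", {
  co <- scenario_cohort("main", seed = 23)
  sc <- score_table(co$trials)
  sc <- sc[match(co$factors$subject_id, sc$subject_id), ]
  se <- simple_effects(sc$transformed, co$factors, "piano", "age_group")
  expect_true(all(se$df_den == 117))
  # antisymmetry: swapping the target's levels flips the estimate
  flipped <- co$factors
  flipped$piano <- factor(flipped$piano, levels = c("player", "non-player"))
  se2 <- simple_effects(sc$transformed, flipped, "piano", "age_group")
  expect_equal(se2$estimate, -se$estimate)
  expect_equal(se2$F, se$F)
})

test_that("scalar tests match their textbook formulas", {
  tt <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tt$df, 2)
  sym <- one_sample_t(c(4, 6, 5), 5)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 1)
  expect_error(one_sample_t(c(3)), "n >= 2")
  expect_error(one_sample_t(c(3, 3, 3)), "zero-variance")

  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$statistic, 1)
  expect_equal(pearson_r(1:10, -(1:10))$statistic, -1)
  r <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$statistic, 0.6)
  expect_equal(r$df, 2)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("Fisher z comparison matches the reported worked example", {
  fz <- fisher_z_compare(-0.448, 64, -0.167, 64, tail = "one")
  expect_equal(round(fz$statistic, 2), -1.73)
  expect_equal(round(fz$p, 3), 0.042)

  eq <- fisher_z_compare(0.3, 30, 0.3, 30, tail = "one")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 0.5)

  ab <- fisher_z_compare(0.5, 40, 0.2, 50)
  ba <- fisher_z_compare(0.2, 50, 0.5, 40)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p, ba$p)
  expect_error(fisher_z_compare(1, 30, 0.5, 30), "\\|r\\| < 1")
  expect_error(fisher_z_compare(0.2, 3, 0.5, 30), "n >= 4")
})

test_that("curve-parameter ANOVAs analyze I, R and the implied improvement", {
  subjects <- generate_design(8, canonical_factors(), seed = 12)
  est <- data.frame(
    subject_id = subjects$subject_id,
    I = ifelse(subjects$piano == "player", 14, 8) + rnorm(128, 0, 0.5),
    C = rnorm(128, 8, 0.5),
    R = rep(0.5, 128) + rnorm(128, 0, 1e-6))
  tabs <- curve_param_anovas(est, subjects, n_train = 12)
  expect_named(tabs, c("I", "R", "improvement"))
  F_piano_I <- tabs$I$F[tabs$I$effect == "piano"]
  F_piano_R <- tabs$R$F[tabs$R$effect == "piano"]
  expect_gt(F_piano_I, 100)
  expect_lt(F_piano_R, 5)
  expect_true(all(tabs$improvement$df_den == 117, na.rm = TRUE))
  expect_error(curve_param_anovas(est[-1, ], subjects), "missing subject")
})

test_that("partial SS agree with car's Type-III ANOVA on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(31)
  subjects <- generate_design(3, canonical_factors(), seed = 8)[-c(2, 9), ]
  y <- rnorm(nrow(subjects)) + (subjects$piano == "player")
  tab <- factorial_anova(y, subjects)
  dat <- taplearn:::as_effect_factors(
    subjects, c("piano", "age_group", "intelligence", "gender"))
  dat$.y <- y
  fit <- lm(.y ~ (piano + age_group + intelligence + gender)^2, dat)
  a3 <- car::Anova(fit, type = 3)
  for (eff in tab$effect[tab$effect != "Residuals"]) {
    expect_equal(tab$ss[tab$effect == eff], a3[eff, "Sum Sq"],
                 tolerance = 1e-10)
    expect_equal(tab$F[tab$effect == eff], a3[eff, "F value"],
                 tolerance = 1e-10)
  }
})

test_that("simple effects agree with emmeans joint tests", {
  skip_if_not_installed("emmeans")
  co <- scenario_cohort("main", seed = 23)
  sc <- score_table(co$trials)
  sc <- sc[match(co$factors$subject_id, sc$subject_id), ]
  se <- simple_effects(sc$transformed, co$factors, "piano", "age_group")
  dat <- taplearn:::as_effect_factors(
    co$factors, c("piano", "age_group", "intelligence", "gender"))
  dat$.y <- sc$transformed
  fit <- lm(.y ~ (piano + age_group + intelligence + gender)^2, dat)
  jt <- as.data.frame(suppressMessages(
    emmeans::joint_tests(fit, by = "age_group")))
  for (lv in se$within_level) {
    ref <- jt[jt$age_group == lv & trimws(jt$`model term`) == "piano", ]
    expect_equal(se$F[se$within_level == lv], ref$F.ratio,
                 tolerance = 5e-3) # joint_tests rounds F to 3 d.p.
  }
})
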