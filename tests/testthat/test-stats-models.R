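test_that("fit_lmm matches lme4 maximum likelihood on a seeded dataset", {
  skip_if_not_installed("lme4")
  d <- gen_morphometry(morpho_sim_config(seed = 7))
  wk <- d[d$week == 13, ]
  ours <- fit_lmm(wk, "log_area")
  wk$genotype <- relevel(factor(wk$genotype), "control")
  ref <- lme4::lmer(log(area_mm2) ~ genotype + (1 | line_id), data = wk,
                    REML = FALSE)
  expect_equal(unname(coef(ours)), unname(lme4::fixef(ref)), tolerance = 1e-6)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(ours$sigma_line, sqrt(unname(unlist(lme4::VarCorr(ref)))),
               tolerance = 1e-4)
  expect_equal(ours$sigma_resid, stats::sigma(ref), tolerance = 1e-4)
})

test_that("at the sigma_line = 0 boundary the fit collapses to OLS", {
  set.seed(21)
  # genotype balanced within line; residuals centred within line so the
  # between-line variance component is genuinely zero, not just small
  d <- data.frame(line_id = rep(c("a", "b", "c", "d"), each = 6),
                  genotype = rep(c("control", "case"), 12))
  eps <- rnorm(24)
  eps <- eps - ave(eps, d$line_id)
  d$y <- eps + (d$genotype == "case")
  f <- fit_lmm(d, "y")
  ols <- lm(y ~ relevel(factor(genotype), "control"), data = d)
  # ML residual variance uses 1/n; logLik(lm) is the same ML quantity
  expect_lte(f$sigma_line, 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(ols)), tolerance = 1e-6)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("planted genotype log-fold is recovered across simulations", {
  est <- vapply(1:100, function(s) {
    d <- gen_morphometry(morpho_sim_config(genotype_fold = 1.5,
                                           residual_sd = 0.05,
                                           line_sd = 0.05, seed = s))
    wk <- d[d$week == 13, ]
    unname(coef(fit_lmm(wk, "log_area"))[2])
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(1.5)), 2 * se)
})

test_that("duplicating observations changes the likelihood, not the GLS betas", {
  d <- gen_morphometry(morpho_sim_config(seed = 13))
  wk <- d[d$week == 13, ]
  f1 <- fit_lmm(wk, "log_area")
  f2 <- fit_lmm(rbind(wk, wk), "log_area")
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-4)
  expect_false(isTRUE(all.equal(f1$loglik, f2$loglik)))
})

test_that("LRT nesting and degenerate cases behave", {
  d <- gen_morphometry(morpho_sim_config(seed = 17))
  wk <- d[d$week == 13, ]
  lrt <- lrt_genotype(wk, "log_area")
  expect_gte(lrt$chi2, 0)
  expect_gte(lrt$fit_full$loglik, lrt$fit_null$loglik - 1e-8)
  expect_equal(lrt$df, 1L)

  wk$flat <- 1.0   # identical response values
  flat <- lrt_genotype(wk, "flat")
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)

  one <- wk[wk$genotype == "case", ]
  expect_error(fit_lmm(one, "log_area"), "single level")
})

test_that("a planted 1.5-fold effect gives overwhelming LRT evidence", {
  chi2 <- vapply(1:20, function(s) {
    d <- gen_morphometry(morpho_sim_config(genotype_fold = 1.5,
                                           residual_sd = 0.15,
                                           line_sd = 0.05, seed = 100 + s))
    lrt_genotype(d[d$week == 13, ], "log_area")$chi2
  }, numeric(1))
  expect_gt(median(chi2), 3.84)
})

test_that("chi-square upper tail matches the normal-tail oracle at df = 1", {
  expect_equal(chi2_upper_tail(0, 1), 1)
  expect_equal(chi2_upper_tail(3.8415, 1), 2 * pnorm(-sqrt(3.8415)),
               tolerance = 1e-10)
  for (z in c(0.5, 1, 1.96, 2.5, 3.3)) {
    expect_equal(chi2_upper_tail(z^2, 1), 2 * pnorm(-z), tolerance = 1e-10)
    expect_equal(p_from_z(z), chi2_upper_tail(z^2, 1), tolerance = 1e-10)
  }
  expect_error(chi2_upper_tail(-1, 1), "non-negative")
})

test_that("welch_t reduces to the pooled t for equal n and variance", {
  a <- c(1, 2, 3, 4, 5)
  b <- a + 2
  w <- welch_t(a, b)
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$df, 2 * length(a) - 2)
  expect_equal(w$t_stat, unname(pooled$statistic))
  expect_equal(w$p_value, pooled$p.value)

  same <- welch_t(a, a)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  const <- welch_t(rep(2, 3), rep(2, 4))
  expect_equal(const$p_value, 1)
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "constant")
  expect_error(welch_t(1, 1:3), "n >= 2")
})

test_that("one-sample t handles symmetry and rejects zero variance", {
  sym <- one_sample_t(c(-2, -1, 1, 2), mu0 = 0)
  expect_equal(sym$t_stat, 0)
  expect_equal(sym$p_value, 1)
  h <- one_sample_t(c(1, 2, 3), mu0 = 0)   # hand: t = 2/(1/sqrt(3))
  expect_equal(h$t_stat, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(h$p_value, 0.0741799, tolerance = 1e-6)
  expect_error(one_sample_t(rep(5, 4), 0), "zero variance")
})

test_that("subject z-scores standardize against the reference stratum", {
  expect_equal(subject_z(50, 50, 1.5)$z, 0)
  expect_equal(subject_z(53, 50, 1.5)$z, 2)
  ref <- data.frame(sex = c("m", "f"), age_months = c(24, 24),
                    mean = c(50, 49), sd = c(1.5, 1.4))
  z <- subject_z(54.4, ref = ref, sex = "m", age_months = 24)
  expect_equal(z$z, (54.4 - 50) / 1.5, tolerance = 1e-9)
  expect_equal(round(z$z, 3), 2.933)
  expect_error(subject_z(54, ref = ref, sex = "m", age_months = 36),
               "age_months=36")
  expect_error(subject_z(54, 50, 0), "positive")
})

test_that("weighted z combination obeys the Stouffer identities", {
  one <- combined_weighted_z(2.93)
  expect_equal(one$z_combined, 2.93)
  expect_equal(one$p_two_sided, 2 * pnorm(-2.93))
  expect_equal(combined_weighted_z(rep(1.2, 4))$z_combined, 1.2 * 2)
  expect_equal(combined_weighted_z(c(1.7, -1.7))$z_combined, 0)
  expect_error(combined_weighted_z(c(1, 2), c(0, 0)), "not all zero")
  expect_error(combined_weighted_z(c(1, 2), 1), "lengths")
})

test_that("median of three blinded ordinal scores is the middle one", {
  expect_equal(median_score(c(0, 1, 2)), 1L)
  expect_equal(median_score(c(2, 2, 0)), 2L)
  expect_equal(median_score(c(-1, 0, 1)), 0L)
  expect_error(median_score(c(1, 2)), "exactly 3")
  expect_error(median_score(c(0, 1, 3)), "-2..2")
})
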