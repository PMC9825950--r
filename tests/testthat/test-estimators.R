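test_that("with no censoring the IPWCC estimate equals the full-data fit", {
  cfg <- scenario_config("ordinal", beta = log(1.5), n_max = 200)
  full <- generate_trial(cfg, seed = 8)
  snap <- interim_data(full, cfg$t_end)      # everyone fully followed
  po <- outcome_model("proportional_odds", n_categories = 6L)
  ipw <- fit_ipwcc(snap, po)
  ref <- solve_estimating_equation(po, full$outcome, full$arm)
  expect_identical(ipw$beta, ref$beta)
  expect_identical(unname(ipw$theta), unname(ref$theta))
  # dependent variable reduces to the influence values
  expect_equal(ipw$yhat, ipw$m)
})

test_that("binary IPWCC equals the log ratio of treatment-specific KM estimates", {
  skip_if_not_installed("survival")
  rr <- outcome_model("log_relative_risk")
  for (s in 1:12) {
    snap <- random_binary_snapshot(s, n = 150, t = 150 + 10 * (s %% 4))
    fit <- fit_ipwcc(snap, rr)
    ev <- snap$ascertained == 1L & !is.na(snap$outcome) & snap$outcome == 1
    p <- vapply(0:1, function(a) {
      sel <- snap$arm == a
      sf <- survival::survfit(survival::Surv(snap$obs_time[sel], ev[sel]) ~ 1)
      1 - summary(sf, times = snap$tf - 1e-9)$surv
    }, numeric(1))
    expect_equal(fit$beta, log(p[2] / p[1]), tolerance = 1e-10)
  }
})

test_that("the dependent variable has mean zero at the Step-1 solution", {
  cfg <- scenario_config("ordinal", beta = log(1.5), n_max = 400)
  snap <- interim_data(generate_trial(cfg, seed = 14), 165)
  po <- outcome_model("proportional_odds", n_categories = 6L)
  ipw <- fit_ipwcc(snap, po)
  expect_lt(abs(sum(ipw$yhat)), 1e-8 * snap$n_enrolled)
  yh <- dependent_variable(snap, ipw)
  expect_equal(yh, ipw$yhat)
})

test_that("augmentation covariates: baseline centering and martingale structure", {
  snap <- fixture_censor4()
  cm <- censoring_km(snap)
  bs <- basis_spec(f = list(function(x) rep(2, nrow(x))))  # constant-2 'covariate'
  # with pi known the baseline column is (A - pi) f(X)
  Xa <- augmentation_covariates(snap, bs, cm, include_h = FALSE)
  expect_equal(unname(Xa[, 2]), (snap$arm - snap$pi_t) * 2)

  # no censoring events: martingale columns vanish and AIPW2 = AIPW1
  cfg <- scenario_config("ordinal", beta = 0, n_max = 150)
  snap2 <- interim_data(generate_trial(cfg, seed = 4), cfg$t_end)
  cm2 <- censoring_km(snap2)
  Xa2 <- augmentation_covariates(snap2, default_basis(snap2), cm2)
  hcols <- grep("^h", colnames(Xa2))
  expect_true(length(hcols) == 6)
  expect_true(all(Xa2[, hcols] == 0))

  # martingale columns are mean-zero noise: standardized arm means are small
  snap3 <- interim_data(generate_trial(scenario_config("ordinal", beta = 0), seed = 6), 150)
  cm3 <- censoring_km(snap3)
  Xa3 <- augmentation_covariates(snap3, default_basis(snap3), cm3)
  for (j in grep("^h", colnames(Xa3))) {
    a <- as.integer(sub(".*_arm", "", colnames(Xa3)[j]))
    col <- Xa3[snap3$arm == a, j]
    if (sd(col) > 0)
      expect_lt(abs(mean(col)) / (sd(col) / sqrt(length(col))), 4)
  }
})

test_that("AIPW1 and AIPW2 coincide at the final analysis", {
  cfg <- scenario_config("ordinal", beta = log(1.5), n_max = 250)
  snap <- interim_data(generate_trial(cfg, seed = 10), cfg$t_end)
  po <- outcome_model("proportional_odds", n_categories = 6L)
  a1 <- fit_aipwcc(snap, po, include_h = FALSE)
  a2 <- fit_aipwcc(snap, po, include_h = TRUE)
  expect_equal(a1$beta, a2$beta, tolerance = 1e-12)
  expect_equal(a1$se, a2$se, tolerance = 1e-12)
})

test_that("an intercept-only basis leaves the Step-1 estimate essentially unchanged", {
  cfg <- scenario_config("ordinal", beta = 0, n_max = 400)
  snap <- interim_data(generate_trial(cfg, seed = 12), 170)
  po <- outcome_model("proportional_odds", n_categories = 6L)
  a1 <- fit_aipwcc(snap, po, basis = basis_spec(), include_h = FALSE)
  expect_lt(abs(a1$beta - a1$beta_init), a1$se / 100)
})

test_that("the augmented estimator is a genuine variance reduction in-sample", {
  cfg <- scenario_config("ordinal", beta = log(1.5), n_max = 500)
  snap <- interim_data(generate_trial(cfg, seed = 19), 160)
  po <- outcome_model("proportional_odds", n_categories = 6L)
  cm <- censoring_km(snap)
  ipw <- fit_ipwcc(snap, po, cm)
  a1 <- fit_aipwcc(snap, po, cm = cm, include_h = FALSE, ipw = ipw)
  a2 <- fit_aipwcc(snap, po, cm = cm, include_h = TRUE, ipw = ipw)
  # least squares cannot increase the residual sum of squares
  expect_lte(a1$se, ipw$se + 1e-12)
  expect_lte(a2$se, a1$se + 1e-12)
})

test_that("Wald statistics behave as ratios", {
  snap <- fixture_censor4()
  fit <- list(kind = "tf", beta = 0.730, se = 0.292, t = 1)
  class(fit) <- "gslag_fit"
  expect_equal(wald_statistic(fit), 0.730 / 0.292)
  expect_equal(round(wald_statistic(fit), 3), 2.500)
  fit$beta <- 0
  expect_equal(wald_statistic(fit), 0)
  fit$beta <- -0.5
  expect_lt(wald_statistic(fit), 0)
})

test_that("fully-followed-only estimator matches the full-data analysis when complete", {
  cfg <- scenario_config("continuous", beta = 6.24, n_max = 120)
  full <- generate_trial(cfg, seed = 30)
  snap <- interim_data(full, cfg$t_end)
  dm <- outcome_model("difference_of_means")
  tf_fit <- fit_tf_only(snap, dm)
  y <- full$outcome; a <- full$arm
  expect_equal(tf_fit$beta, mean(y[a == 1]) - mean(y[a == 0]), tolerance = 1e-12)
  # continuous scenario: TF-only and IPWCC agree at interims too (T = tf for all)
  snap2 <- interim_data(full, 130)
  tf2 <- fit_tf_only(snap2, dm)
  ipw2 <- fit_ipwcc(snap2, dm)
  expect_equal(tf2$beta, ipw2$beta, tolerance = 1e-12)
})
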