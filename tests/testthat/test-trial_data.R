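test_that("interim snapshot computes censoring, observed time, ascertainment", {
  # one subject with lag exceeding follow-up so far: forced censored
  full <- full_trial_data(entry = c(100, 10, 20), arm = c(1, 0, 1),
                          lag = c(90, 90, 30), outcome = c(5, 2, 6), tf = 90)
  snap <- interim_data(full, 150)
  i <- which(snap$entry == 100)
  expect_equal(snap$cens_time[i], 50)
  expect_equal(snap$obs_time[i], 50)
  expect_equal(snap$ascertained[i], 0L)
  expect_true(is.na(snap$outcome[i]))        # outcome hidden exactly when censored
  expect_equal(snap$pi_t, 2 / 3)
  expect_equal(snap$n_fully_followed, 2L)

  # late enough analysis reproduces the full data exactly
  late <- interim_data(full, max(full$entry) + full$tf)
  expect_equal(late$n_enrolled, full$n)
  expect_true(all(late$ascertained == 1L))
  expect_equal(late$obs_time, full$lag)
  expect_equal(late$outcome, full$outcome)
})

test_that("interim snapshot errors and warnings guard degenerate analyses", {
  full <- full_trial_data(entry = c(0, 5, 100), arm = c(0, 1, 1),
                          lag = c(30, 30, 30), outcome = c(1, 0, 1), tf = 30)
  expect_error(interim_data(full, -1), "positive")
  # only arm-0 subject enrolled very early
  full2 <- full_trial_data(entry = c(1, 50), arm = c(0, 1),
                           lag = c(30, 30), outcome = c(1, 0), tf = 30)
  expect_error(interim_data(full2, 10), "arm")
  expect_warning(interim_data(full, 20), "followed")
})

test_that("scenario-1 final analysis has everyone enrolled and fully followed", {
  cfg <- scenario_config("ordinal", beta = 0)
  snap <- interim_data(generate_trial(cfg, seed = 1), 330)
  expect_equal(snap$n_enrolled, 602L)
  expect_equal(snap$n_fully_followed, 602L)
})

test_that("censoring Kaplan-Meier follows the pr{C >= u} convention", {
  snap <- fixture_censor4()
  cm <- censoring_km(snap, hazard = "neglog-km")
  expect_equal(km_survival(cm, 20, group = 0), 1)        # strictly-earlier jumps only
  expect_equal(km_survival(cm, 30, group = 0), 2 / 3)
  expect_equal(km_cum_hazard(cm, 30, group = 0), -log(2 / 3))
  expect_equal(km_survival(cm, c(0, 10), group = 0), c(1, 1))
  # no censoring events in arm 1: survival identically 1
  expect_equal(km_survival(cm, c(10, 55), group = 1), c(1, 1))
  expect_equal(km_cum_hazard(cm, 55, group = 1), 0)
})

test_that("censoring KM agrees with survival::survfit on simulated data", {
  skip_if_not_installed("survival")
  snap <- random_binary_snapshot(4)
  cm <- censoring_km(snap, arm_specific = FALSE)
  sf <- survival::survfit(survival::Surv(snap$obs_time, 1 - snap$ascertained) ~ 1)
  at <- sf$time[sf$n.event > 0]
  # left limit of the right-continuous survfit curve = our pr{C >= u}
  ours <- km_survival(cm, at + 1e-9, group = 0)
  theirs <- summary(sf, times = at)$surv
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("martingale integral matches hand computation on the 4-point fixture", {
  snap <- fixture_censor4()
  h <- function(u) 2.5
  cens20 <- which(snap$obs_time == 20 & snap$arm == 0L)

  # -log K increments: (1 - 0.4055) h(20)
  cm_nl <- censoring_km(snap, hazard = "neglog-km")
  expect_equal(martingale_integral(cens20, cm_nl, h),
               2.5 * (1 - (-log(2 / 3))), tolerance = 1e-12)

  # product-limit-consistent increments: (1 - 1/3) h(20)
  cm <- censoring_km(snap)
  expect_equal(martingale_integral(cens20, cm, h), 2.5 * (1 - 1 / 3))

  # ascertained before the first jump: empty sum, no event
  first <- which(snap$obs_time == 10)
  expect_equal(martingale_integral(first, cm, h), 0)
  # arm with no censoring events: zero for every subject
  for (i in which(snap$arm == 1L))
    expect_equal(martingale_integral(i, cm, h), 0)
  # vector integrand passes through elementwise
  expect_equal(martingale_integral(cens20, cm, function(u) c(1, u)),
               c(1, 20) * (1 - 1 / 3))
})

test_that("estimated censoring martingales sum to zero within an arm", {
  snap <- fixture_censor4()
  cm <- censoring_km(snap)
  s <- sum(vapply(which(snap$arm == 0L),
                  function(i) martingale_integral(i, cm, function(u) 1),
                  numeric(1)))
  expect_lt(abs(s), 1e-8)
  # and on a larger simulated snapshot, arm by arm
  snap2 <- random_binary_snapshot(9, n = 150)
  cm2 <- censoring_km(snap2)
  for (a in 0:1) {
    s2 <- sum(vapply(which(snap2$arm == a),
                     function(i) martingale_integral(i, cm2, function(u) 1),
                     numeric(1)))
    expect_lt(abs(s2), 1e-8)
  }
})

test_that("inverse-probability weights average to one within arms", {
  cfg <- scenario_config("ordinal", beta = log(1.5), n_max = 300)
  snap <- interim_data(generate_trial(cfg, seed = 21), 170)
  cm <- censoring_km(snap)
  d <- snap$ascertained
  for (a in 0:1) {
    idx <- which(snap$arm == a)
    cc <- idx[d[idx] == 1L]
    w <- 1 / km_survival(cm, snap$obs_time[cc], group = a)
    expect_lt(abs(sum(w) / length(idx) - 1), 0.15)
  }
})

test_that("trial data round-trips through CSV", {
  cfg <- scenario_config("ordinal", beta = log(1.5), n_max = 40)
  full <- generate_trial(cfg, seed = 3)
  fs <- tempfile(fileext = ".csv"); fc <- tempfile(fileext = ".csv")
  write_trial_data(full, fs, fc)
  back <- read_trial_data(fs, tf = full$tf, covariate_file = fc)
  expect_equal(back$entry, full$entry)
  expect_equal(back$arm, full$arm)
  expect_equal(back$outcome, full$outcome)
  expect_equal(unname(back$x), unname(full$x))
  for (i in c(1L, 17L)) {
    expect_equal(back$paths[[i]]$time, full$paths[[i]]$time)
    expect_equal(unname(back$paths[[i]]$value), unname(full$paths[[i]]$value))
  }
  unlink(c(fs, fc))
})

test_that("path queries are right-continuous last-value-carried-forward", {
  p <- list(time = c(0, 3, 7), value = cbind(c(1, 2, 5)))
  expect_equal(as.numeric(path_value(p, c(0, 2.9, 3, 6.9, 7, 100))),
               c(1, 1, 2, 2, 5, 5))
})
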