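# Hand-checkable censoring fixture.  Arm 0 carries observed times/statuses
# (U, D) = (10,1), (20,0), (30,1), (40,0): censoring events at 20 and 40, so
# K(20) = 1, K(30) = 2/3 (product-limit with risk set {20,30,40} at 20).
# Arm 1 holds two fully followed subjects so both arms are non-empty.
# tf = 41, analysis at t = 100.
fixture_censor4 <- function() {
  full <- full_trial_data(
    entry = c(90, 80, 70, 60, 50, 45),
    arm = c(0, 0, 0, 0, 1, 1),
    lag = c(10, 41, 30, 41, 20, 25),
    outcome = c(1, 0, 1, 0, 1, 0),
    tf = 41)
  interim_data(full, 100)
}

# small random interim snapshot from the binary scenario
random_binary_snapshot <- function(seed, n = 120, t = 170) {
  cfg <- scenario_config("binary", beta = log(1.5), n_max = n)
  interim_data(generate_trial(cfg, seed = seed), t)
}

expect_equal_tol <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
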