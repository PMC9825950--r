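#' Configure a benchmark synthetic-trial scenario
#'
#' Three generative scenarios, each with staggered uniform enrollment over
#' `[0, e_max]` and 1:1 Bernoulli randomization, emulating monitored trials
#' with a time-lagged outcome:
#'
#' * `"ordinal"`: a six-category ordinal endpoint at `tf = 90` days (the
#'   worst category, death, is ascertained at the random death time; all
#'   others only at 90 days), generated from a latent uniform so that a
#'   proportional odds model holds exactly with log odds ratio `beta`.
#'   Control category probabilities are (0.12, 0.23, 0.17, 0.10, 0.05, 0.33).
#'   Defaults: `n_max = 602`, `e_max = 240`, analyses at
#'   (150, 195, 240, 285) and final at 330 days.  A correlated baseline
#'   covariate `X ~ N(1.5(U - 0.5), 1)` and two time-dependent covariates
#'   (hospital-discharge indicator `L1(u)` and expected days out of hospital
#'   `L2(u)`) are produced.
#' * `"binary"`: same latent machinery, `Y = 1` (death, ascertained at the
#'   death time) when the latent exceeds 0.67, else `Y = 0` (known only at 90
#'   days); `beta` is still the latent log odds ratio, and the analysis-scale
#'   effect is the log relative risk (see [scenario_effect()]).  Default
#'   `n_max = 900`.
#' * `"continuous"`: a longitudinal endpoint measured at visit weeks
#'   (0, 4, 12, 24, 52) from a linear mixed model with random intercept and
#'   slope; the outcome is the week-52 value, so `T = tf = 52` for everyone.
#'   `beta` is the treatment difference in mean outcome at week 52
#'   (treatment slope `xi2 = xi1 + beta/52` with control slope
#'   `xi1 = -0.3`).  The baseline covariate is the week-0 measurement; the
#'   time-dependent covariate is the most recent measurement.  Defaults:
#'   `n_max = 300`, `e_max = 156`, analyses (104, 130, 156, 182), final 208.
#'
#' @param scenario `"ordinal"`, `"binary"`, or `"continuous"`.
#' @param beta treatment effect on the scenario's generative scale (see
#'   above); 0 is the null.
#' @param n_max,e_max,analysis_times,t_end optional overrides of the
#'   scenario defaults.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("ordinal", "binary", "continuous"),
                            beta = 0, n_max = NULL, e_max = NULL,
                            analysis_times = NULL, t_end = NULL) {
  scenario <- match.arg(scenario)
  def <- switch(scenario,
    ordinal = list(n_max = 602L, e_max = 240, tf = 90,
                   analysis_times = c(150, 195, 240, 285), t_end = 330),
    binary = list(n_max = 900L, e_max = 240, tf = 90,
                  analysis_times = c(150, 195, 240, 285), t_end = 330),
    continuous = list(n_max = 300L, e_max = 156, tf = 52,
                      analysis_times = c(104, 130, 156, 182), t_end = 208))
  cfg <- list(scenario = scenario, beta = beta,
              n_max = if (is.null(n_max)) def$n_max else as.integer(n_max),
              e_max = if (is.null(e_max)) def$e_max else e_max,
              tf = def$tf,
              analysis_times = if (is.null(analysis_times)) def$analysis_times else analysis_times,
              t_end = if (is.null(t_end)) def$t_end else t_end,
              cutpoints = c(0, 0.12, 0.35, 0.52, 0.62, 0.67, 1),
              xi1 = -0.3, visit_weeks = c(0, 4, 12, 24, 52), sigma = 4.5,
              D = matrix(c(80, -0.5, -0.5, 0.08), 2L, 2L),
              x1_probs = c(0.4, 0.3, 0.2, 0.1), x1_means = c(65, 60, 55, 49))
  if (cfg$analysis_times[1L] < cfg$tf)
    stop("the first analysis must occur at least tf after trial start")
  if (cfg$t_end < cfg$e_max + cfg$tf)
    stop("'t_end' must allow full follow-up of the last enrollee")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': n_max = %d, enrollment over [0, %g], tf = %g\n",
              x$scenario, x$n_max, x$e_max, x$tf))
  cat(sprintf("  beta = %g; analyses at (%s), final at %g\n",
              x$beta, paste(x$analysis_times, collapse = ", "), x$t_end))
  invisible(x)
}

#' CDF of the latent uniform in the treated arm
#'
#' The ordinal/binary scenarios draw a latent `U(0,1)` variable and, in the
#' treated arm, transform it so that `logit pr(latent <= u | A = 1) =
#' logit(u) + beta`.  This is that treated-arm CDF,
#' `u e^{beta} / (1 - u + u e^{beta})`, in closed form; the generative
#' transform applied to the uniform draw is its inverse, which is the same
#' function evaluated at `-beta`.
#'
#' @param u evaluation point(s) in `[0, 1]`.
#' @param beta log odds ratio.
#' @return `pr(latent <= u | A = 1)`.
#' @export
latent_treated_cdf <- function(u, beta) {
  u * exp(beta) / (1 - u + u * exp(beta))
}

#' Category probabilities of the ordinal scenario
#'
#' Closed-form per-arm category probabilities implied by the latent
#' construction and the fixed cutpoints.
#'
#' @param beta log odds ratio.
#' @param arm 0 (control) or 1 (active).
#' @param config optional [scenario_config()] supplying the cutpoints.
#' @return numeric vector of 6 probabilities.
#' @export
ordinal_category_probs <- function(beta, arm = 0L, config = scenario_config("ordinal")) {
  cut <- config$cutpoints
  cdf <- if (arm == 1L) latent_treated_cdf(cut, beta) else cut
  diff(cdf)
}

#' True analysis-scale treatment effect of a scenario
#'
#' The effect the interim estimators target: the log odds ratio (`"ordinal"`),
#' the implied log relative risk of the worst category (`"binary"`), or the
#' week-52 mean difference (`"continuous"`).
#'
#' @param config a [scenario_config()].
#' @return scalar.
#' @export
scenario_effect <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  switch(config$scenario,
    ordinal = config$beta,
    binary = {
      p0 <- 1 - config$cutpoints[6L]                          # pr(latent >= 0.67 | A=0)
      p1 <- 1 - latent_treated_cdf(config$cutpoints[6L], config$beta)
      log(p1 / p0)
    },
    continuous = config$beta)
}

#' Outcome model matching a scenario
#'
#' @param config a [scenario_config()].
#' @return An [outcome_model()] (proportional odds with 6 categories, log
#'   relative risk, or difference of means).
#' @export
scenario_model <- function(config) {
  switch(config$scenario,
    ordinal = outcome_model("proportional_odds", n_categories = 6L),
    binary = outcome_model("log_relative_risk"),
    continuous = outcome_model("difference_of_means"))
}

# per-subject uniform draws in a fixed layout: row i holds subject i's draws,
# so the first subjects are unchanged when n_max grows (prefix stability)
subject_uniforms <- function(n, k) {
  matrix(stats::runif(n * k), nrow = n, ncol = k, byrow = TRUE)
}

#' Generate a synthetic trial
#'
#' Draws a complete trial (full data: entry times, arms, covariates, lag
#' times, outcomes, covariate paths) from the configured scenario.  Within a
#' scenario each subject consumes a fixed number of uniform draws, so with
#' the same seed the first subjects are identical across different `n_max`.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer seed (set before drawing when supplied).
#' @return A [full_trial_data()] object.
#' @export
generate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  switch(config$scenario,
    ordinal = generate_latent_scenario(config, ordinal = TRUE),
    binary = generate_latent_scenario(config, ordinal = FALSE),
    continuous = generate_continuous_scenario(config))
}

generate_latent_scenario <- function(config, ordinal) {
  n <- config$n_max
  tf <- config$tf
  U <- subject_uniforms(n, 5L)
  entry <- config$e_max * U[, 1L]
  arm <- as.integer(U[, 2L] < 0.5)
  ups <- U[, 3L]
  gam <- ifelse(arm == 1L, latent_treated_cdf(ups, -config$beta), ups)
  ycat <- findInterval(gam, config$cutpoints)        # 1..6
  death <- gam >= config$cutpoints[6L]
  lag <- rep(tf, n)
  lag[death] <- ifelse(arm[death] == 1L, 20 + 30 * U[death, 4L], 30 * U[death, 4L])
  x <- matrix(1.5 * (ups - 0.5) + stats::qnorm(U[, 5L]), ncol = 1L)
  hosp <- tf * gam / config$cutpoints[4L]            # time in hospital when gam < 0.52
  w <- ifelse(gam < config$cutpoints[4L], hosp, tf)  # discharge time W
  paths <- lapply(seq_len(n), function(i) {
    if (w[i] < lag[i]) {
      list(time = c(0, w[i]), value = cbind(l1 = c(0, 1), l2 = c(0, tf - w[i])))
    } else {
      list(time = 0, value = cbind(l1 = 0, l2 = 0))
    }
  })
  outcome <- if (ordinal) as.numeric(ycat) else as.numeric(death)
  full_trial_data(entry = entry, arm = arm, lag = lag, outcome = outcome,
                  tf = tf, x = x, paths = paths)
}

generate_continuous_scenario <- function(config) {
  n <- config$n_max
  s <- config$visit_weeks
  U <- subject_uniforms(n, 10L)
  entry <- config$e_max * U[, 1L]
  arm <- as.integer(U[, 2L] < 0.5)
  x1 <- findInterval(U[, 3L], cumsum(config$x1_probs), left.open = TRUE) + 1L
  Rt <- chol(config$D)                               # b = z %*% chol(D)
  b <- cbind(stats::qnorm(U[, 4L]), stats::qnorm(U[, 5L])) %*% Rt
  e <- stats::qnorm(U[, 6:10, drop = FALSE]) * config$sigma
  xi2 <- config$xi1 + config$beta / config$tf
  slope <- ifelse(arm == 1L, xi2, config$xi1)
  mu <- config$x1_means[x1]
  Z <- mu + outer(slope, s) + b[, 1L] + outer(b[, 2L], s) + e
  paths <- lapply(seq_len(n), function(i)
    list(time = s, value = cbind(l1 = Z[i, ])))
  full_trial_data(entry = entry, arm = arm, lag = rep(config$tf, n),
                  outcome = Z[, length(s)], tf = config$tf,
                  x = matrix(Z[, 1L], ncol = 1L), paths = paths)
}
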