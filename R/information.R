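#' Estimated variance of the full-data influence function
#'
#' Estimates `var{m(Y, A; alpha0, beta0)}` — the per-subject information
#' scale of the *full-data* analysis — from the interim data, by the
#' inverse-probability-weighted mean of the squared influence values
#' evaluated at the interim estimate.  For the augmented estimators the
#' influence values are first residualized on the baseline augmentation
#' columns by weighted least squares (the same formula serves AIPW1 and
#' AIPW2: only baseline columns enter).  This is the numerator of the
#' effective sample size.
#'
#' @param interim an [interim_data()] object.
#' @param fit a `gslag_fit` from [fit_ipwcc()] or [fit_aipwcc()].
#' @param cm the [censoring_km()] used by the fit (defaults to the stored
#'   one).
#' @return scalar variance estimate.
#' @export
influence_variance <- function(interim, fit, cm = NULL) {
  stopifnot(inherits(fit, "gslag_fit"))
  if (fit$kind == "tf") stop("influence_variance applies to the IPW/AIPW estimators")
  if (is.null(cm)) cm <- fit$cm
  n <- interim$n_enrolled
  cc <- which(interim$ascertained == 1L)
  # influence values at (alpha_hat, beta_hat): Step-1 G row reused
  theta <- fit$theta
  m_star <- numeric(n)
  m_star[cc] <- influence_values(fit$model, interim$outcome[cc], interim$arm[cc],
                                 theta, G = fit$G)
  w <- fit$weights
  if (fit$kind == "ipw") return(sum(w[cc] * m_star[cc]^2) / n)
  Xf <- augmentation_covariates(interim, fit$basis, cm, include_h = FALSE)
  sw <- sqrt(w[cc])
  qr_ <- qr(Xf[cc, , drop = FALSE] * sw)
  psi <- qr.coef(qr_, sw * m_star[cc])
  psi[is.na(psi)] <- 0
  pred_star <- as.numeric(Xf %*% psi)
  sum(w[cc] * (m_star[cc] - pred_star[cc])^2) / n
}

#' Effective sample size of an interim estimator
#'
#' The number of fully followed subjects whose complete-case analysis would
#' match the interim estimator's precision: the estimated full-data
#' influence-function variance divided by the squared interim standard
#' error.  Equals the enrolled count at a final analysis with everything
#' ascertained.
#'
#' @param var_m influence-function variance from [influence_variance()].
#' @param se interim standard error.
#' @return scalar.
#' @export
effective_sample_size <- function(var_m, se) {
  stopifnot(var_m > 0, se > 0)
  var_m / se^2
}

#' Proportion of statistical information at an interim analysis
#'
#' Under fixed-sample monitoring the fraction is `n_ESS(t) / n_max` for the
#' IPW/AIPW estimators and `n_A(t) / n_max` for the fully-followed-only
#' estimator; under information-based monitoring it is
#' `SE^{-2} / max_information`.  Fractions above 1 (possible from estimator
#' noise) are clipped with a warning.
#'
#' @param fit a `gslag_fit`.
#' @param n_max maximum (planned) sample size (fixed-sample mode).
#' @param interim the [interim_data()] the fit came from; required for the
#'   IPW/AIPW estimators in fixed-sample mode.
#' @param max_information target maximum information (information-based
#'   mode); if supplied, overrides fixed-sample mode.
#' @return An object of class `information_state`: list with `information`
#'   (`SE^{-2}`), `ess` (effective sample size, `NA` for the
#'   fully-followed-only estimator), `fraction`, and `mode`.
#' @export
information_fraction <- function(fit, n_max = NULL, interim = NULL,
                                 max_information = NULL) {
  stopifnot(inherits(fit, "gslag_fit"))
  inf_t <- fit$se^-2
  ess <- NA_real_
  if (!is.null(max_information)) {
    frac <- inf_t / max_information
    mode <- "information_based"
  } else {
    if (is.null(n_max)) stop("supply 'n_max' (fixed-sample) or 'max_information'")
    if (fit$kind == "tf") {
      frac <- fit$n_fully_followed / n_max
    } else {
      if (is.null(interim)) stop("'interim' is required for the IPW/AIPW fraction")
      ess <- effective_sample_size(influence_variance(interim, fit), fit$se)
      frac <- ess / n_max
    }
    mode <- "fixed_sample"
  }
  if (frac > 1) {
    warning("information fraction ", signif(frac, 4), " > 1; clipped to 1")
    frac <- 1
  }
  structure(list(information = inf_t, ess = ess, fraction = frac, mode = mode),
            class = "information_state")
}

#' @export
print.information_state <- function(x, ...) {
  cat(sprintf("Information %.4g (%s); fraction %.3f", x$information, x$mode, x$fraction))
  if (!is.na(x$ess)) cat(sprintf("; effective sample size %.1f", x$ess))
  cat("\n")
  invisible(x)
}

#' Maximum information for an information-monitored trial
#'
#' `MI = {(z_{alpha/2} + z_gamma) / beta_alt}^2 * inflation`: the information
#' needed for a two-sided level-`alpha` test to have power `1 - gamma`
#' against `beta_alt`, inflated for repeated testing (about 1.03 for
#' O'Brien-Fleming boundaries).
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param gamma type-II error (1 - power) in (0, 1).
#' @param beta_alt clinically meaningful treatment effect (nonzero).
#' @param inflation inflation factor `>= 1` (user input; 1 = none).
#' @return scalar maximum information.
#' @export
max_information <- function(alpha, gamma, beta_alt, inflation = 1) {
  stopifnot(alpha > 0, alpha < 1, gamma > 0, gamma < 1, inflation >= 1)
  if (beta_alt == 0) stop("'beta_alt' must be nonzero")
  ((stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - gamma)) / beta_alt)^2 * inflation
}
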