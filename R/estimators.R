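#' Basis functions for the augmentation terms
#'
#' The augmented estimators approximate the (unknown) optimal augmentation by
#' linear combinations of user-chosen basis functions: `f` functions of the
#' baseline covariates (a constant `f0 = 1` is always prepended internally)
#' and `h` functions of time, baseline covariates, and the current
#' time-dependent covariate value.
#'
#' @param f list of functions `f(x)` taking the baseline covariate matrix of
#'   the enrolled subjects and returning one value per subject.
#' @param h list of functions `h(u, x, l)` taking a time point, the baseline
#'   covariate matrix, and the matrix of time-dependent covariate values at
#'   `u` for the same subjects, returning one value per subject.  May be
#'   empty.
#' @return An object of class `basis_spec`.
#' @seealso [default_basis()]
#' @export
basis_spec <- function(f = list(), h = list()) {
  stopifnot(all(vapply(f, is.function, logical(1))),
            all(vapply(h, is.function, logical(1))))
  structure(list(f = f, h = h), class = "basis_spec")
}

#' Default augmentation basis: covariate components
#'
#' Uses each baseline covariate column as an `f` basis function and each
#' baseline plus each time-dependent covariate column as an `h` basis
#' function (the time-dependent value being the most recent one at `u`).
#'
#' @param interim an [interim_data()] object (used only to inspect covariate
#'   dimensions).
#' @return A [basis_spec()].
#' @export
default_basis <- function(interim) {
  px <- if (is.null(interim$x)) 0L else ncol(interim$x)
  f <- lapply(seq_len(px), function(j) {
    force(j); function(x) x[, j]
  })
  h <- lapply(seq_len(px), function(j) {
    force(j); function(u, x, l) x[, j]
  })
  ql <- 0L
  if (!is.null(interim$paths)) {
    nonnull <- which(!vapply(interim$paths, is.null, logical(1)))
    if (length(nonnull)) ql <- ncol(interim$paths[[nonnull[1L]]]$value)
  }
  hl <- lapply(seq_len(ql), function(q) {
    force(q); function(u, x, l) l[, q]
  })
  basis_spec(f = f, h = c(h, hl))
}

new_gslag_fit <- function(kind, model, interim, theta, beta, se, extra = list()) {
  out <- c(list(kind = kind, model = model, t = interim$t,
                theta = theta, beta = beta, se = se, wald = beta / se,
                n_enrolled = interim$n_enrolled,
                n_fully_followed = interim$n_fully_followed,
                pi_t = interim$pi_t),
           extra)
  class(out) <- "gslag_fit"
  out
}

#' @export
print.gslag_fit <- function(x, ...) {
  lab <- c(tf = "fully-followed-only", ipw = "IPWCC",
           aipw1 = "AIPWCC (baseline)", aipw2 = "AIPWCC (baseline + time-dependent)")
  cat(sprintf("%s estimate at t = %g\n", lab[[x$kind]], x$t))
  cat(sprintf("  beta = %.4f  SE = %.4f  Wald = %.3f\n", x$beta, x$se, x$wald))
  cat(sprintf("  n(t) = %d enrolled, nA(t) = %d fully followed\n",
              x$n_enrolled, x$n_fully_followed))
  invisible(x)
}

#' Wald statistic of an interim treatment-effect estimate
#'
#' @param fit a fit from [fit_tf_only()], [fit_ipwcc()], or [fit_aipwcc()].
#' @return `beta / se`.
#' @export
wald_statistic <- function(fit) {
  stopifnot(inherits(fit, "gslag_fit"))
  fit$beta / fit$se
}

#' Interim estimate using only fully followed subjects
#'
#' The conventional interim analysis: the full-data estimator applied to the
#' subjects who have been enrolled for at least the maximum follow-up `tf`,
#' so whose outcome is ascertained with certainty.  The standard error comes
#' from the empirical variance of the estimated influence function over those
#' subjects.
#'
#' @param interim an [interim_data()] object.
#' @param model an [outcome_model()].
#' @return A `gslag_fit` (kind `"tf"`).
#' @export
fit_tf_only <- function(interim, model) {
  stopifnot(inherits(interim, "interim_data"))
  full <- which(interim$cens_time >= interim$tf)
  if (sum(interim$arm[full] == 0L) < 2L || sum(interim$arm[full] == 1L) < 2L)
    stop("analysis too early: fewer than 2 fully followed subjects in an arm")
  y <- interim$outcome[full]
  a <- interim$arm[full]
  nA <- length(full)
  sol <- solve_estimating_equation(model, y, a)
  m <- influence_values(model, y, a, sol$theta, n_norm = nA)
  se <- sqrt(sum(m^2)) / nA
  new_gslag_fit("tf", model, interim, sol$theta, sol$beta, se,
                extra = list(m = m, subset = full, n_used = nA))
}

# per-jump tail sums: for each jump time, sum of `vals` over complete cases
# with U >= jump (ascertainment-first tie convention keeps U == jump in)
tail_sums <- function(u_cc, vals, jump_times) {
  if (length(jump_times) == 0L) return(numeric(0))
  o <- order(u_cc)
  cs <- cumsum(vals[o])
  tot <- if (length(cs)) cs[length(cs)] else 0
  idx <- findInterval(jump_times, u_cc[o], left.open = TRUE)  # # of U < jump
  tot - ifelse(idx > 0L, cs[pmax(idx, 1L)], 0)
}

# mu_hat(m, u, a)/K_hat(u, a): at-risk average (in arm a) of the
# inverse-weighted influence values, at that arm's censoring jump times
mu_m_over_k <- function(cm, group, u_cc_arm, wm_cc_arm) {
  jumps <- censoring_jumps(cm, group)
  if (length(jumps$time) == 0L) return(numeric(0))
  tail_sums(u_cc_arm, wm_cc_arm, jumps$time) / jumps$n_risk
}

#' Inverse probability weighted complete-case (IPWCC) interim estimate
#'
#' Step 1 of the two-step interim algorithm: solves the estimating equations
#' over the complete cases at `t`, each weighted by the inverse of the
#' (arm-specific) Kaplan-Meier censoring survival at its observed time.  The
#' weighting removes the over-representation of short-lag outcomes among the
#' complete cases.  The standard error uses the full interim influence
#' function (inverse-weighted term plus censoring-martingale term).
#'
#' @param interim an [interim_data()] object.
#' @param model an [outcome_model()].
#' @param cm optional [censoring_km()] fit on the same interim data
#'   (arm-specific by default).
#' @return A `gslag_fit` (kind `"ipw"`) additionally carrying the
#'   complete-case weights, influence values `m`, the per-subject dependent
#'   variable `yhat`, and the Step-1 `G` row, for reuse by [fit_aipwcc()].
#' @export
fit_ipwcc <- function(interim, model, cm = NULL) {
  stopifnot(inherits(interim, "interim_data"))
  if (is.null(cm)) cm <- censoring_km(interim)
  n <- interim$n_enrolled
  d <- interim$ascertained
  a <- interim$arm
  cc <- which(d == 1L)
  K <- numeric(n)
  for (g in c(0L, 1L)) {
    sel <- cc[a[cc] == g]
    K[sel] <- km_survival(cm, interim$obs_time[sel], group = g)
  }
  w <- numeric(n)
  w[cc] <- 1 / K[cc]
  sol <- solve_estimating_equation(model, interim$outcome[cc], a[cc], weights = w[cc])
  G <- g_row(model, interim$outcome[cc], a[cc], sol$theta, weights = w[cc], n_norm = n)
  m <- numeric(n)
  m[cc] <- influence_values(model, interim$outcome[cc], a[cc], sol$theta, G = G)
  yhat <- dependent_variable_internal(interim, cm, m, w)
  se <- sqrt(sum(yhat^2)) / n
  new_gslag_fit("ipw", model, interim, sol$theta, sol$beta, se,
                extra = list(m = m, weights = w, yhat = yhat, G = G, cm = cm))
}

dependent_variable_internal <- function(interim, cm, m, w) {
  n <- interim$n_enrolled
  a <- interim$arm
  yhat <- w * m
  for (g in c(0L, 1L)) {
    idx <- which(a == g)
    cc_arm <- idx[interim$ascertained[idx] == 1L]
    q <- mu_m_over_k(cm, g, interim$obs_time[cc_arm], (w * m)[cc_arm])
    yhat[idx] <- yhat[idx] + mart_integral_arm(cm, idx, g, q)
  }
  yhat
}

#' Per-subject dependent variable of the augmentation regression
#'
#' The interim influence-function estimate for each enrolled subject: the
#' inverse-weighted influence value for complete cases plus the
#' censoring-martingale integral of the at-risk average of those weighted
#' values.  Its mean over enrolled subjects is zero at the Step-1 solution.
#'
#' @param interim an [interim_data()] object.
#' @param fit an IPWCC fit from [fit_ipwcc()].
#' @param cm the [censoring_km()] used by `fit` (defaults to the one stored
#'   in it).
#' @return numeric vector over enrolled subjects.
#' @export
dependent_variable <- function(interim, fit, cm = NULL) {
  stopifnot(inherits(fit, "gslag_fit"), fit$kind == "ipw")
  if (is.null(cm)) cm <- fit$cm
  dependent_variable_internal(interim, cm, fit$m, fit$weights)
}

# evaluate the h bases for the subjects in `idx` at each jump time of `group`;
# returns list of n_idx x J matrices, one per h basis
h_value_matrices <- function(interim, basis, cm, idx, group) {
  jumps <- censoring_jumps(cm, group)
  J <- length(jumps$time)
  x <- if (is.null(interim$x)) matrix(numeric(0), length(idx), 0L)
       else interim$x[idx, , drop = FALSE]
  nh <- length(basis$h)
  if (J == 0L || nh == 0L)
    return(rep(list(matrix(0, length(idx), J)), nh))
  ql <- 0L
  if (!is.null(interim$paths)) {
    nonnull <- which(!vapply(interim$paths, is.null, logical(1)))
    if (length(nonnull)) ql <- ncol(interim$paths[[nonnull[1L]]]$value)
  }
  lv <- vector("list", ql)   # per covariate column: n_idx x J matrix of values
  if (ql > 0L) {
    for (q in seq_len(ql)) lv[[q]] <- matrix(0, length(idx), J)
    for (r in seq_along(idx)) {
      p <- interim$paths[[idx[r]]]
      if (is.null(p)) next
      vals <- p$value[findInterval(jumps$time, p$time), , drop = FALSE]
      for (q in seq_len(ql)) lv[[q]][r, ] <- vals[, q]
    }
  }
  lapply(basis$h, function(hf) {
    out <- matrix(0, length(idx), J)
    for (j in seq_len(J)) {
      lmat <- if (ql > 0L) do.call(cbind, lapply(lv, function(mq) mq[, j]))
              else matrix(numeric(0), length(idx), 0L)
      v <- hf(jumps$time[j], x, lmat)
      if (any(!is.finite(v))) stop("h basis function not finite at a required time")
      out[, j] <- v
    }
    out
  })
}

#' Augmentation covariates for the interim regression
#'
#' Builds the design matrix of the Step-2 regression: columns
#' `(A_i - pi_t) f_m(X_i)` for each baseline basis function (including the
#' constant `f0 = 1`), followed by, for each arm and each `h` basis function,
#' the censoring-martingale integral of the at-risk-centered basis values
#' (zero for subjects in the other arm).  With no censoring events all
#' martingale columns vanish.
#'
#' @param interim an [interim_data()] object.
#' @param basis a [basis_spec()].
#' @param cm a [censoring_km()] object.
#' @param include_h logical; include the time-dependent (martingale) columns.
#' @return numeric matrix with `n_enrolled` rows.
#' @export
augmentation_covariates <- function(interim, basis, cm, include_h = TRUE) {
  n <- interim$n_enrolled
  a <- interim$arm
  ctr <- a - interim$pi_t
  xmat <- if (is.null(interim$x)) matrix(numeric(0), n, 0L) else interim$x
  fb <- cbind(f0 = ctr)
  for (j in seq_along(basis$f)) {
    v <- basis$f[[j]](xmat)
    if (any(!is.finite(v))) stop("f basis function not finite on the data")
    fb <- cbind(fb, ctr * v)
  }
  colnames(fb) <- paste0("f", seq_len(ncol(fb)) - 1L)
  if (!include_h || length(basis$h) == 0L) return(fb)
  hcols <- NULL
  for (g in c(0L, 1L)) {
    idx <- which(a == g)
    hmats <- h_value_matrices(interim, basis, cm, idx, g)
    jumps <- censoring_jumps(cm, g)
    for (l in seq_along(hmats)) {
      col <- numeric(n)
      if (length(jumps$time)) {
        mu_h <- colSums(hmats[[l]] * outer(interim$obs_time[idx], jumps$time, ">=")) /
          jumps$n_risk
        centered <- sweep(hmats[[l]], 2L, mu_h)
        col[idx] <- mart_integral_arm(cm, idx, g, centered)
      }
      hcols <- cbind(hcols, col)
      colnames(hcols)[ncol(hcols)] <- sprintf("h%d_arm%d", l, g)
    }
  }
  cbind(fb, hcols)
}

#' Augmented IPWCC (AIPWCC) interim estimate
#'
#' Step 2 of the two-step interim algorithm: regresses the per-subject
#' dependent variable from Step 1 on the augmentation covariates by ordinary
#' least squares and applies the one-step update
#' `beta = beta_init - mean(Pred)`, with standard error from the residuals.
#' `include_h = FALSE` gives the baseline-only estimator (AIPW1);
#' `include_h = TRUE` additionally uses time-dependent covariate information
#' through the censoring-martingale columns (AIPW2).  At a final analysis
#' with all outcomes ascertained the two coincide.
#'
#' @param interim an [interim_data()] object.
#' @param model an [outcome_model()].
#' @param basis a [basis_spec()]; defaults to [default_basis()].
#' @param cm optional [censoring_km()].
#' @param include_h include time-dependent martingale columns (AIPW2)?
#' @param ipw optional precomputed [fit_ipwcc()] on the same data, to avoid
#'   refitting Step 1.
#' @return A `gslag_fit` (kind `"aipw1"` or `"aipw2"`) carrying also
#'   `beta_init`, the regression coefficients `psi`, fitted values `pred`,
#'   and the Step-1 influence pieces.
#' @export
fit_aipwcc <- function(interim, model, basis = NULL, cm = NULL,
                       include_h = TRUE, ipw = NULL) {
  if (is.null(ipw)) {
    if (is.null(cm)) cm <- censoring_km(interim)
    ipw <- fit_ipwcc(interim, model, cm)
  } else {
    if (is.null(cm)) cm <- ipw$cm
  }
  if (is.null(basis)) basis <- default_basis(interim)
  Xa <- augmentation_covariates(interim, basis, cm, include_h = include_h)
  yhat <- ipw$yhat
  # all-zero martingale columns (no censoring events) carry no information
  nonzero <- colSums(abs(Xa)) > 0
  Xr <- Xa[, nonzero, drop = FALSE]
  qr_ <- qr(Xr)
  if (qr_$rank < ncol(Xr))
    warning("collinear augmentation columns dropped (rank ", qr_$rank,
            " of ", ncol(Xr), ")")
  psi <- stats::setNames(numeric(ncol(Xa)), colnames(Xa))
  psi_r <- qr.coef(qr_, yhat)
  psi_r[is.na(psi_r)] <- 0
  psi[nonzero] <- psi_r
  pred <- as.numeric(Xa %*% psi)
  n <- interim$n_enrolled
  beta <- ipw$beta - mean(pred)
  se <- sqrt(sum((yhat - pred)^2)) / n
  theta <- ipw$theta
  theta[length(theta)] <- beta
  new_gslag_fit(if (include_h) "aipw2" else "aipw1", model, interim, theta, beta, se,
                extra = list(beta_init = ipw$beta, psi = psi, pred = pred,
                             yhat = yhat, m = ipw$m, weights = ipw$weights,
                             G = ipw$G, cm = cm, basis = basis,
                             n_f_columns = length(basis$f) + 1L))
}

#' Fit any of the interim treatment-effect estimators
#'
#' Convenience dispatcher over [fit_tf_only()], [fit_ipwcc()], and
#' [fit_aipwcc()].
#'
#' @param interim an [interim_data()] object.
#' @param model an [outcome_model()].
#' @param estimator one of `"tf"`, `"ipw"`, `"aipw1"`, `"aipw2"`.
#' @param basis optional [basis_spec()] for the augmented estimators.
#' @param cm optional [censoring_km()].
#' @return A `gslag_fit`.
#' @export
fit_interim <- function(interim, model,
                        estimator = c("tf", "ipw", "aipw1", "aipw2"),
                        basis = NULL, cm = NULL) {
  estimator <- match.arg(estimator)
  switch(estimator,
         tf = fit_tf_only(interim, model),
         ipw = fit_ipwcc(interim, model, cm),
         aipw1 = fit_aipwcc(interim, model, basis, cm, include_h = FALSE),
         aipw2 = fit_aipwcc(interim, model, basis, cm, include_h = TRUE))
}
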