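#' Specify the treatment-effect model and its estimating function
#'
#' The treatment effect is the last element `beta` of the parameter vector
#' `theta = (alpha, beta)` in one of three marginal models:
#' * `"difference_of_means"`: `E(Y | A = a) = alpha + beta a` (continuous Y);
#' * `"log_relative_risk"`: `E(Y | A = a) = exp(alpha + beta a)` (binary Y);
#' * `"proportional_odds"`: `logit pr(Y <= j | A = a) = alpha_j + beta a`,
#'   `j = 1..c-1` (ordinal Y in `1..c`).  Note the cumulative-indicator
#'   parameterization: `beta > 0` shifts probability toward *lower* (more
#'   favorable, in the motivating trials) categories; sign conventions differ
#'   across software.
#'
#' For the proportional-odds model the estimating function is the generalized
#' score `D' V^{-1} {I(Y <= j) - expit(alpha_j + beta A)}`.  With the default
#' working-independence variance (`variance = "independence"`) this reduces to
#' the simple form `(r_1, ..., r_{c-1}, A * sum_j r_j)`; `variance = "full"`
#' uses the true multinomial covariance of the cumulative indicators and
#' reproduces the maximum-likelihood estimator (used mainly as a cross-check).
#'
#' @param kind model kind; see above.
#' @param n_categories number of ordinal categories `c >= 2`
#'   (proportional-odds only).
#' @param variance `"independence"` (default) or `"full"`
#'   (proportional-odds only).
#' @return An object of class `outcome_model` with `p` the parameter
#'   dimension (2, 2, or `c`).
#' @export
outcome_model <- function(kind = c("difference_of_means", "log_relative_risk",
                                   "proportional_odds"),
                          n_categories = NULL,
                          variance = c("independence", "full")) {
  kind <- match.arg(kind)
  variance <- match.arg(variance)
  if (kind == "proportional_odds") {
    if (is.null(n_categories) || n_categories < 2)
      stop("'n_categories' (>= 2) is required for the proportional-odds model")
    p <- as.integer(n_categories)
  } else {
    n_categories <- NULL
    p <- 2L
  }
  structure(list(kind = kind, n_categories = n_categories, p = p,
                 variance = variance),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("Outcome model: %s (p = %d%s)\n", x$kind, x$p,
              if (x$kind == "proportional_odds")
                paste0(", c = ", x$n_categories, ", ", x$variance, " variance")
              else ""))
  invisible(x)
}

expit <- function(x) 1 / (1 + exp(-x))

check_theta <- function(model, theta) {
  if (length(theta) != model$p) stop("parameter vector must have length ", model$p)
  if (any(!is.finite(theta))) stop("non-finite parameters")
  theta
}

#' Evaluate the estimating function for each subject
#'
#' Returns the `n x p` matrix whose rows are the per-subject estimating
#' function values `M(Y_i, A_i; theta)`; the (possibly weighted) column sums
#' are the estimating equations solved by [solve_estimating_equation()].
#'
#' @param model an [outcome_model()].
#' @param y outcome vector.
#' @param a treatment indicator vector (0/1).
#' @param theta parameter vector `(alpha, beta)` of length `model$p`.
#' @return numeric matrix `length(y) x model$p`.
#' @export
estimating_function <- function(model, y, a, theta) {
  check_theta(model, theta)
  switch(model$kind,
    difference_of_means = {
      r <- y - theta[1L] - theta[2L] * a
      cbind(r, a * r, deparse.level = 0)
    },
    log_relative_risk = {
      if (any(y < 0)) stop("outcome out of range for the log-relative-risk model")
      r <- y - exp(theta[1L] + theta[2L] * a)
      cbind(r, a * r, deparse.level = 0)
    },
    proportional_odds = po_estfun(model, y, a, theta))
}

po_cum_resid <- function(model, y, a, theta) {
  cm1 <- model$n_categories - 1L
  if (any(y < 1 | y > model$n_categories | y != round(y)))
    stop("outcome out of range for the proportional-odds model")
  alpha <- theta[seq_len(cm1)]
  beta <- theta[model$p]
  eta <- outer(a * beta, alpha, "+")          # n x (c-1), eta_ij = alpha_j + beta a_i
  p <- expit(eta)
  ind <- outer(y, seq_len(cm1), "<=") + 0     # I(Y_i <= j)
  list(r = ind - p, p = p, dp = p * (1 - p))
}

po_estfun <- function(model, y, a, theta) {
  z <- po_cum_resid(model, y, a, theta)
  if (model$variance == "independence") {
    # D' V_ind^{-1} r collapses to (r_1..r_{c-1}, A sum_j r_j)
    cbind(z$r, a * rowSums(z$r), deparse.level = 0)
  } else {
    cm1 <- model$n_categories - 1L
    out <- matrix(0, length(y), model$p)
    for (lev in c(0, 1)) {
      idx <- which(a == lev)
      if (!length(idx)) next
      pj <- z$p[idx[1L], ]
      dpj <- z$dp[idx[1L], ]
      V <- outer(seq_len(cm1), seq_len(cm1),
                 function(j, k) pj[pmin(j, k)] * (1 - pj[pmax(j, k)]))
      D <- cbind(diag(dpj, nrow = cm1), dpj * lev)  # (c-1) x c gradient of the mean
      DtVinv <- t(D) %*% solve(V)
      out[idx, ] <- z$r[idx, , drop = FALSE] %*% t(DtVinv)
    }
    out
  }
}

#' Weighted average Jacobian of the estimating function
#'
#' Computes `n_norm^{-1} sum_i w_i dM(Y_i, A_i; theta)/dtheta'` analytically.
#'
#' @inheritParams estimating_function
#' @param weights nonnegative subject weights.
#' @param n_norm normalizing count (defaults to `length(y)`); at an interim
#'   analysis the paper normalizes by the number enrolled, not the number of
#'   complete cases.
#' @return `p x p` matrix.
#' @export
model_jacobian <- function(model, y, a, theta, weights = NULL, n_norm = length(y)) {
  check_theta(model, theta)
  n <- length(y)
  w <- if (is.null(weights)) rep(1, n) else weights
  switch(model$kind,
    difference_of_means = {
      sw <- sum(w); swa <- sum(w * a)
      -matrix(c(sw, swa, swa, swa), 2L, 2L) / n_norm
    },
    log_relative_risk = {
      mu <- exp(theta[1L] + theta[2L] * a)
      s0 <- sum(w * mu); s1 <- sum(w * a * mu)
      -matrix(c(s0, s1, s1, s1), 2L, 2L) / n_norm
    },
    proportional_odds = po_jacobian(model, y, a, theta, w, n_norm))
}

po_jacobian <- function(model, y, a, theta, w, n_norm) {
  cm1 <- model$n_categories - 1L
  z <- po_cum_resid(model, y, a, theta)
  if (model$variance == "independence") {
    # rows 1..c-1: d r_k / d alpha_l = -dp_k delta_kl ; d r_k / d beta = -dp_k a
    # row c: -a dp_l ; -a sum dp
    J <- matrix(0, model$p, model$p)
    wd <- w * z$dp                         # n x (c-1) scaled
    J[cbind(seq_len(cm1), seq_len(cm1))] <- -colSums(wd)
    J[seq_len(cm1), model$p] <- -colSums(a * wd)
    J[model$p, seq_len(cm1)] <- -colSums(a * wd)
    J[model$p, model$p] <- -sum(a * rowSums(wd))
    J / n_norm
  } else {
    numeric_jacobian(function(th) {
      colSums(w * po_estfun(model, y, a, th)) / n_norm
    }, theta)
  }
}

#' Central-difference Jacobian of a vector-valued function
#'
#' Utility used as the fallback when an analytic Jacobian is unavailable and
#' as an independent cross-check in tests; step `1e-6 * max(1, |theta|)` per
#' coordinate.
#'
#' @param fn function of the parameter vector returning a numeric vector.
#' @param theta evaluation point.
#' @return Jacobian matrix `length(fn(theta)) x length(theta)`.
#' @export
numeric_jacobian <- function(fn, theta) {
  p <- length(theta)
  f0 <- fn(theta)
  J <- matrix(0, length(f0), p)
  for (k in seq_len(p)) {
    hk <- 1e-6 * max(1, abs(theta[k]))
    up <- theta; up[k] <- up[k] + hk
    dn <- theta; dn[k] <- dn[k] - hk
    J[, k] <- (fn(up) - fn(dn)) / (2 * hk)
  }
  J
}

#' Last row of the inverted negative weighted Jacobian
#'
#' The influence function of the treatment-effect estimator is
#' `m_i = G M(Y_i, A_i; theta)` where `G` is the last row of the inverse of
#' the negated (weighted, normalized) Jacobian of the estimating function.
#'
#' @inheritParams model_jacobian
#' @return numeric vector of length `model$p`.
#' @export
g_row <- function(model, y, a, theta, weights = NULL, n_norm = length(y)) {
  J <- model_jacobian(model, y, a, theta, weights, n_norm)
  Ji <- tryCatch(solve(-J), error = function(e) {
    sv <- svd(-J)
    bad <- which(sv$d < max(sv$d) * 1e-10)
    stop("singular weighted Jacobian; deficient direction(s): ",
         paste(apply(round(sv$v[, bad, drop = FALSE], 3), 2L, paste, collapse = ","),
               collapse = " | "))
  })
  Ji[model$p, ]
}

#' Influence-function values of the treatment-effect estimator
#'
#' Convenience wrapper returning `m_i = G M_i` for every subject.
#'
#' @inheritParams model_jacobian
#' @param G optional precomputed row from [g_row()].
#' @return numeric vector of per-subject influence contributions.
#' @export
influence_values <- function(model, y, a, theta, weights = NULL,
                             n_norm = length(y), G = NULL) {
  if (is.null(G)) G <- g_row(model, y, a, theta, weights, n_norm)
  as.numeric(estimating_function(model, y, a, theta) %*% G)
}

#' Solve the (weighted) estimating equations
#'
#' Finds `theta = (alpha, beta)` with `sum_i w_i M(Y_i, A_i; theta) = 0`.
#' The two 2-parameter models are solved in closed form; the
#' proportional-odds model by Newton iteration with analytic Jacobian,
#' step-halving, and a numeric-Jacobian fallback.
#'
#' @inheritParams estimating_function
#' @param weights positive subject weights (default all 1).
#' @param init optional starting value; by default `alpha` comes from pooled
#'   weighted cumulative logits (ordinal) or the control-arm (log-)mean, and
#'   `beta` from 0.
#' @param tol convergence tolerance on the sup-norm of the equations,
#'   relative to the sample size.
#' @param max_iter maximum Newton iterations.
#' @return list with `theta`, `alpha`, `beta`, `iterations`, `converged`.
#' @export
solve_estimating_equation <- function(model, y, a, weights = NULL, init = NULL,
                                      tol = 1e-9, max_iter = 100L) {
  n <- length(y)
  w <- if (is.null(weights)) rep(1, n) else weights
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w[a == 1L] > 0) == 0L || sum(w[a == 0L] > 0) == 0L)
    stop("both arms must be represented (with positive weight) among complete cases")
  out <- switch(model$kind,
    difference_of_means = {
      m1 <- sum(w * a * y) / sum(w * a)
      m0 <- sum(w * (1 - a) * y) / sum(w * (1 - a))
      list(theta = c(m0, m1 - m0), iterations = 0L, converged = TRUE)
    },
    log_relative_risk = {
      m1 <- sum(w * a * y) / sum(w * a)
      m0 <- sum(w * (1 - a) * y) / sum(w * (1 - a))
      if (m0 <= 0 || m1 <= 0)
        stop("a weighted arm mean is zero; the log relative risk is not estimable ",
             "(try a later analysis time)")
      list(theta = c(log(m0), log(m1) - log(m0)), iterations = 0L, converged = TRUE)
    },
    proportional_odds = po_newton(model, y, a, w, init, tol, max_iter))
  names(out$theta) <- c(paste0("alpha", seq_len(model$p - 1L)), "beta")
  out$alpha <- out$theta[-model$p]
  out$beta <- unname(out$theta[model$p])
  out
}

po_newton <- function(model, y, a, w, init, tol, max_iter) {
  cm1 <- model$n_categories - 1L
  if (is.null(init)) {
    cum <- vapply(seq_len(cm1), function(j) sum(w * (y <= j)) / sum(w), numeric(1))
    cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
    init <- c(stats::qlogis(cummax(cum + seq_len(cm1) * 1e-10)), 0)
  }
  theta <- init
  scale <- sum(w)
  eqn <- function(th) colSums(w * po_estfun(model, y, a, th))
  g <- eqn(theta)
  iter <- 0L
  while (max(abs(g)) > tol * scale && iter < max_iter) {
    iter <- iter + 1L
    J <- po_jacobian(model, y, a, theta, w, 1)
    step <- tryCatch(solve(J, -g),
                     error = function(e) solve(numeric_jacobian(eqn, theta), -g))
    lam <- 1
    repeat {
      cand <- theta + lam * step
      gc_ <- tryCatch(eqn(cand), error = function(e) rep(Inf, length(g)))
      if (all(is.finite(gc_)) && max(abs(gc_)) < max(abs(g))) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- theta + step; gc_ <- eqn(cand); break }
    }
    theta <- cand
    g <- gc_
  }
  if (max(abs(g)) > tol * scale)
    stop("estimating-equation solver did not converge (possible separation); ",
         "consider a later analysis time")
  fits <- expit(outer(a * theta[model$p], theta[seq_len(cm1)], "+"))
  if (any(fits[w > 0, ] > 1 - 1e-12) || any(fits[w > 0, ] < 1e-12))
    stop("fitted cumulative probabilities pinned at 0/1 (separation); ",
         "consider a later analysis time")
  list(theta = theta, iterations = iter, converged = TRUE)
}
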