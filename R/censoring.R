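#' Kaplan-Meier model for the censoring distribution at an interim analysis
#'
#' At an interim analysis at calendar time `t`, the censoring time of an
#' enrolled subject is `C(t) = t - E`, and an observation with ascertainment
#' indicator `D(t) = 0` is a censoring *event* for the censoring distribution
#' `K_t(u) = pr{C(t) >= u | E <= t}` (subjects with `D(t) = 1` are the
#' censored observations of that reversed problem).  This function fits the
#' product-limit estimator of `K_t`, by default separately per arm; using
#' arm-specific weights is never harmful and is the recommended default even
#' though randomization makes the true censoring distribution arm-free.
#'
#' Conventions (important for real data with ties):
#' * `K_t(u)` estimates `pr{C >= u}`, so evaluation at a point `u` includes
#'   only product factors from event times strictly before `u`
#'   (left-continuous evaluation of the right-continuous KM curve).
#' * When an ascertainment (`D = 1`) and a censoring event share the same
#'   observed time, the ascertainment is treated as occurring first, so the
#'   complete case remains in the censoring risk set.
#' * The cumulative hazard accessor reports `-log K_t(u)`.  The discrete
#'   hazard increments used for martingale integrals are, by default, the
#'   product-limit-consistent (Nelson-Aalen) increments `d_j / Y_j`, under
#'   which estimated censoring-martingale sums are exactly zero;
#'   `hazard = "neglog-km"` instead uses differences of `-log K_t` across
#'   jumps, `-log(1 - d_j / Y_j)`.  The two are asymptotically equivalent.
#'
#' @param interim an [interim_data()] object.
#' @param arm_specific logical; fit per arm (default) or pooled.
#' @param hazard `"nelson-aalen"` (default) or `"neglog-km"`; see Details.
#' @return An object of class `censoring_km` carrying, per arm (or pooled):
#'   jump (censoring-event) times, at-risk counts, event counts, the survival
#'   value just after each jump, and hazard increments.  The object also keeps
#'   the subject-level `(U, D, A)` so martingale integrals can be formed.
#' @export
censoring_km <- function(interim, arm_specific = TRUE,
                         hazard = c("nelson-aalen", "neglog-km")) {
  stopifnot(inherits(interim, "interim_data"))
  hazard <- match.arg(hazard)
  u <- interim$obs_time
  d <- interim$ascertained
  a <- interim$arm
  groups <- if (arm_specific) list("0" = which(a == 0L), "1" = which(a == 1L))
            else list(pooled = seq_along(u))
  arms <- lapply(groups, function(idx) {
    if (length(idx) == 0L) stop("cannot fit censoring model: empty arm")
    km_censoring_curve(u[idx], d[idx])
  })
  cm <- structure(
    list(arm_specific = arm_specific, hazard = hazard, arms = arms,
         obs_time = u, ascertained = d, arm = a, t = interim$t),
    class = "censoring_km")
  # weights downstream are 1/K(U_i) for complete cases; K must stay positive there
  for (g in names(groups)) {
    idx <- groups[[g]]
    cc <- idx[d[idx] == 1L]
    if (length(cc) && any(km_survival(cm, u[cc], group = g) <= 0))
      stop("estimated censoring survival is zero at an ascertained observation time; ",
           "the analysis time is too early for inverse weighting")
  }
  cm
}

# product-limit curve where events are the D = 0 observations
km_censoring_curve <- function(u, d) {
  ev <- sort(unique(u[d == 0L]))
  if (length(ev) == 0L) {
    return(list(jump_times = numeric(0), n_risk = integer(0), n_event = integer(0),
                surv_after = numeric(0), cumprod_log = numeric(0)))
  }
  # at-risk uses U >= u; ties with ascertainments keep the complete case at risk
  n_risk <- vapply(ev, function(s) sum(u >= s), integer(1))
  n_event <- vapply(ev, function(s) sum(u == s & d == 0L), integer(1))
  frac <- 1 - n_event / n_risk
  list(jump_times = ev, n_risk = n_risk, n_event = n_event,
       surv_after = cumprod(frac), cumprod_log = cumsum(log(frac)))
}

arm_curve <- function(cm, group) {
  g <- as.character(group)
  if (!cm$arm_specific) g <- "pooled"
  cm$arms[[g]]
}

#' Evaluate the censoring survival estimate
#'
#' Returns `K_t(u) = pr{C(t) >= u}`: only jumps strictly before `u` enter the
#' product.
#'
#' @param cm a [censoring_km()] object.
#' @param u numeric vector of evaluation times.
#' @param group arm, `0` or `1` (ignored for a pooled fit).
#' @return numeric vector of survival probabilities.
#' @export
km_survival <- function(cm, u, group = 0L) {
  crv <- arm_curve(cm, group)
  if (length(crv$jump_times) == 0L) return(rep(1, length(u)))
  idx <- findInterval(u, crv$jump_times, left.open = TRUE)  # jumps < u
  out <- rep(1, length(u))
  pos <- idx > 0L
  out[pos] <- exp(crv$cumprod_log[idx[pos]])
  out
}

#' Cumulative censoring hazard, `-log K_t(u)`
#'
#' @inheritParams km_survival
#' @return numeric vector; `Inf` where the survival estimate is zero.
#' @export
km_cum_hazard <- function(cm, u, group = 0L) {
  -log(km_survival(cm, u, group))
}

#' Censoring-event jump times and hazard increments for one arm
#'
#' @inheritParams km_survival
#' @return A list with `time`, `n_risk`, `n_event` and `increment` (discrete
#'   hazard increments under the convention chosen in [censoring_km()]).
#' @export
censoring_jumps <- function(cm, group = 0L) {
  crv <- arm_curve(cm, group)
  inc <- if (cm$hazard == "nelson-aalen") crv$n_event / crv$n_risk
         else -log(1 - crv$n_event / crv$n_risk)
  list(time = crv$jump_times, n_risk = crv$n_risk, n_event = crv$n_event,
       increment = inc)
}

#' @export
print.censoring_km <- function(x, ...) {
  cat(sprintf("Censoring Kaplan-Meier at t = %g (%s, %s hazard increments)\n",
              x$t, if (x$arm_specific) "arm-specific" else "pooled", x$hazard))
  for (g in names(x$arms)) {
    crv <- x$arms[[g]]
    cat(sprintf("  %s: %d censoring events over %d observations\n",
                if (g == "pooled") "pooled" else paste("arm", g),
                sum(crv$n_event), sum(x$arm == as.integer(g) | !x$arm_specific)))
  }
  invisible(x)
}

#' Censoring-martingale integral for one subject
#'
#' Computes `int_0^t dMhat_i(u) g(u)` where `dMhat_i(u) = dN_i(u) -
#' dLambda_hat(u) Y_i(u)` is the estimated censoring martingale increment of
#' subject `i` in its own arm: the result is `(1 - D_i) g(U_i) - sum_{u_j <=
#' U_i} dLambda_hat(u_j) g(u_j)`, a finite sum over the arm's censoring jump
#' times.
#'
#' @param subject index of the subject within the interim data used to fit
#'   `cm`.
#' @param cm a [censoring_km()] object.
#' @param integrand a function of time `u` returning a numeric vector (of
#'   fixed length).
#' @return numeric vector, the integral.
#' @export
martingale_integral <- function(subject, cm, integrand) {
  stopifnot(inherits(cm, "censoring_km"))
  ui <- cm$obs_time[subject]
  di <- cm$ascertained[subject]
  jumps <- censoring_jumps(cm, cm$arm[subject])
  probe <- as.numeric(integrand(ui))
  if (any(!is.finite(probe))) stop("integrand not evaluable at the subject's observed time")
  out <- if (di == 0L) probe else numeric(length(probe))
  k <- findInterval(ui, jumps$time)  # jumps <= U_i (subject's own at-risk indicator)
  for (j in seq_len(k)) {
    v <- as.numeric(integrand(jumps$time[j]))
    if (any(!is.finite(v))) stop("integrand not evaluable at jump time ", jumps$time[j])
    out <- out - jumps$increment[j] * v
  }
  out
}

# Vectorized martingale integrals for all subjects in one arm given the
# integrand evaluated at that arm's jump times.
#
# vals_at_jumps: either a vector of length J (integrand depends on u only) or
# an n_arm x J matrix (integrand depends on subject and u; rows follow `idx`).
# Returns a vector over `idx`.
mart_integral_arm <- function(cm, idx, group, vals_at_jumps) {
  jumps <- censoring_jumps(cm, group)
  J <- length(jumps$time)
  ui <- cm$obs_time[idx]
  di <- cm$ascertained[idx]
  n <- length(idx)
  if (J == 0L) return(numeric(n))
  V <- if (is.matrix(vals_at_jumps)) vals_at_jumps
       else matrix(vals_at_jumps, nrow = n, ncol = J, byrow = TRUE)
  k <- findInterval(ui, jumps$time)              # jumps <= U_i
  W <- sweep(V, 2L, jumps$increment, "*")
  csum <- W
  if (J > 1L) for (j in 2:J) csum[, j] <- csum[, j - 1L] + W[, j]
  comp <- ifelse(k > 0L, csum[cbind(seq_len(n), pmax(k, 1L))], 0)
  event <- numeric(n)
  cens <- which(di == 0L)
  if (length(cens)) {
    j_at <- match(ui[cens], jumps$time)
    event[cens] <- V[cbind(cens, j_at)]
  }
  event - comp
}
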