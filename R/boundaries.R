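#' Alpha-spending plan for group-sequential monitoring
#'
#' Lan-DeMets error spending: a nondecreasing function `a*(s)` with
#' `a*(0) = 0` and `a*(1) = alpha` allocates the type-I error over interim
#' looks at arbitrary information fractions.  Two spending shapes are
#' provided:
#' * `"obf"` (O'Brien-Fleming-type): `a*(s) = 2{1 - Phi(z_{alpha/2}/sqrt(s))}`
#'   with `z_{alpha/2} = Phi^{-1}(1 - alpha/2)`, very conservative early;
#' * `"pocock"` (Pocock-type): `a*(s) = alpha log{1 + (e - 1) s}`, spending
#'   more evenly.
#'
#' For a one-sided plan all of `alpha` is spent on one tail.
#'
#' @param alpha total type-I error (per side convention implied by `sides`);
#'   e.g. 0.025 one-sided.
#' @param type `"obf"` or `"pocock"`.
#' @param sides 1 (default) or 2.
#' @return An object of class `spending_plan`.
#' @export
spending_plan <- function(alpha = 0.025, type = c("obf", "pocock"), sides = 1L) {
  type <- match.arg(type)
  stopifnot(alpha > 0, alpha < 1, sides %in% c(1L, 2L))
  structure(list(alpha = alpha, type = type, sides = as.integer(sides)),
            class = "spending_plan")
}

#' @export
print.spending_plan <- function(x, ...) {
  cat(sprintf("%s-type Lan-DeMets spending, %d-sided alpha = %g\n",
              if (x$type == "obf") "O'Brien-Fleming" else "Pocock", x$sides, x$alpha))
  invisible(x)
}

#' Cumulative alpha spent at an information fraction
#'
#' @param plan a [spending_plan()].
#' @param s information fraction(s) in `[0, 1]`.
#' @return cumulative error spent by `s` (equals `alpha` at `s = 1`).
#' @export
spending_value <- function(plan, s) {
  stopifnot(inherits(plan, "spending_plan"))
  if (any(s < 0 | s > 1)) stop("information fraction must lie in [0, 1]")
  out <- switch(plan$type,
    obf = {
      z <- stats::qnorm(1 - plan$alpha / 2)
      v <- 2 * (1 - stats::pnorm(z / sqrt(pmax(s, .Machine$double.eps))))
      v[s == 0] <- 0
      v
    },
    pocock = plan$alpha * log(1 + (exp(1) - 1) * s))
  out
}

# one recursion stage: given the continuation-region subdensity of the score
# S_{j-1} (grid `sg`, values `fg`; NULL at stage 1), information fractions
# p_{j-1}, p_j, and the drift of Z per unit sqrt-information, find the stage
# boundary whose incremental crossing probability is `spend`, then propagate.
# Works on the score scale S_j = Z_j * sqrt(p_j) ~ N(drift * p_j, p_j).
stage_boundary <- function(sg, fg, p_prev, p_j, drift, spend, two_sided,
                           grid_size, tol = 1e-6) {
  v <- p_j - p_prev
  cross_prob <- function(b) {           # b on the z scale
    bs <- b * sqrt(p_j)
    if (is.null(fg)) {
      pr <- stats::pnorm(bs, mean = drift * p_j, sd = sqrt(p_j), lower.tail = FALSE)
      if (two_sided) pr <- pr + stats::pnorm(-bs, mean = drift * p_j, sd = sqrt(p_j))
      return(pr)
    }
    up <- stats::pnorm(bs - sg, mean = drift * v, sd = sqrt(v), lower.tail = FALSE)
    pr <- trapz(sg, fg * up)
    if (two_sided) {
      lo <- stats::pnorm(-bs - sg, mean = drift * v, sd = sqrt(v))
      pr <- pr + trapz(sg, fg * lo)
    }
    pr
  }
  if (spend <= 1e-12) {
    b <- Inf
  } else {
    lo <- 0; hi <- 10
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (cross_prob(mid) > spend) lo <- mid else hi <- mid
    }
    b <- (lo + hi) / 2
  }
  # propagate the subdensity over the new continuation region
  upper <- if (is.finite(b)) b * sqrt(p_j) else 8.5 * sqrt(p_j)
  lower <- if (two_sided && is.finite(b)) -b * sqrt(p_j) else -8.5 * sqrt(p_j)
  new_sg <- seq(lower, upper, length.out = grid_size)
  if (is.null(fg)) {
    new_fg <- stats::dnorm(new_sg, mean = drift * p_j, sd = sqrt(p_j))
  } else {
    inc <- stats::dnorm(outer(new_sg, sg, "-"), mean = drift * v, sd = sqrt(v))
    dx <- sg[2L] - sg[1L]
    wts <- rep(dx, length(sg)); wts[c(1L, length(sg))] <- dx / 2
    new_fg <- as.numeric(inc %*% (fg * wts))
  }
  list(b = b, sg = new_sg, fg = new_fg)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Group-sequential stopping boundaries by error spending
#'
#' Computes the stage-wise boundaries `b_j` such that, under the canonical
#' joint normal law with independent increments
#' (`cov(Z_i, Z_j) = sqrt(p_i / p_j)`, mean `drift * sqrt(p_j)`), the
#' probability of first crossing at stage `j` equals the incremental error
#' spent between `p_{j-1}` and `p_j`.  Uses subdensity propagation on a
#' numerical grid with bisection for each boundary.
#'
#' @param plan a [spending_plan()].
#' @param fractions strictly increasing information fractions in `(0, 1]`.
#' @param drift mean drift of the standardized statistic per unit
#'   square-root information (0 under the null).
#' @param grid_size grid points per stage (default 4000).
#' @return An object of class `gs_boundaries`: list with `boundaries`,
#'   `fractions`, `cumulative_spend`, `plan`, `drift`.  A stage whose
#'   incremental spend is below 1e-12 gets an `Inf` boundary.
#' @export
gs_boundaries <- function(plan, fractions, drift = 0, grid_size = 4000L) {
  stopifnot(inherits(plan, "spending_plan"))
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions > 1))
    stop("'fractions' must be strictly increasing in (0, 1]")
  K <- length(fractions)
  cum <- spending_value(plan, fractions)
  b <- numeric(K)
  sg <- NULL; fg <- NULL; p_prev <- 0; spent <- 0
  for (j in seq_len(K)) {
    st <- stage_boundary(sg, fg, p_prev, fractions[j], drift,
                         spend = cum[j] - spent, two_sided = plan$sides == 2L,
                         grid_size = grid_size)
    b[j] <- st$b
    if (!is.finite(st$b))
      warning("incremental spend ~ 0 at stage ", j, "; boundary set to Inf")
    sg <- st$sg; fg <- st$fg
    p_prev <- fractions[j]
    spent <- if (is.finite(b[j])) cum[j] else spent
  }
  structure(list(boundaries = b, fractions = fractions, cumulative_spend = cum,
                 plan = plan, drift = drift, grid_size = grid_size),
            class = "gs_boundaries")
}

#' @export
print.gs_boundaries <- function(x, ...) {
  print(x$plan)
  tab <- data.frame(fraction = x$fractions, boundary = round(x$boundaries, 4),
                    cum_spend = signif(x$cumulative_spend, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Probability of ever crossing a group-sequential boundary
#'
#' Total crossing probability of the boundary sequence under the canonical
#' joint normal law with the given drift; with `drift = 0` this recovers the
#' total alpha spent, and for large drift it approaches 1.
#'
#' @param boundaries a `gs_boundaries` object, or a numeric vector of
#'   stage boundaries (then `fractions` must be given).
#' @param fractions information fractions (taken from the object if omitted).
#' @param drift drift parameter.
#' @param two_sided count crossings of both `+b` and `-b`.
#' @param grid_size grid points per stage.
#' @return scalar rejection probability.
#' @export
sequential_power <- function(boundaries, fractions = NULL, drift = 0,
                             two_sided = NULL, grid_size = 4000L) {
  if (inherits(boundaries, "gs_boundaries")) {
    if (is.null(fractions)) fractions <- boundaries$fractions
    if (is.null(two_sided)) two_sided <- boundaries$plan$sides == 2L
    boundaries <- boundaries$boundaries
  }
  if (is.null(two_sided)) two_sided <- FALSE
  if (length(boundaries) != length(fractions)) stop("boundary/fraction length mismatch")
  K <- length(boundaries)
  total <- 0
  sg <- NULL; fg <- NULL; p_prev <- 0
  for (j in seq_len(K)) {
    p_j <- fractions[j]
    v <- p_j - p_prev
    bs <- boundaries[j] * sqrt(p_j)
    if (is.null(fg)) {
      pr <- stats::pnorm(bs, drift * p_j, sqrt(p_j), lower.tail = FALSE)
      if (two_sided) pr <- pr + stats::pnorm(-bs, drift * p_j, sqrt(p_j))
    } else {
      up <- stats::pnorm(bs - sg, drift * v, sqrt(v), lower.tail = FALSE)
      pr <- trapz(sg, fg * up)
      if (two_sided) pr <- pr + trapz(sg, fg * stats::pnorm(-bs - sg, drift * v, sqrt(v)))
    }
    total <- total + pr
    upper <- if (is.finite(bs)) bs else 8.5 * sqrt(p_j)
    lower <- if (two_sided && is.finite(bs)) -bs else -8.5 * sqrt(p_j)
    new_sg <- seq(lower, upper, length.out = grid_size)
    if (is.null(fg)) {
      fg <- stats::dnorm(new_sg, drift * p_j, sqrt(p_j))
    } else {
      inc <- stats::dnorm(outer(new_sg, sg, "-"), drift * v, sqrt(v))
      dx <- sg[2L] - sg[1L]
      wts <- rep(dx, length(sg)); wts[c(1L, length(sg))] <- dx / 2
      fg <- as.numeric(inc %*% (fg * wts))
    }
    sg <- new_sg
    p_prev <- p_j
  }
  total
}

#' Apply group-sequential monitoring to a sequence of Wald statistics
#'
#' Recomputes the spending boundaries from the realized information-fraction
#' path (so unplanned analysis schedules are handled, as error spending
#' permits) and reports the first stage, if any, at which the statistic
#' crosses.  Fractions that fail to increase strictly (estimator noise) are
#' bumped by `1e-6` with a warning.
#'
#' @param statistics Wald statistics in analysis order.
#' @param fractions realized information fractions, same length.
#' @param plan a [spending_plan()].
#' @param direction `"upper"` (reject when `T >= b`), `"lower"`
#'   (`T <= -b`), or `"two_sided"` (`|T| >= b`; requires a 2-sided plan).
#' @param grid_size grid points per stage for the boundary recursion.
#' @return An object of class `monitoring_result`: list with `stop` (logical),
#'   `stage` (first crossing stage or `NA`), `boundaries`, `fractions`,
#'   `statistics`, `crossed` (logical vector).
#' @export
monitor_trial <- function(statistics, fractions, plan,
                          direction = c("upper", "lower", "two_sided"),
                          grid_size = 4000L) {
  direction <- match.arg(direction)
  if (length(statistics) != length(fractions)) stop("length mismatch")
  if (direction == "two_sided" && plan$sides != 2L)
    stop("two-sided monitoring needs a 2-sided spending plan")
  frac <- pmin(fractions, 1)
  for (j in seq_along(frac)[-1L]) {
    if (frac[j] <= frac[j - 1L]) {
      warning("information fraction not increasing at stage ", j, "; bumped by 1e-6")
      frac[j] <- frac[j - 1L] + 1e-6
    }
  }
  # keep the path strictly increasing and within (0, 1]: when the bump (or a
  # clip at 1) has pushed a non-final look to the ceiling, pull earlier looks
  # infinitesimally below their successors (incremental spend there ~ 0)
  frac <- pmin(frac, 1)
  for (j in rev(seq_along(frac)[-length(frac)])) {
    if (frac[j] >= frac[j + 1L]) frac[j] <- frac[j + 1L] - 1e-9
  }
  bds <- gs_boundaries(plan, frac, grid_size = grid_size)$boundaries
  crossed <- switch(direction,
                    upper = statistics >= bds,
                    lower = statistics <= -bds,
                    two_sided = abs(statistics) >= bds)
  stage <- if (any(crossed)) which(crossed)[1L] else NA_integer_
  structure(list(stop = !is.na(stage), stage = stage, boundaries = bds,
                 fractions = frac, statistics = statistics, crossed = crossed,
                 plan = plan, direction = direction),
            class = "monitoring_result")
}

#' @export
print.monitoring_result <- function(x, ...) {
  print(x$plan)
  tab <- data.frame(stage = seq_along(x$statistics), fraction = round(x$fractions, 3),
                    boundary = round(x$boundaries, 3),
                    statistic = round(x$statistics, 3), crossed = x$crossed)
  print(tab, row.names = FALSE)
  if (x$stop) cat("=> stop at stage", x$stage, "\n") else cat("=> no boundary crossed\n")
  invisible(x)
}
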