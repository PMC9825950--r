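#' Assemble full (end-of-trial) data for a two-arm trial with a time-lagged outcome
#'
#' Represents the data that would be available at the final analysis of a
#' two-arm randomized trial in which the outcome `outcome` of subject `i` is
#' ascertained only after a subject-specific lag `lag` (in subject time, at
#' most the maximum follow-up `tf`).  Entry into the trial is staggered:
#' `entry` is calendar time since trial start.
#'
#' @param entry numeric vector of calendar entry times `E >= 0`.
#' @param arm integer/numeric vector of treatment indicators (0 = control,
#'   1 = active).
#' @param lag numeric vector of ascertainment lag times `T` in `(0, tf]`;
#'   the outcome of subject `i` becomes known `lag[i]` time units after entry.
#' @param outcome numeric vector of outcomes: continuous, binary `{0,1}`, or
#'   ordinal `{1..c}` codes.
#' @param tf maximum follow-up time: the subject time by which the outcome is
#'   known with certainty for everyone (`pr(T <= tf) = 1`).
#' @param x optional numeric matrix (or vector) of baseline covariates, one
#'   row per subject.
#' @param paths optional list of per-subject time-dependent covariate paths;
#'   each element is `NULL` or a list with components `time` (ascending change
#'   times starting at 0, subject time) and `value` (matrix with one row per
#'   change time).  Paths are piecewise constant: a query at `u` returns the
#'   row whose change time is the last one at or before `u`.
#'
#' @return An object of class `full_trial_data`.
#' @seealso [interim_data()], [generate_trial()], [read_trial_data()]
#' @export
full_trial_data <- function(entry, arm, lag, outcome, tf, x = NULL, paths = NULL) {
  n <- length(entry)
  if (!is.null(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) != n) stop("'x' must have one row per subject")
  }
  arm <- as.integer(arm)
  if (length(arm) != n || length(lag) != n || length(outcome) != n)
    stop("'entry', 'arm', 'lag' and 'outcome' must have equal length")
  if (!all(arm %in% c(0L, 1L))) stop("'arm' must contain only 0/1")
  if (!is.numeric(tf) || length(tf) != 1L || tf <= 0) stop("'tf' must be a positive scalar")
  if (any(entry < 0)) stop("entry times must be nonnegative")
  if (any(lag <= 0) || any(lag > tf + 1e-12))
    stop("lag times must lie in (0, tf]: the outcome is known by 'tf' for everyone")
  if (!is.null(paths)) {
    if (length(paths) != n) stop("'paths' must have one element per subject")
    paths <- lapply(paths, validate_path)
  }
  structure(
    list(entry = as.numeric(entry), arm = arm, lag = as.numeric(lag),
         outcome = as.numeric(outcome), x = x, paths = paths,
         tf = as.numeric(tf), n = n),
    class = "full_trial_data")
}

validate_path <- function(p) {
  if (is.null(p)) return(NULL)
  if (!is.list(p) || is.null(p$time) || is.null(p$value))
    stop("each covariate path needs 'time' and 'value'")
  v <- as.matrix(p$value)
  storage.mode(v) <- "double"
  if (length(p$time) != nrow(v)) stop("path 'time' and 'value' rows must match")
  if (is.unsorted(p$time, strictly = TRUE)) stop("path change times must be strictly increasing")
  if (p$time[1L] > 0) stop("paths must start at time 0")
  list(time = as.numeric(p$time), value = v)
}

#' Query a piecewise-constant covariate path
#'
#' Returns the most recent value of the path at or before each query time
#' (right-continuous step function).
#'
#' @param path a path as stored in [full_trial_data()] (`NULL` allowed,
#'   returning an empty matrix).
#' @param u numeric vector of query times.
#' @return matrix with `length(u)` rows.
#' @export
path_value <- function(path, u) {
  if (is.null(path)) return(matrix(numeric(0), nrow = length(u), ncol = 0L))
  idx <- findInterval(u, path$time)
  if (any(idx == 0L)) stop("path queried before its first change time")
  path$value[idx, , drop = FALSE]
}

#' @export
print.full_trial_data <- function(x, ...) {
  cat(sprintf("Full trial data: %d subjects (%d active / %d control), tf = %g\n",
              x$n, sum(x$arm == 1L), sum(x$arm == 0L), x$tf))
  cat(sprintf("  entry over [%.3g, %.3g]; %d baseline covariate(s); paths: %s\n",
              min(x$entry), max(x$entry),
              if (is.null(x$x)) 0L else ncol(x$x),
              if (is.null(x$paths)) "none" else "yes"))
  invisible(x)
}

#' Snapshot the data observable at an interim analysis
#'
#' Constructs the observed data at calendar analysis time `t` from full trial
#' data.  Only subjects enrolled by `t` (`E <= t`) appear.  For each, the
#' censoring time is `C(t) = t - E`, the observed time `U(t) = min(T, C(t))`,
#' and the ascertainment indicator `D(t) = I(T <= C(t))`; the outcome is
#' visible only when `D(t) = 1`, and the covariate path is truncated at
#' `U(t)`.
#'
#' @param full a [full_trial_data()] object.
#' @param t calendar analysis time (`> 0`).
#' @return An object of class `interim_data` with per-subject fields `entry`,
#'   `arm`, `x`, `cens_time`, `obs_time`, `ascertained`, `outcome` (`NA` when
#'   not ascertained), `paths`; and trial summaries `n_enrolled`,
#'   `n_fully_followed` (subjects with `C(t) >= tf`), and `pi_t` (enrolled
#'   treated fraction).
#' @export
interim_data <- function(full, t) {
  stopifnot(inherits(full, "full_trial_data"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0) stop("'t' must be a positive scalar")
  keep <- which(full$entry <= t)
  if (length(keep) == 0L) stop("analysis too early: no subjects enrolled by t = ", t)
  arm <- full$arm[keep]
  if (!any(arm == 0L) || !any(arm == 1L))
    stop("analysis too early: an arm has no enrolled subjects at t = ", t)
  cens <- t - full$entry[keep]
  lag <- full$lag[keep]
  asc <- as.integer(lag <= cens)
  obs <- pmin(lag, cens)
  y <- full$outcome[keep]
  y[asc == 0L] <- NA_real_
  n_full <- sum(cens >= full$tf)
  if (n_full == 0L)
    warning("no subject has been followed for the full 'tf' at t = ", t,
            "; the first interim analysis should occur at least tf after trial start")
  paths <- NULL
  if (!is.null(full$paths)) {
    paths <- lapply(seq_along(keep), function(j) {
      p <- full$paths[[keep[j]]]
      if (is.null(p)) return(NULL)
      sel <- p$time <= obs[j]
      list(time = p$time[sel], value = p$value[sel, , drop = FALSE])
    })
  }
  structure(
    list(t = t, index = keep, entry = full$entry[keep], arm = arm,
         x = if (is.null(full$x)) NULL else full$x[keep, , drop = FALSE],
         cens_time = cens, obs_time = obs, ascertained = asc, outcome = y,
         paths = paths, tf = full$tf,
         n_enrolled = length(keep), n_fully_followed = n_full,
         pi_t = mean(arm == 1L)),
    class = "interim_data")
}

#' @export
print.interim_data <- function(x, ...) {
  cat(sprintf("Interim data at t = %g: n(t) = %d enrolled, nA(t) = %d fully followed\n",
              x$t, x$n_enrolled, x$n_fully_followed))
  cat(sprintf("  ascertained outcomes: %d (%.1f%%); treated fraction %.3f\n",
              sum(x$ascertained), 100 * mean(x$ascertained), x$pi_t))
  invisible(x)
}

#' Read subject-level trial data from delimited text
#'
#' The subject table must have columns `id`, `entry_time`, `arm`, `lag_time`,
#' `outcome`, and optionally baseline covariates `x1..xp`.  The optional long
#' table of time-dependent covariates has columns `id`, `time`, and covariate
#' columns; per subject it defines a piecewise-constant path (last value
#' carried forward).
#'
#' @param subject_file path to the subject CSV.
#' @param tf maximum follow-up time.
#' @param covariate_file optional path to the long-format covariate CSV.
#' @return A [full_trial_data()] object.
#' @export
read_trial_data <- function(subject_file, tf, covariate_file = NULL) {
  d <- utils::read.csv(subject_file)
  need <- c("id", "entry_time", "arm", "lag_time", "outcome")
  if (!all(need %in% names(d))) stop("subject file must have columns: ", paste(need, collapse = ", "))
  xcols <- grep("^x[0-9]+$", names(d), value = TRUE)
  x <- if (length(xcols)) as.matrix(d[xcols]) else NULL
  paths <- NULL
  if (!is.null(covariate_file)) {
    long <- utils::read.csv(covariate_file)
    if (!all(c("id", "time") %in% names(long))) stop("covariate file must have columns 'id' and 'time'")
    lcols <- setdiff(names(long), c("id", "time"))
    paths <- lapply(d$id, function(id) {
      rows <- long[long$id == id, , drop = FALSE]
      if (nrow(rows) == 0L) return(NULL)
      rows <- rows[order(rows$time), , drop = FALSE]
      list(time = rows$time, value = as.matrix(rows[lcols]))
    })
  }
  full_trial_data(entry = d$entry_time, arm = d$arm, lag = d$lag_time,
                  outcome = d$outcome, tf = tf, x = x, paths = paths)
}

#' Write trial data to delimited text
#'
#' Inverse of [read_trial_data()]: writes the subject table and, when paths
#' are present, the long-format covariate table.
#'
#' @param full a [full_trial_data()] object.
#' @param subject_file output path for the subject CSV.
#' @param covariate_file optional output path for the long covariate CSV.
#' @return Invisibly, `full`.
#' @export
write_trial_data <- function(full, subject_file, covariate_file = NULL) {
  stopifnot(inherits(full, "full_trial_data"))
  d <- data.frame(id = seq_len(full$n), entry_time = full$entry, arm = full$arm,
                  lag_time = full$lag, outcome = full$outcome)
  if (!is.null(full$x)) {
    xs <- as.data.frame(full$x)
    names(xs) <- paste0("x", seq_len(ncol(xs)))
    d <- cbind(d, xs)
  }
  utils::write.csv(d, subject_file, row.names = FALSE)
  if (!is.null(covariate_file) && !is.null(full$paths)) {
    rows <- lapply(seq_len(full$n), function(i) {
      p <- full$paths[[i]]
      if (is.null(p)) return(NULL)
      v <- as.data.frame(p$value)
      names(v) <- paste0("l", seq_len(ncol(v)))
      cbind(data.frame(id = i, time = p$time), v)
    })
    utils::write.csv(do.call(rbind, rows), covariate_file, row.names = FALSE)
  }
  invisible(full)
}
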