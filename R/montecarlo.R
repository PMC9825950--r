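#' Analyze one simulated trial at a sequence of looks
#'
#' Generates one trial from `config` and, at each requested look, fits the
#' requested estimators and computes their fixed-sample information fractions
#' (fully-followed count over `n_max` for the `"tf"` estimator, effective
#' sample size over `n_max` for the others; the fraction at the final
#' analysis is 1 by construction).  Step 1 is shared between the IPW and
#' AIPW estimators at a look.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed for this replicate.
#' @param estimators subset of `c("tf", "ipw", "aipw1", "aipw2")`.
#' @param looks numeric vector of analysis calendar times (default: the
#'   configured interim times plus the final time), or a named list giving a
#'   separate vector per estimator (compute-saving for large Monte Carlo
#'   runs).
#' @param basis optional [basis_spec()] for the augmented estimators
#'   (default: covariate components via [default_basis()]).
#' @return A list with one element per estimator: a data.frame with columns
#'   `time`, `beta`, `se`, `wald`, `fraction`, `n_enrolled`,
#'   `n_fully_followed`.
#' @export
run_replicate <- function(config, seed,
                          estimators = c("tf", "ipw", "aipw1", "aipw2"),
                          looks = NULL, basis = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  all_looks <- c(config$analysis_times, config$t_end)
  if (is.null(looks)) looks <- all_looks
  look_map <- if (is.list(looks)) {
    if (!all(estimators %in% names(looks))) stop("'looks' list must name every estimator")
    looks
  } else {
    stats::setNames(rep(list(looks), length(estimators)), estimators)
  }
  full <- generate_trial(config, seed = seed)
  model <- scenario_model(config)
  times <- sort(unique(unlist(look_map)))
  rows <- stats::setNames(vector("list", length(estimators)), estimators)
  for (tt in times) {
    snap <- interim_data(full, tt)
    at_tt <- estimators[vapply(estimators, function(e) tt %in% look_map[[e]], logical(1))]
    need_w <- any(at_tt %in% c("ipw", "aipw1", "aipw2"))
    cm <- if (need_w) censoring_km(snap) else NULL
    ipw <- if (need_w) fit_ipwcc(snap, model, cm) else NULL
    bas <- if (any(at_tt %in% c("aipw1", "aipw2"))) {
      if (is.null(basis)) default_basis(snap) else basis
    } else NULL
    for (est in at_tt) {
      fit <- switch(est,
                    tf = fit_tf_only(snap, model),
                    ipw = ipw,
                    aipw1 = fit_aipwcc(snap, model, bas, cm, include_h = FALSE, ipw = ipw),
                    aipw2 = fit_aipwcc(snap, model, bas, cm, include_h = TRUE, ipw = ipw))
      # at the final analysis (everyone fully followed) the fixed-sample
      # fraction is 1 by definition; avoid O(1/n) estimator noise around it
      frac <- if (snap$n_fully_followed == config$n_max) 1 else
        suppressWarnings(
          information_fraction(fit, n_max = config$n_max, interim = snap)$fraction)
      rows[[est]] <- rbind(rows[[est]], data.frame(
        time = tt, beta = fit$beta, se = fit$se, wald = fit$wald,
        fraction = frac, n_enrolled = fit$n_enrolled,
        n_fully_followed = fit$n_fully_followed))
    }
  }
  rows
}

#' Monte Carlo operating characteristics of the monitored estimators
#'
#' Replicates [run_replicate()] `n_reps` times and aggregates, per estimator
#' and look: Monte Carlo mean and SD of the estimate, mean of the standard
#' errors, and the MSE ratio of the fully-followed-only estimator to the
#' estimator (when `"tf"` is among the estimators and shares the look).
#' For estimators observed at every look, group-sequential monitoring is
#' applied per replicate with boundaries recomputed from that replicate's
#' realized information-fraction path, yielding the rejection proportion and
#' the mean (SD) of the enrolled count and calendar time at stopping.
#'
#' @param config a [scenario_config()].
#' @param n_reps number of Monte Carlo replicates.
#' @param seed master seed; per-replicate seeds are drawn from it.
#' @param estimators,looks,basis passed to [run_replicate()].
#' @param plans named list of [spending_plan()]s to monitor with (default
#'   O'Brien-Fleming-type and Pocock-type, one-sided 0.025); `NULL` disables
#'   monitoring.
#' @param direction monitoring direction (see [monitor_trial()]); by default
#'   `"upper"` unless the scenario's true effect is negative under its
#'   alternative (binary scenario), then `"lower"`.
#' @param grid_size boundary-recursion grid per stage; the default for Monte
#'   Carlo use (301) is coarser than the single-trial default (4000) but
#'   accurate to well under 0.001 on the z scale.
#' @param progress print a dot every 200 replicates.
#' @return An object of class `gslag_mc`: list with `estimates` (long
#'   data.frame of per-look aggregates), `monitoring` (per estimator x plan),
#'   `covariance` (per-estimator covariance matrix of the estimates across
#'   looks), `beta_true`, `n_reps`, `failures`.
#' @export
run_monte_carlo <- function(config, n_reps, seed = 1L,
                            estimators = c("tf", "ipw", "aipw1", "aipw2"),
                            looks = NULL, basis = NULL,
                            plans = list(obf = spending_plan(0.025, "obf"),
                                         pocock = spending_plan(0.025, "pocock")),
                            direction = NULL, grid_size = 301L,
                            progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 2)
  estimators <- match.arg(estimators, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  if (is.null(direction))
    direction <- if (config$scenario == "binary" && config$beta != 0) "lower" else "upper"
  all_looks <- c(config$analysis_times, config$t_end)
  beta_true <- scenario_effect(config)
  reps <- vector("list", n_reps)
  failures <- 0L
  for (r in seq_len(n_reps)) {
    reps[[r]] <- tryCatch(
      run_replicate(config, seed = rep_seeds[r], estimators = estimators,
                    looks = looks, basis = basis),
      error = function(e) {
        warning("replicate ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(reps[[r]])) failures <- failures + 1L
    if (progress && r %% 200L == 0L) cat(".")
  }
  if (progress) cat("\n")
  reps <- reps[!vapply(reps, is.null, logical(1))]
  est_tab <- NULL
  covs <- list()
  mse <- list()
  for (est in estimators) {
    tab <- do.call(rbind, lapply(reps, `[[`, est))
    for (tt in unique(tab$time)) {
      sel <- tab$time == tt
      b <- tab$beta[sel]
      mse[[est]][[as.character(tt)]] <- mean((b - beta_true)^2)
      est_tab <- rbind(est_tab, data.frame(
        estimator = est, time = tt, mc_mean = mean(b), mc_sd = stats::sd(b),
        mean_se = mean(tab$se[sel]), mse = mean((b - beta_true)^2),
        mean_fraction = mean(tab$fraction[sel])))
    }
    bmat <- do.call(rbind, lapply(reps, function(r) r[[est]]$beta))
    if (ncol(bmat) > 1L) covs[[est]] <- stats::cov(bmat)
  }
  if ("tf" %in% estimators) {
    est_tab$mse_ratio <- NA_real_
    for (i in seq_len(nrow(est_tab))) {
      ref <- mse[["tf"]][[as.character(est_tab$time[i])]]
      if (!is.null(ref)) est_tab$mse_ratio[i] <- ref / est_tab$mse[i]
    }
  }
  mon_tab <- NULL
  if (!is.null(plans)) {
    for (est in estimators) {
      if (!all(all_looks %in% (reps[[1L]][[est]]$time))) next
      stats_mat <- do.call(rbind, lapply(reps, function(r) r[[est]]$wald))
      frac_mat <- do.call(rbind, lapply(reps, function(r) r[[est]]$fraction))
      n_mat <- do.call(rbind, lapply(reps, function(r) r[[est]]$n_enrolled))
      for (pl in names(plans)) {
        res <- vapply(seq_len(nrow(stats_mat)), function(r) {
          mr <- suppressWarnings(
            monitor_trial(stats_mat[r, ], frac_mat[r, ], plans[[pl]],
                          direction = direction, grid_size = grid_size))
          st <- if (mr$stop) mr$stage else length(all_looks)
          c(reject = as.numeric(mr$stop), n_stop = n_mat[r, st],
            t_stop = all_looks[st])
        }, numeric(3))
        mon_tab <- rbind(mon_tab, data.frame(
          estimator = est, plan = pl,
          p_reject = mean(res["reject", ]),
          mean_ss = mean(res["n_stop", ]), sd_ss = stats::sd(res["n_stop", ]),
          mean_stop = mean(res["t_stop", ]), sd_stop = stats::sd(res["t_stop", ])))
      }
    }
  }
  structure(list(estimates = est_tab, monitoring = mon_tab, covariance = covs,
                 beta_true = beta_true, n_reps = length(reps),
                 failures = failures, config = config, direction = direction),
            class = "gslag_mc")
}

#' @export
print.gslag_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo over %d replicates (%d failed), scenario '%s', true beta %.4g\n",
              x$n_reps, x$failures, x$config$scenario, x$beta_true))
  cat("\nEstimates by look:\n")
  print(cbind(x$estimates[, c("estimator", "time")],
              round(x$estimates[, setdiff(names(x$estimates), c("estimator", "time"))], 4)),
        row.names = FALSE)
  if (!is.null(x$monitoring)) {
    cat("\nMonitoring:\n")
    print(cbind(x$monitoring[, c("estimator", "plan")],
                round(x$monitoring[, -(1:2)], 4)), row.names = FALSE)
  }
  invisible(x)
}

#' Empirical check of the independent-increments property
#'
#' For sequentially computed estimates with independent increments,
#' `cov{beta(s), beta(t)} = var{beta(t)}` for `s < t`.  Given a Monte Carlo
#' covariance matrix of the estimates across looks, returns the maximum
#' relative deviation of the off-diagonal entries from the later look's
#' variance.
#'
#' @param cov_matrix covariance matrix of the estimates across looks (in
#'   analysis order).
#' @param threshold pass/fail threshold on the maximum relative deviation.
#' @return list with `max_deviation` and `pass`.
#' @export
independent_increments_check <- function(cov_matrix, threshold = 0.20) {
  K <- ncol(cov_matrix)
  dev <- 0
  for (s in seq_len(K - 1L)) {
    for (t in (s + 1L):K) {
      dev <- max(dev, abs(cov_matrix[s, t] - cov_matrix[t, t]) / cov_matrix[t, t])
    }
  }
  list(max_deviation = dev, pass = dev <= threshold)
}
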