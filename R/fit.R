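#' Smoothed false alarm rate from null-pair responses
#'
#' Estimates the false alarm rate F from the null (identical-face) cells as
#' `(n_false_alarms + 1/2) / (n_nulls + 1)`. The +1/2 smoothing keeps the
#' estimate strictly inside (0, 1) so the decision stage of the
#' psychometric model stays finite even when no (or every) null cell was
#' clicked.
#'
#' @param records A response-record data frame (see [classify_chart()]);
#'   only rows with `is_target == FALSE` are used.
#' @return The smoothed false alarm probability.
#' @export
estimate_false_alarm_rate <- function(records) {
  records <- as.data.frame(records)
  nulls <- records[!records$is_target, , drop = FALSE]
  if (nrow(nulls) == 0L) {
    stop("no null records: the false alarm rate must be supplied",
         call. = FALSE)
  }
  (sum(nulls$response_yes) + 0.5) / (nrow(nulls) + 1)
}

# Bin target records by exact level value (levels are discrete by
# construction, so no tolerance-based merging is needed).
bin_by_level <- function(records) {
  tg <- records[records$is_target, , drop = FALSE]
  lev <- sort(unique(tg$level))
  n <- vapply(lev, function(l) sum(tg$level == l), 0L)
  y <- vapply(lev, function(l) sum(tg$response_yes[tg$level == l]), 0L)
  data.frame(level = lev, n = n, yes = y, p_obs = y / n)
}

.nonconverged_fit <- function(records, reason, params = NULL) {
  structure(
    list(params = params, se = c(theta = NA_real_, gamma = NA_real_),
         residual_norm = NA_real_, converged = FALSE, fallback = TRUE,
         reason = reason, n_records = nrow(as.data.frame(records)),
         bins = NULL, false_alarm_fixed = TRUE),
    class = "psychometric_fit")
}

#' Fit the psychometric function to response records
#'
#' Weighted nonlinear least squares of observed yes-proportions against the
#' saturating d-prime model, binned by exact test level. Each bin is
#' weighted by the inverse of its binomial standard error; the error
#' estimate is model-based, `sqrt(p(1 - p)/n)` at the current fitted
#' probabilities, and the weights are iterated to their fixed point
#' (iteratively reweighted least squares), at which the weighted
#' least-squares normal equations coincide with the quasi-binomial score
#' equations, so extreme bins keep finite, correctly scaled weight. The
#' false alarm rate is estimated from the null cells with
#' [estimate_false_alarm_rate()] and held fixed by default (freeing it on
#' the few nulls a session provides is unstable; set
#' `fix_false_alarm = FALSE` for sensitivity analysis, which adds the
#' level-0 bin to the fit). Threshold and slope are fit on the log scale
#' under bounds (theta > 0, gamma in `gamma_bounds`) by
#' Levenberg-Marquardt least squares, multi-started from three initial
#' thresholds (the minimum, geometric mean and maximum of the tested
#' levels); the start with the lowest penalized deviance wins, ties broken
#' by the smaller threshold.
#'
#' Sparse chart data (a few dozen one-trial bins) cannot identify the
#' slope: unregularized fits drift to steep step-like solutions that
#' inflate the threshold. The slope is therefore ridge-regularized toward
#' the canonical unit slope with penalty
#' `slope_ridge * n_target * log(gamma)^2` added to the weighted residual
#' sum of squares. Scaling the penalty with the number of target records
#' keeps its strength a fixed fraction of the data information, which also
#' makes the point estimate exactly invariant to duplicating every record.
#' The default `slope_ridge = 0.45` corresponds, at a typical session
#' (about 24 target records), to a lognormal prior on the slope with
#' standard deviation about 0.3 log units; set `slope_ridge = 0` for an
#' unregularized fit.
#'
#' @param records Response-record data frame with columns `level`,
#'   `is_target`, `response_yes` (see [classify_chart()]). At least one
#'   null record and two distinct positive levels are required; otherwise a
#'   non-converged fit with `fallback = TRUE` is returned.
#' @param init Optional [psychometric_params()] supplying the starting
#'   slope (and false alarm rate when no nulls are present).
#' @param fix_false_alarm Hold F fixed at its null-cell estimate (default)
#'   or fit it as a free bounded parameter.
#' @param false_alarm Optional known F, overriding the null-cell estimate.
#' @param gamma_bounds Box constraints on the slope; the default
#'   `c(0.25, 8)` prevents degenerate step-function fits on sparse data.
#' @param slope_ridge Per-target-record weight of the slope ridge penalty.
#' @param dprime_max Saturating d-prime, fixed during fitting.
#' @return An object of class `psychometric_fit`: `params`
#'   (a [psychometric_params()]), `se` (standard errors of the free
#'   parameters), `residual_norm`, `converged`, `fallback`, `n_records`,
#'   `bins`, and `false_alarm_fixed`.
#' @export
fit_psychometric <- function(records, init = NULL, fix_false_alarm = TRUE,
                             false_alarm = NULL, gamma_bounds = c(0.25, 8),
                             slope_ridge = 0.45, dprime_max = 5) {
  records <- as.data.frame(records)
  need <- c("level", "is_target", "response_yes")
  if (!all(need %in% names(records))) {
    stop("`records` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n_null <- sum(!records$is_target)
  bins <- bin_by_level(records)

  if (is.null(false_alarm)) {
    if (n_null >= 1L) {
      false_alarm <- estimate_false_alarm_rate(records)
    } else if (!is.null(init)) {
      false_alarm <- init$false_alarm
    } else {
      return(.nonconverged_fit(records, "no null records and no F supplied"))
    }
  }
  if (nrow(bins) < 2L) {
    return(.nonconverged_fit(
      records, "fewer than 2 distinct positive levels",
      params = if (!is.null(init)) init))
  }
  if (all(bins$p_obs == 1) || all(bins$p_obs == 0)) {
    return(.nonconverged_fit(
      records, "all-yes or all-no target data",
      params = if (!is.null(init)) init))
  }

  gamma0 <- if (!is.null(init)) init$gamma else 1
  gamma0 <- min(max(gamma0, gamma_bounds[1L]), gamma_bounds[2L])
  starts <- unique(c(min(bins$level), exp(mean(log(bins$level))),
                     max(bins$level)))
  if (!is.null(init)) starts <- unique(c(init$theta, starts))

  n_target <- sum(bins$n)
  kappa <- slope_ridge * n_target
  free_f <- !fix_false_alarm
  # free-F fits include the level-0 bin so the nulls constrain F directly
  if (free_f) {
    null_p <- mean(records$response_yes[!records$is_target])
    fbins <- rbind(data.frame(level = 0, n = n_null, yes = sum(
      records$response_yes[!records$is_target]), p_obs = null_p), bins)
  } else {
    fbins <- bins
  }
  eps <- 1e-4
  # parameters on unconstrained-friendly scales: log theta, log gamma,
  # logit F (the latter only when F is free)
  par0_of <- function(theta0) {
    c(log(theta0), log(gamma0),
      if (free_f) stats::qlogis(min(max(false_alarm, eps), 1 - eps)))
  }
  lowerb <- c(log(1e-4), log(gamma_bounds[1L]),
              if (free_f) stats::qlogis(eps))
  upperb <- c(log(1e4), log(gamma_bounds[2L]),
              if (free_f) stats::qlogis(1 - eps))
  p_of <- function(par) {
    Fv <- if (free_f) stats::plogis(par[3L]) else false_alarm
    p_yes(fbins$level, psychometric_params(exp(par[1L]), exp(par[2L]),
                                           Fv, dprime_max))
  }
  # one IRLS pass: weights frozen at the current fit, then an LM solve;
  # at the fixed point the weighted-LS score equals the quasi-binomial score
  irls <- function(par) {
    for (it in seq_len(25L)) {
      p_cur <- pmin(pmax(p_of(par), 1e-8), 1 - 1e-8)
      w <- sqrt(fbins$n / (p_cur * (1 - p_cur)))
      sol <- try(suppressWarnings(minpack.lm::nls.lm(
        par,
        fn = function(q) c(w * (fbins$p_obs - p_of(q)),
                           sqrt(kappa) * q[2L]),
        lower = lowerb, upper = upperb,
        control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
      if (inherits(sol, "try-error")) return(NULL)
      moved <- max(abs(sol$par - par))
      par <- sol$par
      if (moved < 1e-10) break
    }
    par
  }
  # penalized binomial deviance, the objective the IRLS fixed point solves
  pdev <- function(par) {
    p <- pmin(pmax(p_of(par), 1e-12), 1 - 1e-12)
    -2 * sum(fbins$yes * log(p) + (fbins$n - fbins$yes) * log(1 - p)) +
      kappa * par[2L]^2
  }

  best <- NULL
  for (theta0 in starts) {
    par <- irls(par0_of(theta0))
    if (is.null(par)) next
    v <- pdev(par)
    if (is.null(best) || v < best$v - 1e-9 ||
        (abs(v - best$v) <= 1e-9 && par[1L] < best$par[1L])) {
      best <- list(v = v, par = par)
    }
  }
  if (is.null(best)) {
    return(.nonconverged_fit(records, "optimizer failed from all starts",
                             params = if (!is.null(init)) init))
  }

  par <- best$par
  theta_hat <- exp(par[1L]); gamma_hat <- exp(par[2L])
  F_hat <- if (free_f) stats::plogis(par[3L]) else false_alarm
  # Gauss-Newton covariance of (log theta, log gamma[, logit F]) at the
  # solution, delta-method back to the natural scale
  p_fin <- pmin(pmax(p_of(par), 1e-8), 1 - 1e-8)
  w_fin <- sqrt(fbins$n / (p_fin * (1 - p_fin)))
  jac <- vapply(seq_along(par), function(j) {
    h <- 1e-6
    ph <- p_of(par + h * (seq_along(par) == j))
    w_fin * (ph - p_fin) / h
  }, numeric(nrow(fbins)))
  info <- crossprod(jac) + diag(c(0, kappa, 0)[seq_along(par)], length(par))
  cov_log <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, length(par), length(par)))
  ses <- c(theta = theta_hat * sqrt(cov_log[1L, 1L]),
           gamma = gamma_hat * sqrt(cov_log[2L, 2L]))
  wres <- w_fin * (fbins$p_obs - p_fin)
  structure(
    list(params = psychometric_params(theta_hat, gamma_hat, F_hat,
                                      dprime_max),
         se = ses,
         residual_norm = sqrt(sum(wres^2)),
         converged = TRUE, fallback = FALSE, reason = NULL,
         n_records = nrow(records), bins = bins,
         false_alarm_fixed = fix_false_alarm),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (!x$converged) {
    cat("psychometric_fit: NOT converged (", x$reason, "), n = ",
        x$n_records, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "psychometric_fit: theta = %.4g (SE %.3g), gamma = %.4g, F = %.4g [%s], n = %d\n",
    x$params$theta, x$se[["theta"]], x$params$gamma, x$params$false_alarm,
    if (x$false_alarm_fixed) "fixed" else "free", x$n_records))
  invisible(x)
}
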