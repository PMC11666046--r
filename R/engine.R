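#' Session configuration
#'
#' Bundles every tunable of an adaptive face-discrimination session. The
#' defaults reproduce the standard protocol: a 3 x 3 chart of 6-degree
#' cells with 3-degree gaps, a target fraction drawn uniformly from
#' (0.6, 0.8) per chart, 4 charts per component set, adaptive placement at
#' discriminability values equally spaced over d' = 0.1 to 4.5, and
#' frontal pose (set `yaw_range = c(-5, 5)` for the rotation variant).
#'
#' @param components List of integer vectors: the component sets under test
#'   (singletons for single-component thresholds, pairs for combined).
#' @param n_charts Charts per component set (>= 2); 3 suits a broad
#'   component survey, 4 the single/combined comparisons.
#' @param grid `c(rows, cols)` of the chart.
#' @param target_fraction Interval for the per-chart target fraction.
#' @param dprime_placement `c(low, high)` d-prime range for adaptive
#'   placement on charts 2+; must lie strictly inside `(0, dprime_max)`.
#' @param initial_levels List `(n_steps, min_level, max_level)` describing
#'   the geometrically spaced first-chart levels. The default 5 steps over
#'   0.5-16 sd brackets thresholds across the sensitivity range a
#'   broad-component survey produces.
#' @param yaw_range Per-face yaw interval in degrees.
#' @param level_cap Maximum emitted test level (sd units). The placement
#'   inverse diverges near `dprime_max`; the cap keeps stimuli inside the
#'   face model's plausible regime. Capped placements are recorded in the
#'   audit log.
#' @param dprime_max Saturating d-prime of the model.
#' @param cell_size_deg,gap_deg Display geometry for renderers.
#' @param seed Optional master seed; per-component, per-chart child seeds
#'   are split from it (see [run_session()]).
#' @return An object of class `session_config`.
#' @export
session_config <- function(components = list(1L),
                           n_charts = 4L,
                           grid = c(3L, 3L),
                           target_fraction = c(0.6, 0.8),
                           dprime_placement = c(0.1, 4.5),
                           initial_levels = list(n_steps = 5L,
                                                 min_level = 0.5,
                                                 max_level = 16),
                           yaw_range = c(0, 0),
                           level_cap = 20,
                           dprime_max = 5,
                           cell_size_deg = 6, gap_deg = 3,
                           seed = NULL) {
  if (!is.list(components) || length(components) == 0L) {
    stop("config field `components`: must be a non-empty list of index sets",
         call. = FALSE)
  }
  components <- lapply(components, as.integer)
  if (n_charts < 2L) {
    stop("config field `n_charts`: must be >= 2", call. = FALSE)
  }
  stopifnot(length(grid) == 2L, all(grid >= 1L))
  if (length(target_fraction) != 2L || target_fraction[1L] <= 0 ||
      target_fraction[2L] >= 1 || target_fraction[1L] > target_fraction[2L]) {
    stop("config field `target_fraction`: must satisfy 0 < low <= high < 1",
         call. = FALSE)
  }
  if (length(dprime_placement) != 2L || dprime_placement[1L] <= 0 ||
      dprime_placement[2L] >= dprime_max ||
      dprime_placement[1L] >= dprime_placement[2L]) {
    stop("config field `dprime_placement`: must satisfy 0 < low < high < dprime_max",
         call. = FALSE)
  }
  il <- initial_levels
  if (!all(c("n_steps", "min_level", "max_level") %in% names(il)) ||
      il$n_steps < 2L || il$min_level <= 0 || il$min_level >= il$max_level) {
    stop("config field `initial_levels`: need n_steps >= 2 and 0 < min_level < max_level",
         call. = FALSE)
  }
  if (level_cap <= 0) {
    stop("config field `level_cap`: must be > 0", call. = FALSE)
  }
  structure(
    list(components = components, n_charts = as.integer(n_charts),
         grid = as.integer(grid), target_fraction = target_fraction,
         dprime_placement = dprime_placement, initial_levels = il,
         yaw_range = yaw_range, level_cap = level_cap,
         dprime_max = dprime_max,
         cell_size_deg = cell_size_deg, gap_deg = gap_deg,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "session_config: %d component set(s), %d charts each, %dx%d grid\n",
    length(x$components), x$n_charts, x$grid[1L], x$grid[2L]))
  cat(sprintf("  target fraction (%g, %g); d' placement (%g, %g); yaw (%g, %g)\n",
              x$target_fraction[1L], x$target_fraction[2L],
              x$dprime_placement[1L], x$dprime_placement[2L],
              x$yaw_range[1L], x$yaw_range[2L]))
  invisible(x)
}

#' First-chart test levels
#'
#' Geometrically (log-equally) spaced levels spanning the configured
#' range, used before any fit exists.
#'
#' @param config A [session_config()].
#' @return Numeric vector of `n_steps` levels with equal consecutive
#'   ratios.
#' @export
initial_levels <- function(config) {
  il <- config$initial_levels
  exp(seq(log(il$min_level), log(il$max_level), length.out = il$n_steps))
}

#' Adaptive test levels for the next chart
#'
#' Places `n_levels` stimuli at discriminability values equally spaced
#' (both endpoints included) over the configured d-prime range, inverted
#' through the current fit's psychometric parameters, so the next chart
#' spans difficult (d' = 0.1) to easy (d' = 4.5) for this observer.
#' Levels are capped at `config$level_cap`; the number capped is reported
#' in the `"capped"` attribute.
#'
#' @param fit A converged [fit_psychometric()] result.
#' @param config A [session_config()].
#' @param n_levels Number of levels (the chart's drawn target count).
#' @return Numeric vector of `n_levels` test levels.
#' @export
next_chart_levels <- function(fit, config, n_levels) {
  if (!inherits(fit, "psychometric_fit") || !fit$converged) {
    stop("fit not converged: fall back to the previous chart's levels",
         call. = FALSE)
  }
  stopifnot(n_levels >= 2L)
  d_grid <- seq(config$dprime_placement[1L], config$dprime_placement[2L],
                length.out = n_levels)
  lv <- invert_dprime(d_grid, fit$params)
  capped <- sum(lv > config$level_cap)
  lv <- pmin(lv, config$level_cap)
  attr(lv, "capped") <- capped
  lv
}

#' Classify chart responses as Hit / Miss / FalseAlarm / CorrectRejection
#'
#' Converts a set of clicked grid positions into one response record per
#' cell: a clicked cell is a "yes" (faces look like different people), and
#' the outcome follows the signal-detection table — target & yes = Hit,
#' target & no = Miss, null & yes = FalseAlarm, null & no =
#' CorrectRejection.
#'
#' @param chart A [build_chart()] result.
#' @param clicked_positions Positions clicked: a list of `c(row, col)`
#'   pairs, a 2-column matrix, or `NULL`/empty for no clicks. Positions
#'   outside the grid are an error.
#' @return A data frame with one row per cell: `component_labels`
#'   (semicolon-joined 1-based indices), `chart_index`, `row`, `col`,
#'   `level`, `is_target`, `response_yes`, `outcome`.
#' @export
classify_chart <- function(chart, clicked_positions = NULL) {
  stopifnot(inherits(chart, "chart_spec"))
  if (is.matrix(clicked_positions)) {
    clicked_positions <- lapply(seq_len(nrow(clicked_positions)),
                                function(i) clicked_positions[i, ])
  }
  key <- function(p) paste(p[1L], p[2L], sep = ",")
  clicked <- vapply(clicked_positions %||% list(), key, "")
  for (p in clicked_positions %||% list()) {
    if (p[1L] < 1L || p[1L] > chart$grid[1L] ||
        p[2L] < 1L || p[2L] > chart$grid[2L]) {
      stop("clicked position (", p[1L], ",", p[2L], ") outside the grid",
           call. = FALSE)
    }
  }
  label <- paste(chart$component_under_test, collapse = ";")
  rows <- lapply(chart$cells, function(cell) {
    yes <- key(cell$pos) %in% clicked
    tg <- cell$pair$is_target
    data.frame(component_labels = label,
               chart_index = chart$chart_index,
               row = cell$pos[1L], col = cell$pos[2L],
               level = cell$pair$test_level,
               is_target = tg, response_yes = yes,
               outcome = classify_outcome(tg, yes))
  })
  do.call(rbind, rows)
}

classify_outcome <- function(is_target, response_yes) {
  ifelse(is_target,
         ifelse(response_yes, "Hit", "Miss"),
         ifelse(response_yes, "FalseAlarm", "CorrectRejection"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic seed splitting: one child stream per (component slot, chart)
# so adding a component set does not perturb the others' streams. Slot 0 /
# chart r seeds the per-round interleaving permutation.
child_seed <- function(master, comp_slot, chart) {
  as.integer((as.numeric(master) * 7919 + comp_slot * 104729 + chart * 7) %%
               2147483647)
}

#' Run a closed-loop adaptive session
#'
#' Executes the full adaptive procedure for every configured component
#' set: chart 1 uses the geometrically spaced [initial_levels()] (recycled
#' over the drawn target count); after each chart the cumulative records
#' for that component set are refit with [fit_psychometric()] and, when
#' the fit converges, the next chart's levels are placed with
#' [next_chart_levels()]; otherwise the previous chart's levels are
#' reused. Component sets are interleaved in a seeded random order within
#' each chart round. The final threshold estimate per component set is the
#' fit after its last chart.
#'
#' Randomness is fully determined by the master seed: each (component set,
#' chart) pair gets its own child seed (recorded in the audit log), so the
#' same configuration and seed reproduce the session bitwise.
#'
#' @param observer Either a [simulated_observer()] or a function
#'   `function(pair) -> TRUE/FALSE` mapping a face pair to a
#'   "different people" response.
#' @param config A [session_config()].
#' @param seed Master seed; defaults to `config$seed`, required.
#' @return An object of class `find_session`: `records` (all response
#'   records), `estimates` (one row per component set: `component_labels`,
#'   `theta_hat`, `se_theta`, `gamma_hat`, `false_alarm_hat`, `converged`,
#'   `n_charts_used`), `fits` (final fits), `trajectory` (per component
#'   set, the fit after each chart), `audit` (per chart: seed, levels
#'   used, capped count, running threshold), `config`, `seed`.
#' @examples
#' obs <- simulated_observer(theta = 4, gamma = 1, false_alarm = 0.05)
#' cfg <- session_config(components = list(1L), seed = 7)
#' sess <- run_session(obs, cfg)
#' sess$estimates
#' @export
run_session <- function(observer, config, seed = config$seed) {
  stopifnot(inherits(config, "session_config"))
  if (is.null(seed)) stop("a master `seed` is required", call. = FALSE)
  responder <- if (inherits(observer, "simulated_observer")) {
    function(pair) respond(pair, observer)
  } else if (is.function(observer)) {
    observer
  } else {
    stop("`observer` must be a simulated_observer or a function",
         call. = FALSE)
  }

  n_comp <- length(config$components)
  init_lv <- initial_levels(config)
  records <- vector("list", n_comp)
  fits <- vector("list", n_comp)
  trajectory <- replicate(n_comp, list(), simplify = FALSE)
  last_levels <- replicate(n_comp, init_lv, simplify = FALSE)
  audit <- list()
  aborted <- FALSE
  abort_msg <- NULL

  for (r in seq_len(config$n_charts)) {
    if (aborted) break
    set.seed(child_seed(seed, 0L, r))
    ord <- sample.int(n_comp)
    for (ci in ord) {
      if (aborted) break
      sd_c <- child_seed(seed, ci, r)
      set.seed(sd_c)
      fit_prev <- fits[[ci]]
      adaptive <- r > 1L && !is.null(fit_prev) && isTRUE(fit_prev$converged)
      capped <- 0L
      provider <- if (adaptive) {
        function(k) {
          lv <- next_chart_levels(fit_prev, config, k)
          capped <<- attr(lv, "capped")
          as.numeric(lv)
        }
      } else {
        function(k) rep_len(last_levels[[ci]], k)
      }
      chart <- build_chart(
        chart_index = r, levels = provider,
        target_components = config$components[[ci]],
        target_fraction = config$target_fraction, grid = config$grid,
        yaw_range = config$yaw_range,
        cell_size_deg = config$cell_size_deg, gap_deg = config$gap_deg)
      clicked <- tryCatch(
        Filter(Negate(is.null), lapply(chart$cells, function(cell) {
          res <- responder(cell$pair)
          if (!is.logical(res) || length(res) != 1L || is.na(res)) {
            stop("observer callback must return a single TRUE/FALSE",
                 call. = FALSE)
          }
          if (res) cell$pos else NULL
        })),
        error = function(e) e)
      if (inherits(clicked, "error")) {
        # abort on callback failure but preserve completed charts
        aborted <- TRUE
        abort_msg <- conditionMessage(clicked)
        warning("observer callback failed (", abort_msg,
                "): session aborted, partial results returned",
                call. = FALSE)
        break
      }
      recs <- classify_chart(chart, clicked)
      records[[ci]] <- rbind(records[[ci]], recs)
      tg_levels <- sort(unique(recs$level[recs$is_target]))
      last_levels[[ci]] <- tg_levels
      # cumulative refit on all charts completed so far for this set
      fit <- fit_psychometric(records[[ci]], dprime_max = config$dprime_max)
      fits[[ci]] <- fit
      trajectory[[ci]][[r]] <- fit
      audit[[length(audit) + 1L]] <- data.frame(
        component_labels = paste(config$components[[ci]], collapse = ";"),
        chart = r, seed = sd_c, adaptive = adaptive,
        n_targets = chart$n_targets, capped = capped,
        levels = paste(signif(tg_levels, 6), collapse = ";"),
        theta_running = if (fit$converged) fit$params$theta else NA_real_,
        converged = fit$converged)
    }
  }

  estimates <- do.call(rbind, lapply(seq_len(n_comp), function(ci) {
    fit <- fits[[ci]]
    ok <- isTRUE(fit$converged)
    data.frame(
      component_labels = paste(config$components[[ci]], collapse = ";"),
      theta_hat = if (ok) fit$params$theta else NA_real_,
      se_theta = if (ok) unname(fit$se[["theta"]]) else NA_real_,
      gamma_hat = if (ok) fit$params$gamma else NA_real_,
      false_alarm_hat = if (ok) fit$params$false_alarm else NA_real_,
      converged = ok,
      n_charts_used = length(trajectory[[ci]]))
  }))

  structure(
    list(records = do.call(rbind, records), estimates = estimates,
         fits = fits, trajectory = trajectory,
         audit = do.call(rbind, audit), config = config, seed = seed,
         aborted = aborted, abort_message = abort_msg),
    class = "find_session")
}

#' @export
print.find_session <- function(x, ...) {
  cat(sprintf("find_session: %d component set(s), %d charts each, seed %d\n",
              length(x$config$components), x$config$n_charts, x$seed))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
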