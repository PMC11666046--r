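#' Simulated observer
#'
#' A generative observer governed by the same psychometric model the
#' engine fits, used to close the adaptive loop for parameter recovery and
#' for the in-silico summation experiment. Each component channel has a
#' true threshold and slope; responses are Bernoulli draws from the
#' model's yes-probability, optionally contaminated by a lapse rate
#' (probability of a random 50:50 response, modelling inattention).
#'
#' Combination rules for pairs whose component set has more than one
#' element:
#' \describe{
#'   \item{`euclidean`}{the per-component differences combine as Euclidean
#'     distance in face space before the d-prime transducer: with each of
#'     `m` target components changed by the test level `S`, the effective
#'     level is `S * sqrt(m)`. Two equally detectable components therefore
#'     reduce the threshold by exactly `sqrt(2)`, the classical
#'     probability-summation benchmark. The channel parameters of the
#'     first listed target component are used; the benchmark presumes the
#'     components share theta and gamma.}
#'   \item{`single`}{the extra components are ignored (effective level =
#'     `S` through the first component's channel) — the no-facilitation
#'     null model.}
#'   \item{`dprime_quadrature`}{each channel's d-prime is computed at `S`
#'     and combined as the root sum of squares after the saturating
#'     transducer, then passed to the decision stage. Near threshold this
#'     gives a ratio slightly below sqrt(2); provided for sensitivity
#'     analysis.}
#' }
#'
#' @param theta True threshold(s): a single value applying to every
#'   component, or a named numeric vector keyed by 1-based component index.
#' @param gamma True slope(s), recycled like `theta`.
#' @param false_alarm True false alarm rate.
#' @param lapse Lapse rate in `[0, 0.1]` (default 0); lapses respond
#'   yes/no with equal probability.
#' @param rule Combination rule, see Details.
#' @param dprime_max Saturating d-prime.
#' @return An object of class `simulated_observer`.
#' @examples
#' obs <- simulated_observer(theta = c("1" = 4, "2" = 3.5), false_alarm = 0.05)
#' @export
simulated_observer <- function(theta, gamma = 1, false_alarm = 0.05,
                               lapse = 0,
                               rule = c("euclidean", "single",
                                        "dprime_quadrature"),
                               dprime_max = 5) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(theta), all(theta > 0),
            is.numeric(gamma), all(gamma > 0),
            length(lapse) == 1L, lapse >= 0, lapse <= 0.1)
  structure(
    list(theta = theta, gamma = gamma, false_alarm = false_alarm,
         lapse = lapse, rule = rule, dprime_max = dprime_max),
    class = "simulated_observer")
}

#' @export
print.simulated_observer <- function(x, ...) {
  cat(sprintf(
    "simulated_observer: rule = %s, F = %g, lapse = %g, %d channel(s)\n",
    x$rule, x$false_alarm, x$lapse, length(x$theta)))
  invisible(x)
}

observer_channel <- function(observer, component) {
  pick <- function(v) {
    if (length(v) == 1L && is.null(names(v))) return(unname(v))
    val <- v[as.character(component)]
    if (is.na(val)) {
      stop("observer has no parameters for component ", component,
           call. = FALSE)
    }
    unname(val)
  }
  list(theta = pick(observer$theta), gamma = pick(observer$gamma))
}

#' Simulated yes/no response to a face pair
#'
#' Draws a Bernoulli response with probability
#' `(1 - lapse) * p_yes(S_eff) + lapse / 2`, where the effective level
#' `S_eff` follows the observer's combination rule. Null pairs
#' (`S_eff = 0`) answer yes at the (lapse-mixed) false alarm rate.
#' Randomness comes from R's global RNG.
#'
#' @param pair A [make_face_pair()] result (or any chart cell's `pair`).
#' @param observer A [simulated_observer()].
#' @return `TRUE` for a "different people" response.
#' @export
respond <- function(pair, observer) {
  stopifnot(inherits(observer, "simulated_observer"))
  p <- response_probability(pair$target_components, pair$test_level, observer)
  stats::runif(1L) < p
}

# Yes-probability for a component set at a given per-component test level.
response_probability <- function(target_components, level, observer) {
  m <- length(target_components)
  first <- observer_channel(observer,
                            if (m) target_components[1L] else NA_integer_)
  if (level == 0 || m == 0L) {
    p_signal <- observer$false_alarm
  } else if (observer$rule == "dprime_quadrature" && m > 1L) {
    d_each <- vapply(target_components, function(cm) {
      ch <- observer_channel(observer, cm)
      dprime(level, psychometric_params(ch$theta, ch$gamma,
                                        observer$false_alarm,
                                        observer$dprime_max))
    }, 0)
    d_eff <- sqrt(sum(d_each^2))
    p_signal <- 1 - stats::pnorm(stats::qnorm(1 - clamp_f(observer$false_alarm)) -
                                   d_eff)
  } else {
    s_eff <- switch(observer$rule,
                    euclidean = level * sqrt(m),
                    single = level,
                    dprime_quadrature = level)
    p_signal <- p_yes(s_eff, psychometric_params(first$theta, first$gamma,
                                                 observer$false_alarm,
                                                 observer$dprime_max))
  }
  (1 - observer$lapse) * p_signal + observer$lapse / 2
}

clamp_f <- function(f, eps = 1e-4) min(max(f, eps), 1 - eps)

#' Neighboring component-set designs
#'
#' Helpers for the single versus combined design: `single_sets(n)` gives
#' the singleton sets 1..n; `neighbor_sets(n)` gives the circular
#' neighboring pairs \{1,2\}, \{2,3\}, ..., \{n,1\}.
#'
#' @param n Number of components (default 10, the most discriminable
#'   components of the face model).
#' @return A list of integer vectors.
#' @export
single_sets <- function(n = 10L) as.list(seq_len(as.integer(n)))

#' @rdname single_sets
#' @export
neighbor_sets <- function(n = 10L) {
  n <- as.integer(n)
  lapply(seq_len(n), function(i) c(i, i %% n + 1L))
}

#' Simulate a cohort of adaptive sessions
#'
#' Runs [run_session()] once per observer under a shared configuration,
#' with per-observer child seeds split from the master seed, and stacks
#' the threshold estimates. With the default single + neighboring-pair
#' component sets this reproduces the single/combined design in silico.
#'
#' @param config A [session_config()]; its `components` field defines the
#'   conditions every observer completes.
#' @param observers List of [simulated_observer()] objects (one per
#'   simulated participant).
#' @param seed Master seed (defaults to `config$seed`).
#' @return An object of class `find_cohort`: `estimates` (the per-session
#'   estimate rows with an `observer` id column prepended) and `sessions`
#'   (the full [run_session()] results).
#' @export
simulate_cohort <- function(config, observers, seed = config$seed) {
  stopifnot(length(observers) >= 1L)
  if (is.null(seed)) stop("a master `seed` is required", call. = FALSE)
  sessions <- lapply(seq_along(observers), function(j) {
    run_session(observers[[j]], config,
                seed = child_seed(seed, 1000L + j, 0L))
  })
  estimates <- do.call(rbind, lapply(seq_along(sessions), function(j) {
    cbind(observer = j, sessions[[j]]$estimates)
  }))
  structure(list(estimates = estimates, sessions = sessions,
                 config = config, seed = seed),
            class = "find_cohort")
}

#' @export
print.find_cohort <- function(x, ...) {
  cat(sprintf("find_cohort: %d observer(s) x %d component set(s), seed %d\n",
              length(x$sessions), length(x$config$components), x$seed))
  invisible(x)
}

#' Threshold matrix from a cohort
#'
#' Reshapes a cohort's estimates into an observers x component-sets matrix
#' of threshold estimates, columns ordered and named as in
#' `config$components`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param sets Optional list of component sets to extract (default: all in
#'   the cohort's configuration).
#' @return Numeric matrix, `NA` where a fit did not converge.
#' @export
cohort_thresholds <- function(cohort, sets = NULL) {
  stopifnot(inherits(cohort, "find_cohort"))
  sets <- sets %||% cohort$config$components
  labels <- vapply(sets, function(s) paste(s, collapse = ";"), "")
  est <- cohort$estimates
  n_obs <- length(cohort$sessions)
  out <- matrix(NA_real_, n_obs, length(labels),
                dimnames = list(NULL, labels))
  for (j in seq_len(n_obs)) {
    sub <- est[est$observer == j, ]
    out[j, ] <- sub$theta_hat[match(labels, sub$component_labels)]
  }
  out
}
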