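#' Psychometric model parameters
#'
#' Container for the parameters of the saturating d-prime psychometric
#' function used throughout the package:
#' \deqn{d'(S) = \frac{d'_{max} (S/\theta)^\gamma}
#'   {\sqrt{(d'_{max}^2 - 1) + (S/\theta)^{2\gamma}}}}
#' followed by the yes/no decision stage
#' \deqn{p(\mathrm{Yes}) = 1 - \Phi(\Phi^{-1}(1 - F) - d'(S)).}
#' The threshold \eqn{\theta} is the test level (face-space distance in
#' standard-deviation units of the face model) at which \eqn{d' = 1};
#' \eqn{\gamma} is the slope; \eqn{F} is the false alarm rate, the
#' probability of a "different" response to an identical (null) face pair;
#' \eqn{d'_{max}} is the saturation ceiling of discriminability, fixed at 5
#' by default.
#'
#' @param theta Threshold, in standard-deviation units. Must be positive.
#' @param gamma Slope exponent, dimensionless. Must be positive.
#' @param false_alarm False alarm rate \eqn{F}. Clamped to
#'   \eqn{[10^{-4}, 1 - 10^{-4}]} so the decision stage stays finite.
#' @param dprime_max Saturating value of d-prime. Must exceed 1.
#'
#' @return An object of class `psychometric_params`.
#' @examples
#' p <- psychometric_params(theta = 4, gamma = 1, false_alarm = 0.1)
#' dprime(4, p)      # exactly 1 at threshold
#' p_yes(0, p)       # exactly the false alarm rate at zero signal
#' @export
psychometric_params <- function(theta, gamma = 1, false_alarm = 0.05,
                                dprime_max = 5) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(false_alarm), length(false_alarm) == 1L,
            is.finite(false_alarm),
            is.numeric(dprime_max), length(dprime_max) == 1L)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (dprime_max <= 1) stop("`dprime_max` must be > 1", call. = FALSE)
  eps <- 1e-4
  false_alarm <- min(max(false_alarm, eps), 1 - eps)
  structure(
    list(theta = theta, gamma = gamma, false_alarm = false_alarm,
         dprime_max = dprime_max),
    class = "psychometric_params"
  )
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf(
    "psychometric_params: theta = %.4g, gamma = %.4g, F = %.4g, d'max = %g\n",
    x$theta, x$gamma, x$false_alarm, x$dprime_max))
  invisible(x)
}

#' Discriminability as a function of test level
#'
#' The saturating d-prime transducer. Strictly increasing in `level`,
#' equal to 1 at `level == theta`, and bounded above by `dprime_max`.
#'
#' @param level Test level(s), standard-deviation units; must be >= 0.
#' @param params A [psychometric_params()] object.
#' @return Numeric vector of d-prime values, same length as `level`.
#' @export
dprime <- function(level, params) {
  stopifnot(inherits(params, "psychometric_params"), is.numeric(level))
  if (any(level < 0)) stop("`level` must be >= 0", call. = FALSE)
  dm <- params$dprime_max
  x <- (level / params$theta)^params$gamma
  dm * x / sqrt((dm^2 - 1) + x^2)
}

#' Probability of a "different" (yes) response
#'
#' Decision stage on top of [dprime()]: `1 - pnorm(qnorm(1 - F) - dprime)`.
#' At zero signal this equals the false alarm rate exactly.
#'
#' @inheritParams dprime
#' @return Probabilities in (0, 1), same length as `level`.
#' @export
p_yes <- function(level, params) {
  d <- dprime(level, params)
  p <- 1 - stats::pnorm(stats::qnorm(1 - params$false_alarm) - d)
  # anchor the zero-signal response at F exactly (no cancellation error)
  p[d == 0] <- params$false_alarm
  p
}

#' Test level at which a target discriminability is reached
#'
#' Closed-form inverse of [dprime()]:
#' \deqn{S = \theta \left[\frac{d^2 (d'_{max}^2 - 1)}
#'   {d'_{max}^2 - d^2}\right]^{1/(2\gamma)}.}
#' Used by the adaptive engine to place stimuli at prescribed d-prime
#' values. Levels diverge as `d_target` approaches `dprime_max`, so
#' requests at or above the ceiling signal a saturation error.
#'
#' @param d_target Target d-prime value(s), `0 <= d_target < dprime_max`.
#' @param params A [psychometric_params()] object.
#' @return Test level(s) such that `dprime(level, params) == d_target`.
#' @export
invert_dprime <- function(d_target, params) {
  stopifnot(inherits(params, "psychometric_params"), is.numeric(d_target))
  if (any(d_target < 0)) stop("`d_target` must be >= 0", call. = FALSE)
  dm <- params$dprime_max
  if (any(d_target >= dm)) {
    stop("saturation: `d_target` must be < dprime_max (", dm, ")",
         call. = FALSE)
  }
  params$theta *
    (d_target^2 * (dm^2 - 1) / (dm^2 - d_target^2))^(1 / (2 * params$gamma))
}
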