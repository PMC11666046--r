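# Independent inverse of the d-prime transducer by bisection, used to
# cross-check the closed-form invert_dprime().
bisect_invert_dprime <- function(d_target, params, tol = 1e-12) {
  lo <- 0
  hi <- params$theta
  while (dprime(hi, params) < d_target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (dprime(mid, params) < d_target) lo <- mid else hi <- mid
    if (hi - lo < tol * max(hi, 1)) break
  }
  (lo + hi) / 2
}

# Bernoulli response records drawn directly from the psychometric model at
# fixed levels (bypasses chart construction; for fitter tests).
simulate_records <- function(params, levels, n_per_level, n_null,
                             true_f = params$false_alarm) {
  tg <- do.call(rbind, lapply(levels, function(l) {
    data.frame(level = l, is_target = TRUE,
               response_yes = stats::runif(n_per_level) < p_yes(l, params))
  }))
  nl <- data.frame(level = 0, is_target = FALSE,
                   response_yes = stats::runif(n_null) < true_f)
  rbind(tg, nl)
}
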