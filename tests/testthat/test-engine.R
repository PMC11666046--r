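test_that("initial levels are geometrically spaced over the configured range", {
  cfg <- session_config(initial_levels = list(n_steps = 5L, min_level = 0.5,
                                              max_level = 16))
  lv <- initial_levels(cfg)
  expect_length(lv, 5L)
  expect_equal(lv[1], 0.5)
  expect_equal(lv[5], 16)
  expect_equal(diff(log(lv)), rep(diff(log(lv))[1], 4))
  cfg2 <- session_config(initial_levels = list(n_steps = 2L, min_level = 1,
                                               max_level = 8))
  expect_equal(initial_levels(cfg2), c(1, 8))
  expect_error(session_config(initial_levels = list(n_steps = 5L,
                                                    min_level = 4,
                                                    max_level = 2)),
               "initial_levels")
})

test_that("chart classification follows the signal-detection table", {
  set.seed(12)
  ch <- build_chart(1, c(1, 2, 4, 8, 12, 16), 1L,
                    target_fraction = c(2/3, 2/3))  # exactly 6 targets
  is_tg <- vapply(ch$cells, function(c) c$pair$is_target, TRUE)
  pos <- lapply(ch$cells, function(c) c$pos)
  # click 3 targets and 1 null
  clicked <- c(pos[which(is_tg)[1:3]], pos[which(!is_tg)[1]])
  rec <- classify_chart(ch, clicked)
  expect_identical(nrow(rec), 9L)
  tab <- table(rec$outcome)
  expect_identical(as.integer(tab[c("Hit", "Miss", "FalseAlarm",
                                    "CorrectRejection")]),
                   c(3L, 3L, 1L, 2L))
  # perfect observer and silent observer
  perfect <- classify_chart(ch, pos[is_tg])
  expect_identical(sum(perfect$outcome == "Hit"), 6L)
  expect_identical(sum(perfect$outcome == "CorrectRejection"), 3L)
  silent <- classify_chart(ch, NULL)
  expect_identical(sum(silent$outcome == "Miss"), 6L)
  expect_identical(sum(silent$outcome == "CorrectRejection"), 3L)
  expect_error(classify_chart(ch, list(c(4, 1))), "outside the grid")
})

test_that("adaptive placement inverts an equally spaced d-prime grid", {
  cfg <- session_config()
  fit <- structure(list(params = psychometric_params(1, 1, 0.05),
                        converged = TRUE),
                   class = "psychometric_fit")
  lv <- next_chart_levels(fit, cfg, 5L)
  expect_equal(dprime(as.numeric(lv), fit$params),
               c(0.1, 1.2, 2.3, 3.4, 4.5), tolerance = 1e-9)
  expect_equal(as.numeric(lv)[5], 10.11513, tolerance = 1e-5)
  expect_equal(dprime(as.numeric(next_chart_levels(fit, cfg, 2L)),
                      fit$params), c(0.1, 4.5), tolerance = 1e-9)
  # scale equivariance: doubling theta doubles every level (below the cap)
  cfg_hi <- session_config(level_cap = 100)
  fit2 <- structure(list(params = psychometric_params(2, 1, 0.05),
                         converged = TRUE),
                    class = "psychometric_fit")
  expect_equal(as.numeric(next_chart_levels(fit2, cfg_hi, 5L)),
               2 * as.numeric(next_chart_levels(fit, cfg_hi, 5L)),
               tolerance = 1e-12)
  # the cap bounds runaway placements and is reported
  fit_big <- structure(list(params = psychometric_params(40, 1, 0.05),
                            converged = TRUE),
                       class = "psychometric_fit")
  lv_big <- next_chart_levels(fit_big, cfg, 5L)
  expect_true(all(lv_big <= cfg$level_cap))
  expect_gt(attr(lv_big, "capped"), 0)
  bad <- structure(list(converged = FALSE), class = "psychometric_fit")
  expect_error(next_chart_levels(bad, cfg, 5L), "not converged")
})

test_that("sessions are bitwise reproducible under the master seed", {
  obs <- simulated_observer(theta = 4, gamma = 1, false_alarm = 0.05)
  cfg <- session_config(components = list(1L, 3L), n_charts = 2L)
  s1 <- run_session(obs, cfg, seed = 31)
  s2 <- run_session(obs, cfg, seed = 31)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$estimates, s2$estimates)
  s3 <- run_session(obs, cfg, seed = 32)
  expect_false(identical(s1$records, s3$records))
})

test_that("refits are strictly cumulative across charts", {
  obs <- simulated_observer(theta = 4, gamma = 1, false_alarm = 0.05)
  cfg <- session_config(components = list(1L))
  s <- run_session(obs, cfg, seed = 7)
  n_rec <- vapply(s$trajectory[[1]], function(f) f$n_records, 0L)
  expect_identical(n_rec, 9L * (1:4))
  expect_identical(nrow(s$records), 36L)
  expect_identical(s$estimates$theta_hat,
                   s$trajectory[[1]][[4]]$params$theta)
})

test_that("a deterministic level-threshold observer is recovered near its step", {
  step_obs <- function(pair) pair$test_level > 4
  cfg <- session_config(components = list(1L))
  s <- run_session(step_obs, cfg, seed = 7)
  expect_true(s$estimates$converged)
  expect_gt(s$estimates$theta_hat, 2)
  expect_lt(s$estimates$theta_hat, 6)
  # placement range shrinks toward the step across charts
  expect_true(all(s$audit$adaptive[-1]))
})

test_that("a random observer yields a flagged, unusable estimate", {
  set.seed(55)
  rand_obs <- function(pair) runif(1) < 0.5
  s <- run_session(rand_obs, session_config(components = list(1L)), seed = 9)
  est <- s$estimates
  expect_true(!est$converged || est$se_theta > est$theta_hat ||
                est$false_alarm_hat > 0.3)
})

test_that("observer callback failure aborts with partial results preserved", {
  n_calls <- 0
  flaky <- function(pair) {
    n_calls <<- n_calls + 1
    if (n_calls > 20) stop("front-end lost connection")
    pair$test_level > 4
  }
  cfg <- session_config(components = list(1L))
  expect_warning(s <- run_session(flaky, cfg, seed = 3), "aborted")
  expect_true(s$aborted)
  expect_gt(nrow(s$records), 0L)
  expect_lt(nrow(s$records), 36L)
})
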