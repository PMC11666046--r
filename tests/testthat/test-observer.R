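test_that("null pairs are answered at the false alarm rate", {
  obs <- simulated_observer(theta = 4, gamma = 1, false_alarm = 0.12)
  base <- local({set.seed(1); face_vector()})
  pair <- local({set.seed(1); make_face_pair(base, 1, 0)})
  set.seed(2)
  rate <- mean(replicate(10000, respond(pair, obs)))
  se <- sqrt(0.12 * 0.88 / 10000)
  expect_lt(abs(rate - 0.12), 3 * se)
})

test_that("a component at its own threshold is detected at Phi(1) when F = 0.5", {
  obs <- simulated_observer(theta = 4, gamma = 1, false_alarm = 0.5)
  set.seed(3)
  pair <- make_face_pair(face_vector(), 1, 4)
  rate <- mean(replicate(10000, respond(pair, obs)))
  se <- sqrt(pnorm(1) * (1 - pnorm(1)) / 10000)
  expect_lt(abs(rate - pnorm(1)), 3 * se)
})

test_that("euclidean rule equates two components at delta with one at delta*sqrt(2)", {
  obs <- simulated_observer(theta = 4, gamma = 1.3, false_alarm = 0.05,
                            rule = "euclidean")
  for (delta in c(1, 2.5, 6)) {
    expect_equal(findface:::response_probability(c(1, 2), delta, obs),
                 findface:::response_probability(1, delta * sqrt(2), obs),
                 tolerance = 1e-12)
  }
  # single rule ignores the extra component
  obs_s <- simulated_observer(theta = 4, gamma = 1.3, false_alarm = 0.05,
                              rule = "single")
  expect_equal(findface:::response_probability(c(1, 2), 2, obs_s),
               findface:::response_probability(1, 2, obs_s),
               tolerance = 1e-12)
  # d-prime quadrature lies between the single and euclidean rules
  obs_q <- simulated_observer(theta = 4, gamma = 1.3, false_alarm = 0.05,
                              rule = "dprime_quadrature")
  p_q <- findface:::response_probability(c(1, 2), 2, obs_q)
  expect_gt(p_q, findface:::response_probability(1, 2, obs_s))
  expect_lt(p_q, findface:::response_probability(c(1, 2), 2, obs))
})

test_that("per-component parameters are looked up by 1-based index", {
  obs <- simulated_observer(theta = c("3" = 2, "7" = 8), gamma = 1,
                            false_alarm = 0.05)
  p3 <- findface:::response_probability(3, 2, obs)   # at its threshold
  p7 <- findface:::response_probability(7, 2, obs)   # well below threshold
  expect_gt(p3, p7)
  set.seed(1)
  pair <- make_face_pair(face_vector(), 5, 2)
  expect_error(respond(pair, obs), "component 5")
})

test_that("lapses mix a 50:50 guess into the response", {
  obs <- simulated_observer(theta = 1, gamma = 1, false_alarm = 0.05,
                            lapse = 0.1)
  # far above threshold the yes-rate saturates at 1 - lapse/2
  p_hi <- findface:::response_probability(1, 50, obs)
  expect_lt(p_hi, 1 - 0.1 / 2 + 1e-9)
  expect_gt(p_hi, 1 - 0.1 / 2 - 0.01)
  # null pairs rise toward lapse/2 above the pure false alarm rate
  expect_equal(findface:::response_probability(1, 0, obs),
               0.9 * 0.05 + 0.05, tolerance = 1e-12)
  expect_error(simulated_observer(theta = 1, lapse = 0.3), "lapse")
})

test_that("cohorts stack one session per observer, deterministically", {
  obs <- replicate(2, simulated_observer(theta = 4, gamma = 1,
                                         false_alarm = 0.05),
                   simplify = FALSE)
  cfg <- session_config(components = c(single_sets(2), neighbor_sets(2)),
                        n_charts = 2L, seed = 17)
  coh <- simulate_cohort(cfg, obs)
  expect_identical(nrow(coh$estimates), 8L)   # 2 observers x 4 sets
  expect_identical(sort(unique(coh$estimates$component_labels)),
                   sort(c("1", "2", "1;2", "2;1")))
  coh2 <- simulate_cohort(cfg, obs)
  expect_identical(coh$estimates, coh2$estimates)
  m <- cohort_thresholds(coh)
  expect_identical(dim(m), c(2L, 4L))
  expect_identical(colnames(m), c("1", "2", "1;2", "2;1"))
})

test_that("neighboring component-set designs wrap circularly", {
  expect_identical(single_sets(3), list(1L, 2L, 3L))
  expect_identical(neighbor_sets(3), list(c(1L, 2L), c(2L, 3L), c(3L, 1L)))
})
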