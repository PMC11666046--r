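test_that("face vectors are 199 + 199 standard-normal coordinates", {
  set.seed(1)
  v <- face_vector()
  expect_length(v$structural, 199)
  expect_length(v$textural, 199)
  expect_true(all(is.finite(c(v$structural, v$textural))))
  set.seed(99); a <- face_vector()
  set.seed(99); b <- face_vector()
  expect_identical(a, b)
  # law-of-large-numbers check on the first structural component
  set.seed(2)
  draws <- replicate(10000, face_vector(n_components = 2L)$structural[1])
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(abs(sd(draws) - 1), 0.05)
})

test_that("face pairs split the test level symmetrically on target components", {
  set.seed(5)
  base <- face_vector()
  pr <- make_face_pair(base, target_components = 4, test_level = 6)
  expect_true(pr$is_target)
  diff <- pr$structural_right - pr$structural_left
  expect_identical(which(diff != 0), 4L)
  expect_equal(abs(diff[4]), 6)
  # base coordinates sit at the midpoint
  expect_equal((pr$structural_left + pr$structural_right) / 2,
               base$structural)
  expect_identical(pr$textural, base$textural)

  # combined components move by the same signed amount -> Euclidean sqrt(2)
  pr2 <- make_face_pair(base, target_components = c(1, 2), test_level = 3)
  d2 <- pr2$structural_right - pr2$structural_left
  expect_identical(which(d2 != 0), c(1L, 2L))
  expect_identical(d2[1], d2[2])
  expect_equal(sqrt(sum(d2^2)), 3 * sqrt(2))

  # null pair: identical realized faces
  pr0 <- make_face_pair(base, target_components = 4, test_level = 0)
  expect_false(pr0$is_target)
  expect_identical(pr0$structural_left, pr0$structural_right)

  expect_error(make_face_pair(base, 200, 1), "1-based")
  expect_error(make_face_pair(base, 4, -1), "test_level")
})

test_that("yaw jitter is drawn per face from the configured range", {
  set.seed(8)
  frontal <- make_face_pair(face_vector(), 1, 2)
  expect_identical(c(frontal$yaw_left, frontal$yaw_right), c(0, 0))
  yaws <- replicate(200, {
    p <- make_face_pair(face_vector(), 1, 2, yaw_range = c(-5, 5))
    c(p$yaw_left, p$yaw_right)
  })
  expect_true(all(yaws >= -5 & yaws <= 5))
  expect_gt(max(abs(yaws[1, ] - yaws[2, ])), 1)  # independent draws
})

test_that("chart target counts follow round(u * 9) on the drawn fraction", {
  set.seed(3)
  counts <- replicate(400, build_chart(1, function(k) rep(1, k), 1L)$n_targets)
  expect_true(all(counts %in% 5:7))
  # degenerate fraction forces the rounding exactly
  set.seed(4)
  forced <- replicate(50, build_chart(1, function(k) rep(1, k), 1L,
                                      target_fraction = c(2/3, 2/3))$n_targets)
  expect_true(all(forced == 6))
  expect_error(build_chart(1, function(k) rep(1, k), 1L,
                           target_fraction = c(0.2, 1.5)), "target_fraction")
  expect_error(build_chart(1, c(1, 2), 1L), "fewer levels")
})

test_that("chart cells have fresh bases, permuted positions, assigned levels", {
  set.seed(6)
  lv <- c(0.5, 1, 2, 4, 8, 12, 16)
  ch <- build_chart(3, lv, target_components = c(2, 3))
  expect_identical(ch$component_under_test, c(2L, 3L))
  expect_length(ch$cells, 9L)
  pos <- t(vapply(ch$cells, function(c) c$pos, c(0L, 0L)))
  expect_identical(nrow(unique(pos)), 9L)
  bases <- vapply(ch$cells, function(c) c$pair$base$structural[1], 0)
  expect_identical(length(unique(bases)), 9L)
  tg_lv <- sort(vapply(Filter(function(c) c$pair$is_target, ch$cells),
                       function(c) c$pair$test_level, 0))
  expect_identical(tg_lv, sort(lv[seq_len(ch$n_targets)]))
  n_null <- sum(!vapply(ch$cells, function(c) c$pair$is_target, TRUE))
  expect_identical(n_null + ch$n_targets, 9L)
})

test_that("chart specs round-trip losslessly through JSON", {
  set.seed(9)
  ch <- build_chart(2, c(1, 2, 4, 8, 12, 16, 20), c(1, 7),
                    yaw_range = c(-5, 5))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  export_chart_spec(ch, path)
  back <- import_chart_spec(path)
  expect_equal(back, ch)
  # realized coordinates and geometry survive bit-exactly
  for (i in seq_along(ch$cells)) {
    expect_identical(back$cells[[i]]$pair$structural_left,
                     ch$cells[[i]]$pair$structural_left)
    expect_identical(back$cells[[i]]$pair$structural_right,
                     ch$cells[[i]]$pair$structural_right)
    expect_identical(back$cells[[i]]$pair$textural,
                     ch$cells[[i]]$pair$textural)
    expect_identical(back$cells[[i]]$pair$test_level,
                     ch$cells[[i]]$pair$test_level)
  }
  # null cells serialize with level 0 and identical realized vectors
  null_cells <- Filter(function(c) !c$pair$is_target, back$cells)
  expect_true(length(null_cells) >= 2L)
  for (cell in null_cells) {
    expect_identical(cell$pair$test_level, 0)
    expect_identical(cell$pair$structural_left, cell$pair$structural_right)
  }
  # per-face yaws survive in degrees
  yl <- vapply(back$cells, function(c) c$pair$yaw_left, 0)
  expect_true(all(abs(yl) <= 5) && any(yl != 0))
})
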