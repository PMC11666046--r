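#' Draw a random face-space coordinate vector
#'
#' A face is specified by 199 structural and 199 textural principal-component
#' coordinates, each in standard-deviation units of the morphable face model
#' and drawn as independent standard-normal deviates. Randomness comes from
#' R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param n_components Number of components per array (199 for the Basel-style
#'   face space).
#' @return An object of class `face_vector`: a list with numeric fields
#'   `structural` and `textural`, each of length `n_components`.
#' @export
face_vector <- function(n_components = 199L) {
  structure(
    list(structural = stats::rnorm(n_components),
         textural = stats::rnorm(n_components)),
    class = "face_vector"
  )
}

#' @export
print.face_vector <- function(x, ...) {
  cat(sprintf("face_vector: %d structural + %d textural components (sd units)\n",
              length(x$structural), length(x$textural)))
  invisible(x)
}

#' Construct a face pair for one chart cell
#'
#' Realizes the two faces of a cell from a shared base vector. For a target
#' pair (`test_level > 0`), half of the test level is subtracted from each
#' target component for one face and added for the other — which face gets
#' the positive half is chosen at random — so the two realized structural
#' vectors differ by exactly `test_level` on every target component, with
#' the same sign across components, and are identical elsewhere. Textural
#' coordinates are shared. A null pair (`test_level == 0`) has two identical
#' faces. Each face's yaw (horizontal rotation, degrees) is drawn
#' independently and uniformly from `yaw_range`; the degenerate range
#' `c(0, 0)` gives frontal pose.
#'
#' @param base A [face_vector()] providing the shared coordinates.
#' @param target_components Integer vector of 1-based structural component
#'   indices that differ between the two faces.
#' @param test_level Total structural difference per target component,
#'   standard-deviation units; must be >= 0.
#' @param yaw_range Length-2 numeric, degrees; per-face yaw is drawn
#'   uniformly from this interval.
#' @return An object of class `face_pair` with fields `base`,
#'   `target_components`, `test_level`, `yaw_left`, `yaw_right`, `is_target`
#'   and the realized vectors `structural_left`, `structural_right`,
#'   `textural`.
#' @examples
#' set.seed(1)
#' pr <- make_face_pair(face_vector(), target_components = 4, test_level = 6)
#' which(pr$structural_left != pr$structural_right)  # only component 4
#' @export
make_face_pair <- function(base, target_components, test_level,
                           yaw_range = c(0, 0)) {
  stopifnot(inherits(base, "face_vector"),
            is.numeric(test_level), length(test_level) == 1L,
            is.finite(test_level),
            is.numeric(yaw_range), length(yaw_range) == 2L)
  if (test_level < 0) stop("`test_level` must be >= 0", call. = FALSE)
  n <- length(base$structural)
  target_components <- as.integer(target_components)
  if (length(target_components) &&
      (any(target_components < 1L) || any(target_components > n))) {
    stop("`target_components` must be 1-based indices in 1..", n,
         call. = FALSE)
  }
  left <- right <- base$structural
  if (test_level > 0) {
    # the same signed half-offset is applied to every target component
    s <- sample(c(-1, 1), 1L)
    left[target_components] <- left[target_components] - s * test_level / 2
    right[target_components] <- right[target_components] + s * test_level / 2
  }
  yaws <- stats::runif(2L, yaw_range[1L], yaw_range[2L])
  structure(
    list(base = base,
         target_components = target_components,
         test_level = test_level,
         yaw_left = yaws[1L], yaw_right = yaws[2L],
         is_target = test_level > 0,
         structural_left = left,
         structural_right = right,
         textural = base$textural),
    class = "face_pair"
  )
}

#' Generate one chart of face pairs
#'
#' Builds a grid (default 3 x 3, 6-degree cells with 3-degree gaps) of face
#' pairs for a single component set under test. The number of target cells
#' is `round(u * n_cells)` with `u` drawn uniformly from `target_fraction`
#' (at the default interval (0.6, 0.8) on 9 cells this yields 5, 6 or 7
#' targets). Every cell receives an independent fresh base vector, so pairs
#' differ from each other in all components; target levels are assigned from
#' `levels`, null cells get level 0, and cell positions are randomly
#' shuffled.
#'
#' @param chart_index Integer chart number (>= 1), recorded in responses.
#' @param levels Either a numeric vector of candidate test levels (an error
#'   is signalled if fewer than the drawn target count) or a
#'   `function(k)` returning `k` levels once the target count is known.
#' @param target_components Integer vector: the component set varied on this
#'   chart (all target cells share it).
#' @param target_fraction Length-2 interval in (0, 1) from which the target
#'   fraction `u` is drawn; may be degenerate.
#' @param grid Length-2 integer `c(rows, cols)`.
#' @param yaw_range Passed to [make_face_pair()].
#' @param cell_size_deg,gap_deg Display geometry carried in the spec for
#'   renderers (degrees of visual angle).
#' @return An object of class `chart_spec`: fields `chart_index`, `grid`,
#'   `cell_size_deg`, `gap_deg`, `component_under_test`, `n_targets` and
#'   `cells`, a list of `list(pos = c(row, col), pair = <face_pair>)`.
#' @export
build_chart <- function(chart_index, levels, target_components,
                        target_fraction = c(0.6, 0.8), grid = c(3L, 3L),
                        yaw_range = c(0, 0), cell_size_deg = 6, gap_deg = 3) {
  stopifnot(length(grid) == 2L, all(grid >= 1L),
            length(target_fraction) == 2L)
  if (target_fraction[1L] <= 0 || target_fraction[2L] >= 1 ||
      target_fraction[1L] > target_fraction[2L]) {
    stop("`target_fraction` must satisfy 0 < low <= high < 1", call. = FALSE)
  }
  n_cells <- prod(grid)
  u <- stats::runif(1L, target_fraction[1L], target_fraction[2L])
  k <- as.integer(round(u * n_cells))
  if (is.function(levels)) {
    lv <- levels(k)
  } else {
    if (length(levels) < k) {
      stop("fewer levels (", length(levels), ") than drawn target count (",
           k, ")", call. = FALSE)
    }
    lv <- levels[seq_len(k)]
  }
  if (any(lv <= 0)) stop("target levels must be > 0", call. = FALSE)
  cell_levels <- c(lv, rep(0, n_cells - k))
  pairs <- lapply(cell_levels, function(l) {
    make_face_pair(face_vector(), target_components, l, yaw_range)
  })
  pos <- expand.grid(row = seq_len(grid[1L]), col = seq_len(grid[2L]))
  perm <- sample.int(n_cells)
  cells <- lapply(seq_len(n_cells), function(i) {
    j <- perm[i]
    list(pos = c(pos$row[j], pos$col[j]), pair = pairs[[i]])
  })
  structure(
    list(chart_index = as.integer(chart_index),
         grid = as.integer(grid),
         cell_size_deg = cell_size_deg, gap_deg = gap_deg,
         component_under_test = as.integer(target_components),
         n_targets = k,
         cells = cells),
    class = "chart_spec"
  )
}

#' @export
print.chart_spec <- function(x, ...) {
  cat(sprintf(
    "chart_spec #%d: %dx%d grid, component set {%s}, %d targets / %d nulls\n",
    x$chart_index, x$grid[1L], x$grid[2L],
    paste(x$component_under_test, collapse = ","),
    x$n_targets, prod(x$grid) - x$n_targets))
  invisible(x)
}

#' Export a chart specification as renderer-agnostic JSON
#'
#' Serializes a chart so an external morphable-model renderer can draw the
#' faces: grid geometry, per-cell position, target flag, test level, target
#' components (1-based), per-face yaw in degrees, and the realized
#' structural/textural coordinate arrays at full floating-point precision.
#' [import_chart_spec()] reverses the operation losslessly.
#'
#' @param chart A [build_chart()] result.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
export_chart_spec <- function(chart, path = NULL) {
  stopifnot(inherits(chart, "chart_spec"))
  doc <- list(
    schema_version = 1L,
    chart_index = chart$chart_index,
    grid = list(rows = chart$grid[1L], cols = chart$grid[2L],
                cell_deg = chart$cell_size_deg, gap_deg = chart$gap_deg),
    component_under_test = I(chart$component_under_test),
    cells = lapply(chart$cells, function(cell) {
      p <- cell$pair
      list(pos = I(cell$pos),
           is_target = p$is_target,
           test_level = p$test_level,
           target_components = I(p$target_components),
           yaw = I(c(p$yaw_left, p$yaw_right)),
           structural_left = I(p$structural_left),
           structural_right = I(p$structural_right),
           textural = I(p$textural))
    })
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Import a chart specification from JSON
#'
#' @param x A JSON string or a path to a file written by
#'   [export_chart_spec()].
#' @return A `chart_spec` object equal to the exported chart (the shared
#'   `base` vector of each pair is reconstructed from the realized faces).
#' @export
import_chart_spec <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cells <- lapply(doc$cells, function(cell) {
    tc <- as.integer(cell$target_components)
    left <- as.numeric(cell$structural_left)
    right <- as.numeric(cell$structural_right)
    base_struct <- left
    # mid-point restores the base coordinates on the target components
    base_struct[tc] <- (left[tc] + right[tc]) / 2
    base <- structure(list(structural = base_struct,
                           textural = as.numeric(cell$textural)),
                      class = "face_vector")
    pair <- structure(
      list(base = base,
           target_components = tc,
           test_level = as.numeric(cell$test_level),
           yaw_left = as.numeric(cell$yaw[1L]),
           yaw_right = as.numeric(cell$yaw[2L]),
           is_target = isTRUE(cell$is_target),
           structural_left = left,
           structural_right = right,
           textural = base$textural),
      class = "face_pair")
    list(pos = as.integer(cell$pos), pair = pair)
  })
  structure(
    list(chart_index = as.integer(doc$chart_index),
         grid = c(as.integer(doc$grid$rows), as.integer(doc$grid$cols)),
         cell_size_deg = doc$grid$cell_deg, gap_deg = doc$grid$gap_deg,
         component_under_test = as.integer(doc$component_under_test),
         n_targets = sum(vapply(cells, function(c) c$pair$is_target, TRUE)),
         cells = cells),
    class = "chart_spec"
  )
}
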