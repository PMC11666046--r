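#' Single versus combined probability-summation analysis
#'
#' Compares thresholds for single components against thresholds for
#' neighboring component pairs. Each combined set \{i, i+1\} is referenced
#' against the mean (default) or minimum of the two corresponding single
#' thresholds; participant-level means are formed across sets, and the
#' headline ratio is mean(single) / mean(combined) on those participant
#' means. If distances along the component axes combine Euclideanly, two
#' equally detectable components should lower the threshold by a factor
#' sqrt(2), so the per-participant ratios are additionally tested against
#' sqrt(2) (ratios above it would indicate superadditive facilitation).
#'
#' @param single Matrix of thresholds, participants x single components
#'   (columns in component order 1..n).
#' @param combined Matrix of thresholds, participants x combined sets;
#'   column `j` is the set \{j, j+1\} (circular), unless `pairs` overrides.
#' @param pairs Optional list of length `ncol(combined)` giving, for each
#'   combined set, the two single-component column indices it references.
#' @param reference `"mean"` (default, each combined set vs the mean of
#'   its two singles) or `"min"` (vs the better single).
#' @return An object of class `summation_result`: `mean_single`,
#'   `mean_combined`, `ratio`, `per_participant` (data frame with
#'   participant means and ratios), `paired_t` (single vs combined:
#'   statistic, df, p), `ratio_vs_sqrt2` (one-sample t on the ratios:
#'   statistic, df, p), `reference`.
#' @export
summation_analysis <- function(single, combined, pairs = NULL,
                               reference = c("mean", "min")) {
  reference <- match.arg(reference)
  single <- as.matrix(single)
  combined <- as.matrix(combined)
  if (nrow(single) != nrow(combined)) {
    stop("`single` and `combined` must have the same number of participants",
         call. = FALSE)
  }
  n_p <- nrow(single)
  if (n_p < 2L) stop("need at least 2 participants", call. = FALSE)
  n_c <- ncol(combined)
  pairs <- pairs %||% lapply(seq_len(n_c),
                             function(j) c(j, j %% ncol(single) + 1L))
  if (length(pairs) != n_c) {
    stop("`pairs` must have one entry per combined column", call. = FALSE)
  }
  ref_fun <- if (reference == "mean") {
    function(a, b) (a + b) / 2
  } else {
    pmin
  }
  single_ref <- vapply(seq_len(n_c), function(j) {
    ref_fun(single[, pairs[[j]][1L]], single[, pairs[[j]][2L]])
  }, numeric(n_p))
  single_ref <- matrix(single_ref, nrow = n_p)

  mean_single_p <- rowMeans(single_ref)
  mean_combined_p <- rowMeans(combined)
  ratios_p <- mean_single_p / mean_combined_p

  paired <- safe_one_sample_t(mean_single_p - mean_combined_p, 0)
  ratio_t <- safe_one_sample_t(ratios_p, sqrt(2))

  structure(
    list(mean_single = mean(mean_single_p),
         mean_combined = mean(mean_combined_p),
         ratio = mean(mean_single_p) / mean(mean_combined_p),
         per_participant = data.frame(participant = seq_len(n_p),
                                      mean_single = mean_single_p,
                                      mean_combined = mean_combined_p,
                                      ratio = ratios_p),
         paired_t = paired,
         ratio_vs_sqrt2 = ratio_t,
         reference = reference),
    class = "summation_result")
}

# one-sample t robust to (numerically) constant input: exactly-on-target
# data give t = 0 (p = 1), off-target constant data a signed infinite
# statistic (p = 0)
safe_one_sample_t <- function(x, mu) {
  n <- length(x)
  tt <- tryCatch(stats::t.test(x, mu = mu), error = function(e) NULL)
  if (!is.null(tt) && is.nan(tt$statistic)) tt <- NULL
  if (is.null(tt)) {
    if (isTRUE(all.equal(mean(x), mu))) {
      return(list(statistic = 0, df = n - 1L, p = 1))
    }
    return(list(statistic = sign(mean(x) - mu) * Inf, df = n - 1L, p = 0))
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' @export
print.summation_result <- function(x, ...) {
  cat(sprintf(
    "summation_result: mean single %.3f, mean combined %.3f, ratio %.4f (ref: %s)\n",
    x$mean_single, x$mean_combined, x$ratio, x$reference))
  cat(sprintf("  paired t(%d) = %.3f, p = %.4g; ratio vs sqrt(2): t(%d) = %.3f, p = %.4g\n",
              x$paired_t$df, x$paired_t$statistic, x$paired_t$p,
              x$ratio_vs_sqrt2$df, x$ratio_vs_sqrt2$statistic,
              x$ratio_vs_sqrt2$p))
  invisible(x)
}

#' Bland-Altman test-retest agreement
#'
#' Assesses agreement between two repeated threshold measurements:
#' differences are `test - retest`, bias is their mean, limits of
#' agreement are `bias +/- 1.96 * sd(differences)`, the bias test is a
#' one-sample t on the differences, and proportional bias is checked by
#' ordinary least-squares regression of the differences on the pairwise
#' means with a t-test on the slope.
#'
#' @param test,retest Paired numeric vectors of equal length `n >= 3`.
#' @return An object of class `bland_altman_result`: `differences`,
#'   `means`, `bias`, `sd_diff`, `limits` (lower, upper), `bias_test`
#'   (statistic, df, p; `NA` when the differences are constant), and
#'   `slope_test` (slope, statistic, p; slope is 0 with `NA` p when the
#'   regression is degenerate).
#' @export
bland_altman <- function(test, retest) {
  stopifnot(is.numeric(test), is.numeric(retest))
  if (length(test) != length(retest)) {
    stop("`test` and `retest` must have equal length", call. = FALSE)
  }
  n <- length(test)
  if (n < 3L) stop("need at least 3 paired measurements", call. = FALSE)
  d <- test - retest
  m <- (test + retest) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  limits <- c(lower = bias - 1.96 * sd_d, upper = bias + 1.96 * sd_d)

  bias_test <- if (sd_d > 0) {
    tt <- tryCatch(stats::t.test(d), error = function(e) NULL)
    if (is.null(tt)) {
      # numerically constant nonzero differences: certain bias
      list(statistic = sign(bias) * Inf, df = n - 1L, p = 0)
    } else {
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
    }
  } else {
    list(statistic = NA_real_, df = n - 1L, p = NA_real_)
  }

  slope_test <- if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    # constant differences give a perfect fit; the summary warning about
    # unreliable significance is the expected degenerate outcome
    cf <- suppressWarnings(summary(fit))$coefficients
    list(slope = unname(cf["m", "Estimate"]),
         statistic = unname(cf["m", "t value"]),
         p = unname(cf["m", "Pr(>|t|)"]))
  } else {
    list(slope = 0, statistic = NA_real_, p = NA_real_)
  }

  structure(
    list(differences = d, means = m, bias = bias, sd_diff = sd_d,
         limits = limits, bias_test = bias_test, slope_test = slope_test,
         n = n),
    class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "bland_altman_result: n = %d, bias = %.4f, limits [%.4f, %.4f]\n",
    x$n, x$bias, x$limits[["lower"]], x$limits[["upper"]]))
  cat(sprintf("  bias t = %.3f (p = %.4g); slope = %.4f (p = %.4g)\n",
              x$bias_test$statistic, x$bias_test$p,
              x$slope_test$slope, x$slope_test$p))
  invisible(x)
}

#' @export
plot.bland_altman_result <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "mean of test and retest",
                 ylab = "difference (test - retest)",
                 main = "Bland-Altman", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = x$limits, lty = 2)
  invisible(x)
}

#' Two-group threshold comparison
#'
#' Student t-test (pooled variance when unpaired) with Cohen's d: pooled-SD
#' d for independent groups, difference-SD d for paired data.
#'
#' @param a,b Numeric threshold vectors (equal length when `paired`).
#' @param paired Paired comparison?
#' @return List with `statistic`, `df`, `p`, `d` (Cohen's d) and `paired`.
#' @export
group_compare <- function(a, b, paired = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired comparison needs equal lengths", call. = FALSE)
    }
    d_vec <- a - b
    if (stats::sd(d_vec) == 0) {
      stop("degenerate paired input: zero difference variance", call. = FALSE)
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    eff <- mean(d_vec) / stats::sd(d_vec)
  } else {
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0) {
      stop("degenerate input: zero variance in both groups", call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    sp <- sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
                 (length(a) + length(b) - 2))
    eff <- (mean(a) - mean(b)) / sp
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = eff, paired = paired)
}
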