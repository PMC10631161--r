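# Method-comparison statistics: Levene's homogeneity-of-variance test
# followed by Student's (pooled) or Welch's t-test, plus Tukey boxplot
# summaries of per-case metric samples.

#' Levene's test for homogeneity of variance
#'
#' Classical (mean-centred) Levene test for two samples: a one-way ANOVA F
#' statistic on the absolute deviations from each group's mean, with
#' (1, n1 + n2 - 2) degrees of freedom.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
levene_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs at least 2 values")
  za <- abs(a - mean(a))
  zb <- abs(b - mean(b))
  n1 <- length(za); n2 <- length(zb); n <- n1 + n2
  zbar <- (sum(za) + sum(zb)) / n
  between <- n1 * (mean(za) - zbar)^2 + n2 * (mean(zb) - zbar)^2
  within <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  df <- c(1, n - 2)
  if (within == 0) {
    # all deviations identical within groups; equal group means of |dev|
    # mean no evidence against homogeneity
    stat <- if (between == 0) 0 else Inf
    p <- if (between == 0) 1 else 0
  } else {
    stat <- (n - 2) * between / within
    p <- stats::pf(stat, df[1], df[2], lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, df = df)
}

#' Levene-gated two-sample t-test
#'
#' The comparison procedure: Levene's test first checks homogeneity of
#' variance; when it does not reject (`levene_p > alpha`) a pooled-variance
#' Student's t-test is used, otherwise the Welch approximation. Two-sided.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @param levene_p Levene p-value; computed from `a`, `b` when `NULL`.
#' @param alpha Homogeneity rejection level (default 0.05).
#' @param paired Paired t-test on differences (requires equal lengths;
#'   default unpaired).
#' @return List of class `comparison_result`: `levene_statistic`,
#'   `levene_p`, `t_statistic`, `t_p`, `df`, `variance_assumption`
#'   (`"pooled"` or `"welch"`), `mean_difference` (mean(a) - mean(b)).
#' @export
t_test <- function(a, b, levene_p = NULL, alpha = 0.05, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs at least 2 values")
  lev <- levene_test(a, b)
  if (is.null(levene_p)) levene_p <- lev$p_value
  pooled <- levene_p > alpha
  if (paired) {
    if (length(a) != length(b)) stop("paired comparison requires equal sample sizes")
    if (stats::var(a - b) == 0) {
      # constant differences: no within-pair variability
      md <- mean(a - b)
      ht <- list(statistic = c(t = if (md == 0) 0 else sign(md) * Inf),
                 p.value = if (md == 0) 1 else 0,
                 parameter = c(df = length(a) - 1))
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
    }
    assumption <- "paired"
  } else if (stats::var(a) + stats::var(b) == 0) {
    # degenerate: both samples constant
    ht <- list(statistic = c(t = 0), p.value = 1,
               parameter = c(df = length(a) + length(b) - 2))
    if (mean(a) != mean(b)) ht$statistic[] <- sign(mean(a) - mean(b)) * Inf
    if (mean(a) != mean(b)) ht$p.value <- 0
    assumption <- "pooled"
  } else {
    ht <- stats::t.test(a, b, var.equal = pooled)
    assumption <- if (pooled) "pooled" else "welch"
  }
  structure(list(levene_statistic = lev$statistic, levene_p = levene_p,
                 t_statistic = unname(ht$statistic), t_p = ht$p.value,
                 df = unname(ht$parameter), variance_assumption = assumption,
                 mean_difference = mean(a) - mean(b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Levene F = %.4g (p = %.4g) -> %s t-test\n",
              x$levene_statistic, x$levene_p, x$variance_assumption))
  cat(sprintf("t = %.4g, df = %.4g, two-sided p = %.4g, mean difference = %.4g\n",
              x$t_statistic, x$df, x$t_p, x$mean_difference))
  invisible(x)
}

#' Tukey boxplot summary
#'
#' Mean, median, linearly interpolated quartiles (type 7), 1.5 IQR whiskers
#' clipped to the data, and the outliers beyond them.
#'
#' @param x Non-empty numeric sample.
#' @return List of class `box_summary`: `mean`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
box_summary <- function(x) {
  if (length(x) == 0) stop("empty sample")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(list(mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(x[inside]), whisker_high = max(x[inside]),
                 outliers = sort(x[!inside])),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf("mean %.4g | q1 %.4g median %.4g q3 %.4g | whiskers [%.4g, %.4g] | %d outlier(s)\n",
              x$mean, x$q1, x$median, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

#' Compare two methods' per-case metrics
#'
#' Runs the Levene-then-t procedure for each shared metric column of two
#' per-case metric tables (as produced by [evaluate_cases()]).
#'
#' @param metrics_a,metrics_b Data frames with columns among `dsc`, `iou`,
#'   `hausdorff`, `asd`, `mae`.
#' @param alpha Levene rejection level.
#' @return Named list of [t_test()] results per metric.
#' @export
compare_methods <- function(metrics_a, metrics_b, alpha = 0.05) {
  cols <- intersect(c("dsc", "iou", "hausdorff", "asd", "mae"),
                    intersect(names(metrics_a), names(metrics_b)))
  if (length(cols) == 0) stop("no shared metric columns")
  out <- lapply(cols, function(cl) {
    a <- metrics_a[[cl]]; b <- metrics_b[[cl]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    t_test(a, b, alpha = alpha)
  })
  names(out) <- cols
  out
}
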