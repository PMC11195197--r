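# Peak-height statistics and partnership-dependence categorization.

#' Mean peak height
#'
#' @param heights Numeric vector of nonnegative peak heights (FPKM).
#' @return Arithmetic mean.
#' @export
mean_height <- function(heights) {
  if (length(heights) == 0L) stop("cannot take the mean of zero heights")
  if (any(!is.finite(heights)) || any(heights < 0)) {
    stop("heights must be finite and nonnegative")
  }
  mean(heights)
}

#' Unpaired two-sample t-test with pooled variance
#'
#' Two-sided t-test assuming equal variance, with `n_a + n_b - 2` degrees
#' of freedom, plus per-group means and quartiles. Degenerate inputs: if
#' the pooled variance is zero and the means are equal, `t = 0` and
#' `p = 1` by convention; zero pooled variance with unequal means is an
#' error.
#'
#' @param a,b Numeric vectors (at least 2 values each).
#' @param label_a,label_b Group labels for reporting.
#' @return Object of class `group_comparison` with fields `labels`, `n`,
#'   `means`, `quartiles` (matrix, one column per group), `t_statistic`,
#'   `df`, `p_value`.
#' @examples
#' pooled_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
pooled_t_test <- function(a, b, label_a = "a", label_b = "b") {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  n_a <- length(a); n_b <- length(b)
  df <- n_a + n_b - 2L
  sp2 <- ((n_a - 1L) * stats::var(a) + (n_b - 1L) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) {
      t_stat <- 0; p <- 1
    } else {
      stop("zero pooled variance with unequal means: t statistic undefined")
    }
  } else {
    t_stat <- dm / sqrt(sp2 * (1 / n_a + 1 / n_b))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(
    labels = c(label_a, label_b),
    n = c(n_a, n_b),
    means = c(mean(a), mean(b)),
    quartiles = cbind(stats::quantile(a, c(0.25, 0.5, 0.75)),
                      stats::quantile(b, c(0.25, 0.5, 0.75))),
    t_statistic = t_stat, df = df, p_value = p
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean %.4g) vs %s (n=%d, mean %.4g): t=%.4g, df=%d, p=%s\n",
              x$labels[1], x$n[1], x$means[1],
              x$labels[2], x$n[2], x$means[2],
              x$t_statistic, x$df, format(signif(x$p_value, 2))))
  invisible(x)
}

#' Categorize partnership dependence of a peak
#'
#' Classifies a peak by comparing wild-type and partnership-defective
#' (Y479A) peak heights at a fold threshold: `lower` if the mutant height
#' times the threshold is at most the wild-type height, `higher` in the
#' mirror case, otherwise `unchanged`. When the input table already carries
#' a category column that label takes precedence and this rule is not used;
#' the computed rule is a stand-in for synthetic data.
#'
#' @param height_wt,height_mut Nonnegative peak heights (FPKM); vectorized.
#' @param fold_threshold Fold change (> 1) required to call a direction;
#'   default 1.5.
#' @return Character vector in `{"lower","higher","unchanged"}`.
#' @examples
#' categorize_y479(1000, 400)  # "lower"
#' @export
categorize_y479 <- function(height_wt, height_mut, fold_threshold = 1.5) {
  stopifnot(fold_threshold > 1, all(height_wt >= 0), all(height_mut >= 0))
  out <- rep("unchanged", length(height_wt))
  out[height_mut * fold_threshold <= height_wt] <- "lower"
  out[height_wt * fold_threshold <= height_mut] <- "higher"
  out[height_wt == 0 & height_mut == 0] <- "unchanged"
  out
}

#' Compare peak heights of adjacent-FBE peaks against all peaks
#'
#' The headline occupancy comparison: mean height of peaks with qualifying
#' adjacent element pairs versus all scanned peaks, with the pooled
#' two-sample t-test. Optionally splits the adjacent-FBE peaks by
#' partnership-dependence category (using the `category` column when
#' present, else [categorize_y479] on `height_wt`/`height_mut`).
#'
#' @param scan An `fbe_scan` from [scan_peaks].
#' @param by_category Also compare lower vs unchanged categories among
#'   adjacent-FBE peaks (default `TRUE` when the information is available).
#' @param fold_threshold Passed to [categorize_y479] when no category
#'   column is present.
#' @return List with `all_vs_adjacent` (a `group_comparison`) and, when
#'   computed, `category_comparison` plus the category counts.
#' @export
compare_peak_heights <- function(scan, by_category = TRUE,
                                 fold_threshold = 1.5) {
  stopifnot(inherits(scan, "fbe_scan"))
  pk <- scan$peaks
  adj <- pk[pk$has_pair, , drop = FALSE]
  if (nrow(adj) < 2L) stop("need at least 2 adjacent-FBE peaks to compare")
  res <- list(all_vs_adjacent = pooled_t_test(
    adj$height_wt, pk$height_wt,
    label_a = "adjacent_fbe_peaks", label_b = "all_peaks"))
  has_cat <- "category" %in% names(adj) && !all(is.na(adj$category))
  has_mut <- "height_mut" %in% names(adj) && !all(is.na(adj$height_mut))
  if (by_category && (has_cat || has_mut)) {
    cat_lab <- if (has_cat) adj$category else
      categorize_y479(adj$height_wt, adj$height_mut, fold_threshold)
    res$category_counts <- table(factor(
      cat_lab, levels = c("lower", "higher", "unchanged")))
    lower <- adj$height_wt[cat_lab == "lower"]
    unchanged <- adj$height_wt[cat_lab == "unchanged"]
    if (length(lower) >= 2L && length(unchanged) >= 2L) {
      res$category_comparison <- pooled_t_test(
        lower, unchanged, label_a = "lower_in_y479a",
        label_b = "unchanged_in_y479a")
    }
  }
  res
}
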