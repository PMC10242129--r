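# Nonparametric contrast statistics. The analysis is nonparametric
# throughout: the KS gate documents the (expected) rejection of normality,
# after which paired contrasts use the Wilcoxon signed-rank test and
# unpaired contrasts the rank-sum test, both two-sided.

contrast_result <- function(test, statistic, p_value, n, alpha = 0.05,
                            note = NA_character_) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, alpha = alpha,
                 significant = is.finite(p_value) && p_value < alpha,
                 note = note),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic), ", p = ",
      format.pval(x$p_value, digits = 4), if (x$significant) " *" else "",
      "  (n = ", paste(x$n, collapse = ", "), ")\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Kolmogorov-Smirnov normality gate
#'
#' Tests the sample against a normal distribution with the sample's own
#' mean and SD. The pipeline proceeds nonparametrically regardless of the
#' outcome; the gate documents the distributional check.
#'
#' @param x Numeric sample, `n >= 8`.
#' @param alpha Significance level (default 0.05).
#' @return A `contrast_result` (test `"ks_normality"`).
#' @export
ks_normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 8L)
    stop("normality gate requires n >= 8, got ", length(x))
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  contrast_result("ks_normality", ks$statistic, ks$p.value, length(x),
                  alpha)
}

#' Paired contrast (Wilcoxon signed rank)
#'
#' Two-sided signed-rank test of `post - baseline`, paired by electrode
#' pair. Exact p-values when `n <= 25` with no ties or zero differences;
#' otherwise the normal approximation with tie/zero handling and
#' continuity correction. If every difference is zero there is no signal
#' and p = 1 by convention.
#'
#' @param baseline_values,post_values Equal-length paired samples.
#' @param alpha Significance level (default 0.05).
#' @return A `contrast_result` (test `"wilcoxon_signed_rank"`).
#' @export
paired_contrast <- function(baseline_values, post_values, alpha = 0.05) {
  if (length(baseline_values) != length(post_values))
    stop("paired samples must have equal length")
  d <- post_values - baseline_values
  if (all(d == 0))
    return(contrast_result("wilcoxon_signed_rank", statistic = 0,
                           p_value = 1, n = length(d), alpha,
                           note = "all differences zero"))
  nz <- d[d != 0]
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz)) && all(d != 0)
  wt <- suppressWarnings(
    stats::wilcox.test(post_values, baseline_values, paired = TRUE,
                       exact = exact, correct = TRUE))
  contrast_result("wilcoxon_signed_rank", wt$statistic, wt$p.value,
                  length(d), alpha,
                  note = if (!exact) "normal approximation" else
                    NA_character_)
}

#' Unpaired contrast (Wilcoxon rank sum)
#'
#' Two-sided rank-sum test with tie correction; exact for small samples
#' without ties.
#'
#' @param group1,group2 Numeric samples, each of size >= 3.
#' @param alpha Significance level (default 0.05).
#' @return A `contrast_result` (test `"wilcoxon_rank_sum"`).
#' @export
unpaired_contrast <- function(group1, group2, alpha = 0.05) {
  if (length(group1) < 3L || length(group2) < 3L)
    stop("each group requires n >= 3")
  exact <- length(group1) + length(group2) <= 50L &&
    !anyDuplicated(c(group1, group2))
  wt <- suppressWarnings(
    stats::wilcox.test(group1, group2, exact = exact, correct = TRUE))
  contrast_result("wilcoxon_rank_sum", wt$statistic, wt$p.value,
                  c(length(group1), length(group2)), alpha,
                  note = if (!exact) "normal approximation" else
                    NA_character_)
}
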