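# Shared statistical kernel. All cohort comparisons in the pipeline reduce to
# a two-sided Wilcoxon rank-sum test with BH-FDR adjustment; mutation
# prevalence contrasts use Fisher's exact test. The surface below wraps the
# classical base R implementations and pins down the edge cases the pipeline
# relies on (constant data, degenerate tables, tie handling).

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration is used when both groups are small and there are no ties;
#' otherwise a tie-corrected normal approximation with continuity correction.
#' Constant pooled data (all values identical) returns p = 1.
#'
#' @param x,y Numeric vectors for groups A and B (both non-empty).
#' @param mode `"auto"` (exact when `min(n) <= exact_threshold` and no ties),
#'   `"exact"`, or `"normal_approx"`.
#' @param exact_threshold Group-size bound for the exact path in auto mode.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx"),
                              exact_threshold = 25L) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    validation_error("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) validation_error("missing values in test input")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0L
  exact <- switch(mode,
    auto = min(length(x), length(y)) <= exact_threshold && !ties,
    exact = !ties,  # exact enumeration is undefined with ties; mid-rank normal
    normal_approx = FALSE)
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  p <- unname(res$p.value)
  if (is.na(p)) 1 else min(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure; output order matches input order.
#'
#' @param p_values Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than the observed table's.
#' Tables with a zero margin give p = 1.
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, c, b, d), 2, 2)` i.e.
#'   rows are feature status, columns are cohorts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    validation_error("Fisher cell counts must be non-negative integers")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  unname(stats::fisher.test(m)$p.value)
}

#' Per-feature two-cohort comparison
#'
#' Runs a two-sided Wilcoxon rank-sum test on every row of a features-by-
#' samples matrix, reports the effect as the difference of group means on the
#' matrix's own scale (for log2 expression this is the log fold change of
#' geometric means), and adjusts p-values across all tested features by BH.
#'
#' @param matrix Numeric features-by-samples matrix with rownames and colnames.
#' @param labels Cohort labels, one per column (two levels), or a named vector
#'   matched to colnames. The first level (alphabetical, or of the factor) is
#'   group A; `effect = mean(A) - mean(B)`.
#' @param group_a Optionally name the label value to treat as group A.
#' @param mode Passed to [wilcoxon_rank_sum].
#' @return Data frame: `feature_id`, `effect`, `p_value`, `q_value`,
#'   `direction` (`"up_in_a"` / `"up_in_b"` / `"none"`), `n_a`, `n_b`.
#' @export
compare_feature_matrix <- function(matrix, labels, group_a = NULL,
                                   mode = "auto") {
  if (is.null(rownames(matrix)))
    validation_error("feature matrix needs rownames")
  if (!is.null(names(labels))) labels <- labels[colnames(matrix)]
  labels <- as.character(labels)
  if (length(labels) != ncol(matrix))
    validation_error("one label per sample required")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) validation_error("exactly two cohort labels required")
  if (!is.null(group_a)) {
    if (!group_a %in% lev) validation_error("group_a not among labels")
    lev <- c(group_a, setdiff(lev, group_a))
  }
  ia <- labels == lev[1]
  ib <- labels == lev[2]
  effect <- rowMeans(matrix[, ia, drop = FALSE]) -
    rowMeans(matrix[, ib, drop = FALSE])
  p <- vapply(seq_len(nrow(matrix)), function(i) {
    wilcoxon_rank_sum(matrix[i, ia], matrix[i, ib], mode = mode)
  }, 0)
  q <- bh_adjust(p)
  data.frame(feature_id = rownames(matrix),
             effect = unname(effect),
             p_value = p,
             q_value = q,
             direction = ifelse(effect > 0, "up_in_a",
                                ifelse(effect < 0, "up_in_b", "none")),
             n_a = sum(ia), n_b = sum(ib),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a comparison result table
#'
#' @param results Data frame from [compare_feature_matrix] (or any of the
#'   differential wrappers built on it).
#' @param path TSV path.
#' @export
write_comparison <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
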