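# Marker-gene immune cell scoring. Each immune cell population is summarised
# per sample as the arithmetic mean of its marker genes' log2 expression
# (the Danaher approach); a total-TIL row averages over all panel genes.

#' Tumor-infiltrating leukocyte scores
#'
#' For every cell type in the panel, the score of a sample is the mean of the
#' cell type's marker genes' log2 expression values in that sample. Panel
#' genes missing from the matrix are dropped (with a message reporting the
#' count); a cell type with no matched marker raises an error naming it. A
#' `total_TIL` row holds the mean over all matched panel genes.
#'
#' @param expr An [expr_matrix] or genes-by-samples log2 matrix.
#' @param panel A `marker_panel` (default: the bundled Danaher-style panel).
#' @param total_over `"genes"` (default: total TIL = mean over all matched
#'   panel genes) or `"cell_types"` (mean of the per-cell-type scores).
#' @return Cell-types-by-samples matrix with a final `total_TIL` row.
#' @export
til_scores <- function(expr, panel = default_marker_panel(),
                       total_over = c("genes", "cell_types")) {
  total_over <- match.arg(total_over)
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  matched <- lapply(panel, function(g) intersect(g, rownames(m)))
  n_missing <- sum(lengths(panel)) - sum(lengths(matched))
  if (n_missing > 0L)
    log_note("til_scores: %d panel gene(s) absent from the matrix", n_missing)
  empty <- names(matched)[lengths(matched) == 0L]
  if (length(empty) > 0L)
    validation_error(paste("no marker gene present for cell type(s):",
                           paste(empty, collapse = ", ")))
  scores <- t(vapply(matched, function(g) {
    colMeans(m[g, , drop = FALSE])
  }, numeric(ncol(m))))
  total <- if (total_over == "genes") {
    colMeans(m[unique(unlist(matched)), , drop = FALSE])
  } else {
    colMeans(scores)
  }
  out <- rbind(scores, total_TIL = total)
  colnames(out) <- colnames(m)
  out
}

#' Compare TIL scores between cohorts
#'
#' Mean score difference (cohort A minus cohort B) plus two-sided Wilcoxon
#' p-values, BH-adjusted across all score rows (the cell types and the
#' total-TIL row together).
#'
#' @param scores Matrix from [til_scores].
#' @param labels Cohort labels, one per sample / named by sample.
#' @param q_threshold FDR threshold for the `status` column.
#' @param group_a Label value treated as cohort A.
#' @return Data frame as from [compare_feature_matrix] plus `status`.
#' @export
compare_til <- function(scores, labels, q_threshold = 0.05, group_a = NULL) {
  res <- compare_feature_matrix(scores, labels, group_a = group_a)
  res$status <- ifelse(res$q_value < q_threshold, res$direction, "ns")
  res
}
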