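# Single-sample pathway scoring by gene set variation analysis (GSVA) and
# cohort-level differential pathway analysis.
#
# The scoring follows the published GSVA algorithm: (1) for every gene,
# estimate the cumulative density of its expression across samples (Gaussian
# kernel with bandwidth sd/4, or the empirical CDF); (2) within each sample,
# rank genes by the density-transformed value and form the symmetric rank
# statistic |p/2 - rank|; (3) walk down the ranked gene list accumulating
# weighted increments for set members and constant decrements for non-members;
# (4) the enrichment score is the sum of the largest positive and largest
# negative deviation of the walk (the "max.diff" statistic), which lies in
# [-1, 1].

#' GSVA single-sample pathway scores
#'
#' @param expr An [expr_matrix] or plain genes-by-samples matrix of log2
#'   expression (at least 2 samples: the density step pools across samples).
#' @param collection A `gene_set_collection`.
#' @param tau Exponent on the symmetric rank statistic weighting the random
#'   walk (default 1, the reference implementation's default).
#' @param kernel `"gaussian"` (kernel CDF with bandwidth sd/4, for continuous
#'   log-expression) or `"ecdf"` (empirical CDF; scores then depend on the
#'   data only through per-gene ranks).
#' @param min_size,max_size Bounds on the effective set size (after
#'   intersection with the matrix genes); sets outside the bounds are skipped
#'   and their names reported in a message.
#' @param max_diff If `TRUE` (default) the score is the sum of the maximum
#'   positive and maximum negative running deviations; if `FALSE`, the single
#'   largest-magnitude deviation.
#' @return Sets-by-samples numeric matrix of scores in `[-1, 1]`, with the
#'   collection's immune flags (subset to scored sets) in `attr(, "immune")`.
#' @export
gsva_scores <- function(expr, collection, tau = 1,
                        kernel = c("gaussian", "ecdf"),
                        min_size = 10L, max_size = 500L, max_diff = TRUE) {
  kernel <- match.arg(kernel)
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (ncol(m) < 2L)
    validation_error("GSVA needs at least 2 samples to estimate densities")
  p <- nrow(m)
  n <- ncol(m)

  sets <- lapply(collection$sets, function(g) which(rownames(m) %in% g))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    log_note("gsva_scores: skipping %d set(s) outside size bounds: %s",
             sum(!keep), paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  if (length(sets) == 0L)
    validation_error("no gene set within the size bounds")

  # per-gene density-transformed expression levels
  z <- matrix(0, p, n, dimnames = dimnames(m))
  for (i in seq_len(p)) {
    x <- m[i, ]
    if (kernel == "gaussian") {
      h <- stats::sd(x) / 4
      if (h <= 0 || !is.finite(h)) {
        z[i, ] <- 0.5
      } else {
        z[i, ] <- colMeans(stats::pnorm(outer(x, x, FUN = function(a, b) (b - a) / h)))
      }
    } else {
      z[i, ] <- (rank(x, ties.method = "average")) / n
    }
  }

  # per-sample gene ranks (1 = highest transformed value) and symmetric stat
  scores <- matrix(NA_real_, length(sets), n,
                   dimnames = list(names(sets), colnames(m)))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)         # walk order
    r <- integer(p); r[ord] <- seq_len(p)           # rank of each gene
    s <- abs(p / 2 - r)^tau
    s_ord <- s[ord]
    for (k in seq_along(sets)) {
      member <- logical(p)
      member[sets[[k]]] <- TRUE
      mem_ord <- member[ord]
      denom_in <- sum(s_ord[mem_ord])
      denom_out <- p - length(sets[[k]])
      if (denom_in <= 0) denom_in <- 1  # all member weights zero: flat walk
      step <- ifelse(mem_ord, s_ord / denom_in, -1 / denom_out)
      walk <- cumsum(step)
      max_pos <- max(0, max(walk))
      max_neg <- min(0, min(walk))
      scores[k, j] <- if (max_diff) max_pos + max_neg else {
        if (max_pos >= -max_neg) max_pos else max_neg
      }
    }
  }
  attr(scores, "immune") <- collection$immune[rownames(scores)]
  scores
}

#' Differential pathway analysis between cohorts
#'
#' Compares each gene set's GSVA scores between the two cohorts (two-sided
#' Wilcoxon, BH across sets); the effect is the mean score difference
#' (cohort A minus cohort B). Each set is annotated with its immune flag so
#' the immune share of the significant sets can be read off directly.
#'
#' @param scores Sets-by-samples score matrix from [gsva_scores].
#' @param labels Cohort labels (two levels), one per sample / named by sample.
#' @param q_threshold FDR threshold for the `status` classification.
#' @param group_a Label value treated as cohort A.
#' @param immune Optional named logical overriding `attr(scores, "immune")`.
#' @return Data frame as from [compare_feature_matrix] plus `status` and
#'   `immune` columns.
#' @export
differential_pathways <- function(scores, labels, q_threshold = 0.05,
                                  group_a = NULL, immune = NULL) {
  res <- compare_feature_matrix(scores, labels, group_a = group_a)
  res$status <- ifelse(res$q_value < q_threshold, res$direction, "ns")
  flags <- immune %||% attr(scores, "immune")
  res$immune <- if (is.null(flags)) FALSE else unname(flags[res$feature_id])
  res
}

#' Pairwise comparison against individual cancer types
#'
#' Compares a reference cohort against each cancer type of the other cohort
#' separately, keeping only types with at least `min_patients` samples.
#' BH adjustment is applied within each pairwise comparison (matching
#' per-panel q-values), not globally.
#'
#' @param feature_matrix Features-by-samples matrix (genes, pathway scores or
#'   TIL scores).
#' @param type_labels Per-sample group labels: the reference label for
#'   reference-cohort samples and the cancer type for the rest.
#' @param reference_label The label of the reference group.
#' @param min_patients Minimum size for a cancer type to be compared.
#' @return Named list (one element per retained cancer type) of comparison
#'   data frames; `effect > 0` means higher in the reference group.
#' @export
pairwise_type_comparison <- function(feature_matrix, type_labels,
                                     reference_label, min_patients = 10L) {
  if (!is.null(names(type_labels)))
    type_labels <- type_labels[colnames(feature_matrix)]
  type_labels <- as.character(type_labels)
  if (!reference_label %in% type_labels)
    validation_error("reference_label absent from type labels")
  ref_idx <- type_labels == reference_label
  counts <- table(type_labels[!ref_idx])
  types <- names(counts)[counts >= min_patients]
  out <- lapply(types, function(ty) {
    idx <- ref_idx | type_labels == ty
    sub <- feature_matrix[, idx, drop = FALSE]
    compare_feature_matrix(sub, type_labels[idx], group_a = reference_label)
  })
  stats::setNames(out, types)
}
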