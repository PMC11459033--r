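# Transcriptome-level stages: variance-based gene selection, cohort
# differential expression on log2 TPM, hypergeometric over-representation
# analysis, and an optional UMAP embedding for visualisation.

#' Select the most variant genes
#'
#' Ranks genes by the standard deviation of their log2 expression across ALL
#' samples (both cohorts pooled) and returns the `n` genes with the largest
#' SD. Ties are broken deterministically by gene identifier (lexicographic,
#' C locale).
#'
#' @param expr An [expr_matrix] (or plain numeric matrix with gene rownames).
#' @param n Number of genes to keep; must not exceed the gene count.
#' @return Character vector of `n` gene identifiers.
#' @export
select_top_variant_genes <- function(expr, n) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (n > nrow(m)) validation_error("n exceeds the number of genes")
  if (n < 1L) validation_error("n must be at least 1")
  sds <- apply(m, 1L, stats::sd)
  ord <- order_c_locale(-sds, rownames(m))
  rownames(m)[ord[seq_len(n)]]
}

#' Differential expression between two cohorts
#'
#' Restricts the matrix to the `top_n` most variant genes (pooled-SD ranking),
#' tests each gene with a two-sided Wilcoxon rank-sum test, BH-adjusts across
#' the tested genes, and classifies genes at `q < q_threshold` as up in cohort
#' A or up in cohort B by the sign of the mean log2 difference.
#'
#' @param expr An [expr_matrix] carrying cohort labels (or pass `labels`).
#' @param labels Optional cohort labels overriding `expr$cohort`.
#' @param q_threshold FDR threshold for calling a gene significant.
#' @param top_n Number of most-variant genes tested; `NULL` tests all genes.
#' @param group_a Label value treated as cohort A (defaults to first
#'   alphabetically).
#' @return Data frame as from [compare_feature_matrix] plus a `status` column
#'   (`"up_in_a"`, `"up_in_b"`, `"ns"`).
#' @export
differential_expression <- function(expr, labels = NULL, q_threshold = 0.25,
                                    top_n = 2000L, group_a = NULL) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  labels <- labels %||% expr$cohort
  if (is.null(labels)) validation_error("cohort labels required")
  if (!is.null(top_n)) {
    keep <- select_top_variant_genes(m, min(top_n, nrow(m)))
    m <- m[keep, , drop = FALSE]
  }
  res <- compare_feature_matrix(m, labels, group_a = group_a)
  res$status <- ifelse(res$q_value < q_threshold, res$direction, "ns")
  res
}

#' Over-representation analysis by the hypergeometric test
#'
#' For each gene set, tests whether the query gene list overlaps the set more
#' than expected when drawing `|query|` genes from the universe, using the
#' one-sided hypergeometric tail P(overlap >= observed). Sets are intersected
#' with the universe before testing; query genes outside the universe are
#' dropped (their number is reported in a message). p-values are BH-adjusted
#' across the tested sets.
#'
#' @param query_genes Character vector of genes of interest (e.g. the
#'   significantly upregulated genes of one cohort).
#' @param collection A `gene_set_collection`.
#' @param universe Character vector of all genes that could have been called
#'   (typically all genes in the expression matrix).
#' @param min_overlap Sets with observed overlap below this are still tested
#'   (default 0 drops nothing); exposed for compatibility with trimmed-output
#'   conventions.
#' @return Data frame: `set_name`, `overlap_count`, `set_size`,
#'   `universe_size`, `query_size`, `gene_ratio`, `p_value`, `q_value`,
#'   `immune`.
#' @export
ora_enrichment <- function(query_genes, collection, universe,
                           min_overlap = 0L) {
  universe <- unique(universe)
  if (length(universe) == 0L) validation_error("empty universe")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    log_note("ora_enrichment: dropping %d query gene(s) outside the universe",
             length(outside))
    query <- intersect(query, universe)
  }
  n_uni <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(query, set))
    if (k < min_overlap) return(NULL)
    # P(X >= k), X ~ Hypergeometric(|set| marked, n_uni - |set|, n_query drawn)
    p <- stats::phyper(k - 1, length(set), n_uni - length(set), n_query,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = length(set),
               universe_size = n_uni, query_size = n_query,
               gene_ratio = if (n_query > 0) k / n_query else 0,
               p_value = p, immune = unname(collection$immune[nm]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[c("set_name", "overlap_count", "set_size", "universe_size",
        "query_size", "gene_ratio", "p_value", "q_value", "immune")]
}

#' UMAP embedding of samples
#'
#' Visualisation-only wrapper: embeds samples in 2-D with UMAP on the
#' `n_top_genes` most variant genes. The seed is fixed so coordinates are
#' reproducible; nothing downstream depends on this stage.
#'
#' @param expr An [expr_matrix].
#' @param n_top_genes Number of most-variant genes used (default 2000, capped
#'   at the gene count).
#' @param seed RNG seed for the embedding.
#' @param n_neighbors UMAP neighbourhood size (capped at n_samples - 1).
#' @return Data frame `sample_id`, `umap1`, `umap2` with the seed stored in
#'   `attr(, "seed")`.
#' @export
embed_umap <- function(expr, n_top_genes = 2000L, seed = 1L,
                       n_neighbors = 15L) {
  if (!requireNamespace("uwot", quietly = TRUE))
    abort("embed_umap requires the uwot package", "immunocompare_dependency_error")
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  keep <- select_top_variant_genes(m, min(n_top_genes, nrow(m)))
  x <- t(m[keep, , drop = FALSE])
  # duplicate expression profiles carry no extra structure and would be
  # scattered by the stochastic layout: embed unique profiles once and give
  # duplicates their representative's coordinates
  key <- apply(x, 1L, paste, collapse = "\r")
  rep_idx <- match(key, key)
  uniq <- unique(rep_idx)
  set.seed(seed)
  emb_u <- uwot::umap(x[uniq, , drop = FALSE],
                      n_neighbors = min(n_neighbors, length(uniq) - 1L),
                      n_threads = 1L)
  emb <- emb_u[match(rep_idx, uniq), , drop = FALSE]
  out <- data.frame(sample_id = colnames(m), umap1 = emb[, 1], umap2 = emb[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}
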