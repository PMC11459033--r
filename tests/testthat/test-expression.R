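test_that("top-variant selection matches brute-force SD ranking", {
  set.seed(71)
  m <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("G%03d", 1:100), sprintf("S%02d", 1:20)))
  for (n in c(1, 10, 100)) {
    sel <- select_top_variant_genes(m, n)
    sds <- apply(m, 1, sd)
    brute <- names(sort(sds, decreasing = TRUE))[seq_len(n)]
    expect_setequal(sel, brute)
  }
  expect_error(select_top_variant_genes(m, 101),
               class = "immunocompare_validation_error")
})

test_that("tie-break on equal SDs is deterministic and lexicographic", {
  m <- matrix(1, 10, 4, dimnames = list(sprintf("g%02d", 10:1), NULL))
  colnames(m) <- paste0("s", 1:4)
  expect_equal(select_top_variant_genes(m, 5),
               sort(rownames(m))[1:5])
  # one gene stands out
  m["g05", ] <- c(0, 10, 0, 10)
  expect_equal(select_top_variant_genes(m, 1), "g05")
})

test_that("differential expression flags shifted genes with the right sign", {
  d <- simulation_design(n_cohort_a = 20L, n_cohort_b = 60L, n_genes = 200L,
                         n_immune_genes = 61L, immune_effect_delta = 2,
                         seed = 15L)
  ex <- simulate_expression(d)
  res <- differential_expression(ex$expr, q_threshold = 0.25, top_n = 150L)
  sig <- res[res$status != "ns", ]
  called_shifted <- sig$feature_id %in% ex$shifted_genes
  # every significant call among the shifted genes points up in cohort A
  expect_true(all(sig$status[called_shifted] == "up_in_a"))
  # the shift is large: most shifted genes inside the tested set are found
  tested_shifted <- intersect(res$feature_id, ex$shifted_genes)
  expect_gt(mean(tested_shifted %in% sig$feature_id), 0.9)
  # q_threshold 0 silences everything
  res0 <- differential_expression(ex$expr, q_threshold = 0, top_n = 150L)
  expect_true(all(res0$status == "ns"))
})

test_that("hypergeometric enrichment matches the tail oracle and Fisher", {
  universe <- sprintf("G%03d", 1:100)
  coll <- gene_set_collection(list(SET10 = universe[1:10],
                                   FAR = universe[91:100]))
  query <- universe[1:10]
  res <- ora_enrichment(query, coll, universe)
  row <- res[res$set_name == "SET10", ]
  expect_equal(row$overlap_count, 10L)
  expect_equal(row$gene_ratio, 1)
  expect_equal(row$p_value, oracle_hyper_tail(10, 10, 100, 10),
               tolerance = 1e-12)
  expect_equal(row$p_value, 1 / choose(100, 10), tolerance = 1e-9)
  # disjoint query: tail includes overlap 0, p = 1
  expect_equal(res$p_value[res$set_name == "FAR"], 1)
  # equivalence with one-sided Fisher on the 2x2
  p_fisher <- stats::fisher.test(matrix(c(10, 0, 0, 90), 2),
                                 alternative = "greater")$p.value
  expect_equal(row$p_value, unname(p_fisher), tolerance = 1e-12)
})

test_that("enrichment drops query genes outside the universe and is invariant
           to gene relabeling", {
  universe <- sprintf("G%03d", 1:50)
  coll <- gene_set_collection(list(S = universe[1:8]))
  expect_message(res <- ora_enrichment(c(universe[1:5], "NOT_THERE"),
                                       coll, universe),
                 "dropping 1")
  expect_equal(res$query_size, 5L)
  # relabel every gene consistently: p unchanged
  relabel <- setNames(sprintf("X%03d", 1:50), universe)
  coll2 <- gene_set_collection(list(S = unname(relabel[universe[1:8]])))
  res2 <- ora_enrichment(unname(relabel[universe[1:5]]), coll2,
                         unname(relabel))
  expect_equal(res2$p_value, res$p_value)
  expect_error(ora_enrichment("G001", coll, character(0)),
               class = "immunocompare_validation_error")
})

test_that("UMAP embedding is reproducible and respects duplicates", {
  ex <- toy_expr(50, 20, seed = 5)
  # duplicate one sample
  vals <- cbind(ex$values, DUP = ex$values[, 1])
  ex2 <- expr_matrix(vals)
  emb1 <- embed_umap(ex2, n_top_genes = 50, seed = 4)
  emb2 <- embed_umap(ex2, n_top_genes = 50, seed = 4)
  expect_equal(emb1, emb2)
  expect_equal(nrow(emb1), ncol(vals))
  span <- max(dist(emb1[, c("umap1", "umap2")]))
  d_dup <- sqrt(sum((emb1[emb1$sample_id == "DUP", 2:3] -
                     emb1[emb1$sample_id == colnames(ex$values)[1], 2:3])^2))
  expect_lt(d_dup, 1e-3 * span + 1e-8)
})
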