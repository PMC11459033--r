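make_variants <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], gene = r[[2]], variant_class = r[[3]],
               sift_call = r[[4]], polyphen_call = r[[5]],
               cosmic_count = as.integer(r[[6]]),
               cosmic_driver_count = as.integer(r[[7]]),
               exonic = as.logical(r[[8]]), stringsAsFactors = FALSE)
  }))
  class(df) <- c("variant_table", "data.frame")
  df
}

roles <- data.frame(gene = c("TSG1", "ONC1", "DUAL1"),
                    role = c("TSG", "oncogene", "both"),
                    immune_gene = c(TRUE, FALSE, FALSE))

test_that("TMB counts exactly the exonic nonsynonymous SNVs per megabase", {
  v <- make_variants(
    list("s1", "G1", "missense", NA, NA, 0, 0, TRUE),
    list("s1", "G2", "nonsense", NA, NA, 0, 0, TRUE),
    list("s1", "G3", "splice_site", NA, NA, 0, 0, TRUE),
    list("s1", "G4", "synonymous", NA, NA, 0, 0, TRUE),     # excluded
    list("s1", "G5", "frameshift_indel", NA, NA, 0, 0, TRUE), # excluded
    list("s1", "G6", "inframe_indel", NA, NA, 0, 0, TRUE),    # excluded
    list("s1", "G7", "missense", NA, NA, 0, 0, FALSE),        # not exonic
    list("s2", "G1", "missense", NA, NA, 0, 0, TRUE))
  tmb <- compute_tmb(v, capture_size_mb = 1.5)
  expect_equal(tmb, c(s1 = 3 / 1.5, s2 = 1 / 1.5))
  # sample with no variants still reported, at 0
  tmb3 <- compute_tmb(v, 1.5, samples = c("s1", "s2", "s3"))
  expect_equal(tmb3[["s3"]], 0)
  expect_error(compute_tmb(v, 0), class = "immunocompare_validation_error")

  # 80 qualifying + 5 synonymous + 3 indels over 40 Mb -> 2.0/Mb
  many <- do.call(make_variants, c(
    lapply(1:80, function(i) list("sx", "G", "missense", NA, NA, 0, 0, TRUE)),
    lapply(1:5, function(i) list("sx", "G", "synonymous", NA, NA, 0, 0, TRUE)),
    lapply(1:3, function(i) list("sx", "G", "frameshift_indel", NA, NA, 0, 0, TRUE))))
  expect_equal(unname(compute_tmb(many, 40)), 2.0)
})

test_that("TMB is additive over disjoint variant subsets", {
  set.seed(91)
  v <- do.call(make_variants, lapply(1:60, function(i) {
    list(sample(c("s1", "s2"), 1), "G",
         sample(c("missense", "synonymous", "nonsense", "inframe_indel"), 1),
         NA, NA, 0, 0, sample(c(TRUE, FALSE), 1))
  }))
  idx <- seq_len(nrow(v)) <= 30
  samples <- c("s1", "s2")
  total <- compute_tmb(v, 2, samples = samples)
  part <- compute_tmb(v[idx, ], 2, samples = samples) +
    compute_tmb(v[!idx, ], 2, samples = samples)
  expect_equal(total, part)
})

test_that("driver rules reproduce the anchored role-specific calls", {
  # TSG nonsense SNV without COSMIC support: driver via truncation
  v1 <- make_variants(list("s1", "TSG1", "nonsense", NA, NA, 0, 0, TRUE))
  r1 <- classify_driver(v1, roles)
  expect_true(r1$driver)
  expect_equal(r1$rule, "tsg_truncating")
  # oncogene frameshift indel: never a driver through the oncogene path
  v2 <- make_variants(list("s1", "ONC1", "frameshift_indel", NA, NA, 50, 0, TRUE))
  r2 <- classify_driver(v2, roles)
  expect_false(r2$driver)
  # TSG benign missense rescued by COSMIC driver-category recurrence >= 10
  v3 <- make_variants(list("s1", "TSG1", "missense", "tolerated", "benign", 0, 12, TRUE))
  r3 <- classify_driver(v3, roles)
  expect_true(r3$driver)
  expect_equal(r3$rule, "tsg_recurrent")
  # gene outside the role table
  v4 <- make_variants(list("s1", "NOT_CANCER", "nonsense", NA, NA, 99, 99, TRUE))
  r4 <- classify_driver(v4, roles)
  expect_false(r4$driver)
  expect_equal(r4$rule, "not_cancer_gene")
  # dual-role gene can fire both paths; the tag records them
  v5 <- make_variants(list("s1", "DUAL1", "nonsense", NA, NA, 5, 0, TRUE))
  r5 <- classify_driver(v5, roles)
  expect_true(r5$driver)
  expect_equal(r5$rule, "tsg_truncating,oncogene_recurrent")
  # unknown class is rejected
  v6 <- v1
  v6$variant_class <- "weird"
  expect_error(classify_driver(v6, roles),
               class = "immunocompare_validation_error")
})

test_that("SCNA driver rules pair role with event direction", {
  scna <- data.frame(sample_id = "s1",
                     gene = c("TSG1", "TSG1", "ONC1", "ONC1", "DUAL1", "NONE"),
                     event = c("deletion", "amplification", "amplification",
                               "deletion", "deletion", "deletion"))
  r <- classify_scna_driver(scna, roles)
  expect_equal(r$driver, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$rule[1], "tsg_deletion")
  expect_equal(r$rule[6], "not_cancer_gene")
  expect_error(classify_scna_driver(
    data.frame(sample_id = "s", gene = "g", event = "gain"), roles),
    class = "immunocompare_validation_error")
})

test_that("normalized driver load divides driver calls by TMB", {
  v <- make_variants(
    list("s1", "TSG1", "nonsense", NA, NA, 0, 0, TRUE),
    list("s1", "TSG1", "missense", "deleterious", NA, 0, 0, TRUE),
    list("s1", "ONC1", "missense", NA, NA, 5, 0, TRUE),
    list("s1", "G", "missense", NA, NA, 0, 0, TRUE),
    list("s2", "G", "missense", NA, NA, 0, 0, TRUE))
  tmb <- compute_tmb(v, 2)   # s1: 4 SNVs / 2 Mb = 2.0 ; s2: 0.5
  load <- normalized_driver_load(v, roles, tmb)
  expect_equal(load[["s1"]], 3 / 2.0)
  expect_equal(load[["s2"]], 0)
  # immune-restricted version counts only immune cancer genes (TSG1)
  load_imm <- normalized_driver_load(v, roles, tmb, immune_only = TRUE)
  expect_equal(load_imm[["s1"]], 2 / 2.0)
  # TMB 0 -> missing value, logged
  tmb0 <- c(s1 = 2, s2 = 0)
  expect_message(load0 <- normalized_driver_load(v, roles, tmb0), "TMB 0")
  expect_true(is.na(load0[["s2"]]))
  # SCNA drivers add to the numerator
  scna <- data.frame(sample_id = "s1", gene = "TSG1", event = "deletion")
  load_sc <- normalized_driver_load(v, roles, tmb, scna = scna)
  expect_equal(load_sc[["s1"]], 4 / 2.0)
})

test_that("wGII equals the per-base oracle on toy profiles", {
  # all segments at ploidy -> 0; all aberrant -> 1
  segs <- data.frame(chrom = rep(as.character(1:22), each = 1),
                     start = 0, end = 1000, total_cn = 2)
  expect_equal(wgii(segment_profile("n", segs, 2)), 0)
  segs$total_cn <- 3
  expect_equal(wgii(segment_profile("a", segs, 2)), 1)
  # chr1 half aberrant, others normal, equal coverage -> 0.5/22
  segs2 <- rbind(data.frame(chrom = "1", start = c(0, 500), end = c(500, 1000),
                            total_cn = c(3, 2)),
                 data.frame(chrom = as.character(2:22), start = 0, end = 1000,
                            total_cn = 2))
  p <- segment_profile("h", segs2, 2)
  expect_equal(wgii(p), 0.5 / 22, tolerance = 1e-12)
  expect_equal(wgii(p), oracle_wgii_per_base(p), tolerance = 1e-12)
  # ploidy rounding: reference CN is round-half-up of real ploidy
  expect_equal(wgii(segment_profile("r", segs2, 2.5)), 21.5 / 22,
               tolerance = 1e-12)  # ref 3: chr1 half normal, rest aberrant
  expect_error(wgii(segment_profile("x", data.frame(
    chrom = "X", start = 0, end = 10, total_cn = 2), 2)),
    class = "immunocompare_validation_error")
})

test_that("per-gene association counts samples once and matches Fisher", {
  v <- make_variants(
    list("a1", "G1", "missense", NA, NA, 0, 0, TRUE),
    list("a1", "G1", "nonsense", NA, NA, 0, 0, TRUE),  # same sample, same gene
    list("a2", "G1", "missense", NA, NA, 0, 0, TRUE),
    list("b1", "G2", "missense", NA, NA, 0, 0, TRUE))
  labels <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  res <- per_gene_association(v, labels, group_a = "A")
  g1 <- res[res$gene == "G1", ]
  expect_equal(g1$n_mut_a, 2L)   # a1 counted once despite two variants
  expect_equal(g1$n_mut_b, 0L)
  expect_equal(g1$p_value, fisher_exact_2x2(2, 0, 1, 2))
  # a gene mutated in nobody gives p = 1
  res2 <- per_gene_association(v, labels, genes = c("G1", "G_SILENT"))
  expect_equal(res2$p_value[res2$gene == "G_SILENT"], 1)
  expect_equal(res2$q_value, bh_adjust(res2$p_value))
})

test_that("a strongly enriched gene reaches significance at realistic sizes", {
  set.seed(92)
  labels <- setNames(rep(c("A", "B"), c(44, 200)),
                     sprintf("p%03d", 1:244))
  mut_a <- sample(names(labels)[1:44], 22)        # 50% prevalence in A
  mut_b <- sample(names(labels)[45:244], 10)      # 5% in B
  v <- do.call(make_variants, lapply(c(mut_a, mut_b), function(s) {
    list(s, "HOT", "missense", NA, NA, 0, 0, TRUE)
  }))
  res <- per_gene_association(v, labels, group_a = "A")
  expect_lt(res$q_value, 0.05)
})
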