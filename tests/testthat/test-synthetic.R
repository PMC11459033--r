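small_design <- function(seed = 9L, ...) {
  simulation_design(n_cohort_a = 15L, n_cohort_b = 45L, n_genes = 120L,
                    n_immune_genes = 61L, seed = seed, ...)
}

test_that("identical design and seed give byte-identical bundles", {
  d <- small_design()
  b1 <- simulate_bundle(d)
  b2 <- simulate_bundle(d)
  expect_identical(b1$expr$values, b2$expr$values)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$context_counts, b2$context_counts)
  expect_identical(lapply(b1$profiles, `[[`, "segments"),
                   lapply(b2$profiles, `[[`, "segments"))
  # a different seed changes the data
  b3 <- simulate_bundle(small_design(seed = 10L))
  expect_false(identical(b1$expr$values, b3$expr$values))
})

test_that("expression shift lands on immune genes with the designed size", {
  # delta = 2, n = 40 vs 200, within-gene sd = 1: empirical mean difference
  # of shifted genes within +/- 0.2 of 2
  d <- simulation_design(n_cohort_a = 40L, n_cohort_b = 200L, n_genes = 400L,
                         n_immune_genes = 100L, immune_effect_delta = 2,
                         baseline_log_sd = 1, seed = 12L)
  ex <- simulate_expression(d)
  expect_setequal(ex$shifted_genes, design_genes_for_test(d)$immune)
  lab <- ex$expr$cohort
  ia <- lab == d$cohort_names[1]
  diff <- rowMeans(ex$expr$values[ex$shifted_genes, ia]) -
    rowMeans(ex$expr$values[ex$shifted_genes, !ia])
  expect_lt(abs(mean(diff) - 2), 0.2)
  # unshifted genes stay near zero
  other <- setdiff(rownames(ex$expr$values), ex$shifted_genes)
  diff0 <- rowMeans(ex$expr$values[other, ia]) -
    rowMeans(ex$expr$values[other, !ia])
  expect_lt(abs(mean(diff0)), 0.1)
})

test_that("a null design rejects about 5% of genes at p < 0.05", {
  d <- simulation_design(n_cohort_a = 25L, n_cohort_b = 60L, n_genes = 400L,
                         n_immune_genes = 61L, immune_effect_delta = 0,
                         baseline_log_mean = 6,  # keep clear of the 0 floor
                         seed = 13L)
  ex <- simulate_expression(d)
  res <- compare_feature_matrix(ex$expr$values, ex$expr$cohort)
  frac <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(frac - 0.05), 4 * se + 0.01)
  expect_length(ex$shifted_genes, 0L)
})

test_that("variant burdens follow the designed Poisson rates", {
  d <- simulation_design(n_cohort_a = 100L, n_cohort_b = 100L, n_genes = 120L,
                         n_immune_genes = 61L, tmb_rate_a = 2, tmb_rate_b = 2,
                         seed = 14L)
  vs <- simulate_variants(d)
  # mean exonic nonsynonymous count within 3 SE of rate * capture = 143.2
  mu <- 2 * d$capture_size_mb
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(vs$nonsyn_count) - mu), 3 * se)
  # recomputed TMB matches the ground-truth counts exactly
  tmb <- compute_tmb(vs$variants, d$capture_size_mb,
                     samples = names(vs$nonsyn_count))
  expect_equal(tmb * d$capture_size_mb, as.numeric(vs$nonsyn_count),
               ignore_attr = TRUE)

  # zero rate: no variants at all
  d0 <- small_design(tmb_rate_a = 0, tmb_rate_b = 0)
  expect_equal(nrow(simulate_variants(d0)$variants), 0L)

  # driver_fraction 0: the driver engine finds nothing
  dnd <- small_design(driver_fraction = 0)
  vs0 <- simulate_variants(dnd)
  ann <- classify_driver(vs0$variants, vs0$role_table)
  expect_equal(sum(ann$driver), 0L)
})

test_that("injected drivers are recovered by the driver engine", {
  d <- small_design(driver_fraction = 0.2)
  vs <- simulate_variants(d)
  ann <- classify_driver(vs$variants, vs$role_table)
  per_sample <- table(factor(ann$sample_id[ann$driver],
                             levels = names(vs$driver_count)))
  expect_equal(as.integer(per_sample), as.integer(vs$driver_count))
})

test_that("segment profiles realise the designed aberrant fraction exactly", {
  d0 <- small_design(aberrant_fraction_a = 0, aberrant_fraction_b = 0)
  sg0 <- simulate_segments(d0)
  expect_true(all(vapply(sg0$profiles, wgii, 0) == 0))

  d1 <- small_design(aberrant_fraction_a = 1, aberrant_fraction_b = 1)
  sg1 <- simulate_segments(d1)
  expect_true(all(vapply(sg1$profiles, wgii, 0) == 1))

  d <- small_design(aberrant_fraction_a = 0.3, aberrant_fraction_b = 0.5)
  sg <- simulate_segments(d)
  w <- vapply(sg$profiles, wgii, 0)
  expect_equal(w, sg$aberrant_fraction[names(w)], tolerance = 1e-12)
  # cohort means sit near their design values
  lab <- design_labels_for_test(d)
  expect_lt(abs(mean(w[lab == d$cohort_names[1]]) - 0.3), 0.15)
  expect_lt(abs(mean(w[lab == d$cohort_names[2]]) - 0.5), 0.15)
})

test_that("context counts follow the designed signature mixture", {
  d <- small_design()
  cx <- simulate_contexts(d, n_mutations = setNames(
    rep(500L, 60L), names(design_labels_for_test(d))))
  expect_equal(dim(cx$counts), c(60L, 96L))
  expect_true(all(rowSums(cx$counts) == 500))
  expect_equal(rowSums(cx$exposures), rep(1, 60), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("design validation rejects inconsistent parameters", {
  expect_error(simulation_design(n_genes = 50, n_immune_genes = 61),
               class = "immunocompare_validation_error")
  expect_error(simulation_design(aberrant_fraction_a = 1.2),
               class = "immunocompare_validation_error")
  expect_error(simulation_design(
    signature_weights = list(a = c(TOYSIG1 = 0.5), b = c(TOYSIG1 = 1))),
    class = "immunocompare_validation_error")
})

test_that("written bundles are readable through the io module", {
  d <- small_design()
  b <- simulate_bundle(d)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  ex <- read_expression(file.path(dir, "expression_tpm.tsv"))
  expect_equal(ex$values, b$expr$values, tolerance = 1e-8)
  v <- read_variants(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), nrow(b$variants))
  gs <- read_gmt(file.path(dir, "gene_sets.gmt"),
                 file.path(dir, "gene_set_categories.tsv"))
  expect_equal(gs$sets, b$collection$sets)
  expect_equal(gs$immune, b$collection$immune)
  prof <- read_segments(file.path(dir, "segments.tsv"),
                        file.path(dir, "ploidy.tsv"))
  expect_equal(vapply(prof, wgii, 0)[names(b$profiles)],
               vapply(b$profiles, wgii, 0))
  cx <- read_context_counts(file.path(dir, "context_counts.tsv"))
  expect_equal(cx, b$context_counts)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(gt$shifted_genes, b$ground_truth$shifted_genes)
})
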