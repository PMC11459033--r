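# End-to-end orchestration: runs every stage of the two-cohort comparison on
# a bundle of inputs (real files read through the io module, or a synthetic
# bundle) under one configuration.

#' Run the full two-cohort comparison
#'
#' Executes, in order: variance-based gene selection and differential
#' expression; over-representation analysis of the up-in-A and up-in-B gene
#' lists; GSVA pathway scoring and differential pathway analysis; TIL scoring
#' and comparison; pairwise per-cancer-type comparisons of the TIL scores;
#' TMB, wGII and TMB-normalised driver load with their cohort contrasts;
#' per-gene driver association tests; and mutational signature refitting with
#' the patient-support filter and per-signature count comparison.
#'
#' @param bundle List with elements `expr` (an [expr_matrix] with cohort
#'   labels), `collection`, `variants`, `role_table`, `profiles`,
#'   `context_counts`, `catalog`, `labels` (named cohort labels) — the shape
#'   produced by [simulate_bundle] or assembled from the io readers.
#' @param config A [pipeline_config].
#' @param group_a Cohort label treated as group A (default: first label
#'   alphabetically).
#' @param panel Marker panel for TIL scoring.
#' @return List of stage results; see the individual stage functions.
#' @export
run_cohort_comparison <- function(bundle, config = pipeline_config(),
                                  group_a = NULL,
                                  panel = default_marker_panel()) {
  validate_config(config)
  labels <- bundle$labels
  group_a <- group_a %||% sort(unique(as.character(labels)))[1]

  de <- differential_expression(bundle$expr, labels = labels,
                                q_threshold = config$de_q_threshold,
                                top_n = config$top_n_variant_genes,
                                group_a = group_a)
  universe <- rownames(bundle$expr$values)
  up_a <- de$feature_id[de$status == "up_in_a"]
  up_b <- de$feature_id[de$status == "up_in_b"]
  ora <- list(
    up_in_a = if (length(up_a)) ora_enrichment(up_a, bundle$collection, universe),
    up_in_b = if (length(up_b)) ora_enrichment(up_b, bundle$collection, universe))

  scores <- gsva_scores(bundle$expr, bundle$collection,
                        min_size = config$gsva_min_size,
                        max_size = config$gsva_max_size)
  pathway_de <- differential_pathways(scores, labels,
                                      q_threshold = config$pathway_q_threshold,
                                      group_a = group_a)

  til <- til_scores(bundle$expr, panel = panel)
  til_de <- compare_til(til, labels, q_threshold = config$pathway_q_threshold,
                        group_a = group_a)
  type_labels <- ifelse(labels == group_a, group_a,
                        bundle$expr$cancer_type[names(labels)])
  til_pairwise <- pairwise_type_comparison(
    til, type_labels, reference_label = group_a,
    min_patients = config$pairwise_min_patients)

  tmb <- compute_tmb(bundle$variants, config$capture_size_mb,
                     samples = names(labels))
  drivers <- classify_driver(bundle$variants, bundle$role_table,
                             tsg_recurrence_min = config$cosmic_tsg_recurrence_min,
                             oncogene_recurrence_min = config$cosmic_oncogene_recurrence_min)
  driver_load <- normalized_driver_load(
    bundle$variants, bundle$role_table, tmb,
    tsg_recurrence_min = config$cosmic_tsg_recurrence_min,
    oncogene_recurrence_min = config$cosmic_oncogene_recurrence_min)
  wgii_per_sample <- vapply(bundle$profiles, wgii, 0)

  two_group_test <- function(x) {
    ok <- !is.na(x)
    la <- labels[names(x)][ok] == group_a
    list(effect = mean(x[ok][la]) - mean(x[ok][!la]),
         p_value = wilcoxon_rank_sum(x[ok][la], x[ok][!la]))
  }
  gene_assoc <- per_gene_association(drivers[drivers$driver, ], labels,
                                     group_a = group_a)

  fit <- estimate_exposures(bundle$context_counts, bundle$catalog)
  kept <- filter_signatures(fit$exposures,
                            min_patients = config$signature_patient_min)
  sig_counts <- signature_counts(fit$exposures, tmb)
  sig_de <- if (length(kept) >= 1L) {
    compare_feature_matrix(t(sig_counts[, kept, drop = FALSE]), labels,
                           group_a = group_a)
  }

  list(config = config, group_a = group_a,
       de = de, ora = ora,
       gsva = scores, pathway_de = pathway_de,
       til = til, til_de = til_de, til_pairwise = til_pairwise,
       tmb = tmb, tmb_test = two_group_test(tmb),
       wgii = wgii_per_sample, wgii_test = two_group_test(wgii_per_sample),
       drivers = drivers, driver_load = driver_load,
       driver_load_test = two_group_test(driver_load),
       gene_association = gene_assoc,
       exposures = fit$exposures, signature_residual = fit$residual,
       signatures_kept = kept, signature_counts = sig_counts,
       signature_de = sig_de)
}
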