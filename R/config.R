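#' Pipeline configuration
#'
#' Bundles the tunable analysis parameters in one validated object. Defaults
#' follow the study design the pipeline implements: differential expression is
#' run on the 2000 most variant genes at an FDR threshold of 0.25, pathway and
#' TIL comparisons use q < 0.05, GSVA keeps gene sets with 10--500 matched
#' genes, tumor mutation burden is normalised to a 71.6 Mb exome capture,
#' driver recurrence cutoffs are 10 (COSMIC driver category, tumor suppressor
#' rule) and 3 (any COSMIC occurrence, oncogene rule), mutational signatures
#' are kept when at least 10 patients carry a nonzero fraction, and pairwise
#' per-cancer-type comparisons require at least 10 patients per type.
#'
#' @param top_n_variant_genes Number of genes kept by variance-based selection.
#' @param de_q_threshold BH-adjusted q-value cutoff for differential expression.
#' @param pathway_q_threshold q-value cutoff for pathway and TIL comparisons.
#' @param gsva_min_size,gsva_max_size Effective gene-set size bounds for GSVA.
#' @param capture_size_mb Exome capture footprint in megabases (TMB denominator).
#' @param cosmic_tsg_recurrence_min COSMIC driver-category recurrence needed for
#'   the tumor-suppressor recurrence rule.
#' @param cosmic_oncogene_recurrence_min COSMIC recurrence needed for the
#'   oncogene rule.
#' @param signature_patient_min Minimum number of patients with nonzero
#'   exposure for a signature to be retained.
#' @param pairwise_min_patients Minimum cohort-B cancer-type size entering the
#'   pairwise comparisons.
#' @param rng_seed Integer seed recorded with every run.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(top_n_variant_genes = 2000L,
                            de_q_threshold = 0.25,
                            pathway_q_threshold = 0.05,
                            gsva_min_size = 10L,
                            gsva_max_size = 500L,
                            capture_size_mb = 71.6,
                            cosmic_tsg_recurrence_min = 10L,
                            cosmic_oncogene_recurrence_min = 3L,
                            signature_patient_min = 10L,
                            pairwise_min_patients = 10L,
                            rng_seed = 1L) {
  cfg <- list(
    top_n_variant_genes = as.integer(top_n_variant_genes),
    de_q_threshold = de_q_threshold,
    pathway_q_threshold = pathway_q_threshold,
    gsva_min_size = as.integer(gsva_min_size),
    gsva_max_size = as.integer(gsva_max_size),
    capture_size_mb = capture_size_mb,
    cosmic_tsg_recurrence_min = as.integer(cosmic_tsg_recurrence_min),
    cosmic_oncogene_recurrence_min = as.integer(cosmic_oncogene_recurrence_min),
    signature_patient_min = as.integer(signature_patient_min),
    pairwise_min_patients = as.integer(pairwise_min_patients),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  for (nm in c("top_n_variant_genes", "de_q_threshold", "pathway_q_threshold",
               "gsva_min_size", "gsva_max_size", "capture_size_mb",
               "cosmic_tsg_recurrence_min", "cosmic_oncogene_recurrence_min",
               "signature_patient_min", "pairwise_min_patients")) {
    assert_scalar_number(cfg[[nm]], nm, positive = TRUE)
  }
  assert_fraction(cfg$de_q_threshold, "de_q_threshold")
  assert_fraction(cfg$pathway_q_threshold, "pathway_q_threshold")
  if (cfg$gsva_min_size > cfg$gsva_max_size)
    validation_error("gsva_min_size must not exceed gsva_max_size")
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' Configurations round-trip unchanged: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param path File path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  x <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
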