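# Mutation-level metrics: tumor mutation burden, the rule-based driver
# annotation engine, TMB-normalised driver load, the weighted genome
# integrity index, and per-gene cohort association tests.

#' Tumor mutation burden
#'
#' TMB is the number of exonic, non-synonymous single-nucleotide variants
#' (classes missense, nonsense, splice_site; indels and synonymous SNVs are
#' excluded) per megabase of capture footprint. Samples without qualifying
#' variants get TMB 0.
#'
#' @param variants A `variant_table` (see [read_variants]).
#' @param capture_size_mb Capture footprint in megabases (> 0).
#' @param samples Optional character vector of all sample ids (so samples
#'   with no variants at all still appear, with TMB 0).
#' @return Named numeric vector of mutations/Mb per sample.
#' @export
compute_tmb <- function(variants, capture_size_mb = 71.6, samples = NULL) {
  assert_scalar_number(capture_size_mb, "capture_size_mb", positive = TRUE)
  samples <- samples %||% sort(unique(variants$sample_id))
  qual <- variants$exonic &
    variants$variant_class %in% c("missense", "nonsense", "splice_site")
  counts <- table(factor(variants$sample_id[qual], levels = samples))
  stats::setNames(as.numeric(counts) / capture_size_mb, samples)
}

#' Rule-based driver mutation annotation
#'
#' Applies role-specific rules to each variant of genes in the role table:
#'
#' * Tumor suppressor (TSG) path: truncating variants (frameshift indel,
#'   nonsense SNV, splice-site SNV) are drivers; missense SNVs are drivers
#'   when called deleterious by SIFT or probably damaging by PolyPhen; any
#'   variant recurring `tsg_recurrence_min` times or more in the COSMIC
#'   driver-mutation category is a driver.
#' * Oncogene path: in-frame (non-frameshift) indels and SNVs with
#'   `oncogene_recurrence_min` or more COSMIC occurrences are drivers;
#'   frameshift indels never qualify through this path.
#' * Genes with role `both` fire on either path; the rule tag records which.
#' * Genes absent from the role table are never drivers (tag
#'   `not_cancer_gene`).
#'
#' @param variants A `variant_table`.
#' @param role_table Data frame from [read_gene_roles].
#' @param tsg_recurrence_min COSMIC driver-category recurrence cutoff
#'   (default 10).
#' @param oncogene_recurrence_min COSMIC recurrence cutoff (default 3).
#' @return The variant table with logical `driver` and character `rule`
#'   columns appended (`rule` is comma-joined when several rules fire, `"none"`
#'   or `"not_cancer_gene"` for non-drivers).
#' @export
classify_driver <- function(variants, role_table, tsg_recurrence_min = 10L,
                            oncogene_recurrence_min = 3L) {
  bad <- setdiff(unique(variants$variant_class), VARIANT_CLASSES)
  if (length(bad))
    validation_error(paste("unknown variant class:", paste(bad, collapse = ", ")))
  role <- role_table$role[match(variants$gene, role_table$gene)]
  is_tsg <- !is.na(role) & role %in% c("TSG", "both")
  is_onc <- !is.na(role) & role %in% c("oncogene", "both")
  cls <- variants$variant_class
  is_snv <- cls %in% SNV_CLASSES

  truncating <- cls %in% c("frameshift_indel", "nonsense", "splice_site")
  deleterious <- cls == "missense" &
    ((!is.na(variants$sift_call) & variants$sift_call == "deleterious") |
     (!is.na(variants$polyphen_call) & variants$polyphen_call == "probably_damaging"))
  tsg_recurrent <- variants$cosmic_driver_count >= tsg_recurrence_min
  onc_recurrent <- (cls == "inframe_indel" | is_snv) &
    variants$cosmic_count >= oncogene_recurrence_min

  rules <- character(nrow(variants))
  add_rule <- function(rules, hit, tag)
    ifelse(hit, ifelse(nzchar(rules), paste(rules, tag, sep = ","), tag), rules)
  rules <- add_rule(rules, is_tsg & truncating, "tsg_truncating")
  rules <- add_rule(rules, is_tsg & deleterious, "tsg_deleterious")
  rules <- add_rule(rules, is_tsg & tsg_recurrent, "tsg_recurrent")
  rules <- add_rule(rules, is_onc & onc_recurrent, "oncogene_recurrent")

  variants$driver <- nzchar(rules)
  variants$rule <- ifelse(variants$driver, rules,
                          ifelse(is.na(role), "not_cancer_gene", "none"))
  variants
}

#' Copy-number driver calls
#'
#' Deletions in tumor suppressors and amplifications in oncogenes are drivers;
#' genes with role `both` qualify for either event; all other combinations
#' (including genes absent from the role table) are not drivers.
#'
#' @param scna Data frame with columns `sample_id`, `gene`, `event`
#'   (`"amplification"` or `"deletion"`).
#' @param role_table Data frame from [read_gene_roles].
#' @return `scna` with logical `driver` and character `rule` columns.
#' @export
classify_scna_driver <- function(scna, role_table) {
  if (!all(scna$event %in% c("amplification", "deletion")))
    validation_error("SCNA event must be amplification or deletion")
  role <- role_table$role[match(scna$gene, role_table$gene)]
  del_tsg <- scna$event == "deletion" & !is.na(role) & role %in% c("TSG", "both")
  amp_onc <- scna$event == "amplification" & !is.na(role) &
    role %in% c("oncogene", "both")
  scna$driver <- del_tsg | amp_onc
  scna$rule <- ifelse(del_tsg, "tsg_deletion",
                      ifelse(amp_onc, "oncogene_amplification",
                             ifelse(is.na(role), "not_cancer_gene", "none")))
  scna
}

#' TMB-normalised driver load
#'
#' Per sample, the number of driver calls (point-mutation drivers plus
#' optional copy-number drivers) divided by the sample's TMB. Samples with
#' TMB 0 get a missing value (reported in a message). The immune-restricted
#' variant counts only drivers in genes flagged `immune_gene` in the role
#' table.
#'
#' @param variants A `variant_table`.
#' @param role_table Data frame from [read_gene_roles].
#' @param tmb_per_sample Named TMB vector from [compute_tmb].
#' @param scna Optional SCNA table (see [classify_scna_driver]).
#' @param immune_only Restrict the driver count to immune genes.
#' @param ... Passed to [classify_driver] (recurrence cutoffs).
#' @return Named numeric vector (drivers / TMB), NA where TMB is 0.
#' @export
normalized_driver_load <- function(variants, role_table, tmb_per_sample,
                                   scna = NULL, immune_only = FALSE, ...) {
  ann <- classify_driver(variants, role_table, ...)
  keep_gene <- if (immune_only) {
    role_table$gene[role_table$immune_gene]
  } else role_table$gene
  drv <- ann[ann$driver & ann$gene %in% keep_gene, ]
  counts <- table(factor(drv$sample_id, levels = names(tmb_per_sample)))
  if (!is.null(scna)) {
    sc <- classify_scna_driver(scna, role_table)
    sc <- sc[sc$driver & sc$gene %in% keep_gene, ]
    counts <- counts + table(factor(sc$sample_id, levels = names(tmb_per_sample)))
  }
  out <- as.numeric(counts) / tmb_per_sample
  zero <- tmb_per_sample == 0
  if (any(zero)) {
    log_note("normalized_driver_load: %d sample(s) with TMB 0 set to NA",
             sum(zero))
    out[zero] <- NA_real_
  }
  stats::setNames(out, names(tmb_per_sample))
}

normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Weighted genome integrity index
#'
#' For each autosome (1--22), the aberrant fraction is the covered length at
#' total copy number different from the sample's rounded ploidy (round half
#' up), divided by the covered length; wGII is the unweighted mean of the
#' per-autosome fractions over autosomes with nonzero coverage. Uncovered
#' genome never enters the denominators; sex chromosomes are ignored.
#'
#' @param profile A `segment_profile` (0-based half-open segments).
#' @return wGII in `[0, 1]`.
#' @export
wgii <- function(profile) {
  segs <- profile$segments
  segs$chrom <- normalize_chrom(segs$chrom)
  segs <- segs[segs$chrom %in% as.character(1:22), ]
  if (nrow(segs) == 0L) validation_error("no covered autosome")
  ref_cn <- floor(profile$ploidy + 0.5)  # round half up
  width <- segs$end - segs$start
  aberr <- segs$total_cn != ref_cn
  per_chr <- vapply(split(seq_len(nrow(segs)), segs$chrom), function(idx) {
    sum(width[idx][aberr[idx]]) / sum(width[idx])
  }, 0)
  mean(per_chr)
}

#' Per-gene mutation association between cohorts
#'
#' Collapses variants to sample-level presence/absence per gene, forms the
#' 2x2 table (mutated / not mutated) x (cohort A / cohort B), tests with
#' Fisher's exact test and adjusts across genes by BH.
#'
#' @param variants A `variant_table` (pre-filter to driver calls to test
#'   driver prevalence).
#' @param labels Named cohort labels (two levels), one per sample; the names
#'   define the sample universe, so unmutated samples are counted.
#' @param genes Optional subset of genes to test (default: all mutated genes).
#' @param group_a Label value treated as cohort A.
#' @return Data frame: `gene`, `n_mut_a`, `n_mut_b`, `n_a`, `n_b`, `p_value`,
#'   `q_value`.
#' @export
per_gene_association <- function(variants, labels, genes = NULL,
                                 group_a = NULL) {
  if (is.null(names(labels)))
    validation_error("labels must be named by sample id")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) validation_error("exactly two cohort labels required")
  if (!is.null(group_a)) lev <- c(group_a, setdiff(lev, group_a))
  samples_a <- names(labels)[labels == lev[1]]
  samples_b <- names(labels)[labels == lev[2]]
  genes <- genes %||% sort(unique(variants$gene))
  if (length(genes) == 0L)
    return(data.frame(gene = character(), n_mut_a = integer(),
                      n_mut_b = integer(), n_a = integer(), n_b = integer(),
                      p_value = numeric(), q_value = numeric()))
  rows <- lapply(genes, function(g) {
    mut <- unique(variants$sample_id[variants$gene == g])
    a <- sum(samples_a %in% mut)
    b <- sum(samples_b %in% mut)
    data.frame(gene = g, n_mut_a = a, n_mut_b = b,
               n_a = length(samples_a), n_b = length(samples_b),
               p_value = fisher_exact_2x2(a, b,
                                          length(samples_a) - a,
                                          length(samples_b) - b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}
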