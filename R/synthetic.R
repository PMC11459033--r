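# Synthetic two-cohort generator. Emulates the statistical structure the
# comparative analysis assumes -- two cohorts of unequal size, log-normal
# expression with a cohort-level shift on immune genes, Poisson mutation
# burdens, tunable aberrant genome fraction, and multinomial trinucleotide
# spectra drawn from signature mixtures -- so that every downstream stage is
# testable without patient data. Every operation is a pure function of the
# design (including its seed); ground-truth manifests accompany each output.

#' Simulation design for a synthetic two-cohort study
#'
#' Defaults mirror the study design the pipeline targets: a small cohort A
#' (n = 44) against a mixed metastatic cohort B (n = 213); a +1 log2 shift on
#' immune genes in cohort A (the "immune-hot" effect); equal mutation rates
#' (2.5 nonsynonymous SNVs/Mb over a 71.6 Mb capture) reflecting the null TMB
#' contrast; slightly lower aberrant genome fraction in cohort A (0.25 vs
#' 0.30); identical signature mixtures in both cohorts; and cohort B cancer
#' types drawn from a mix in which eight named types exceed the 10-patient
#' pairwise-comparison threshold.
#'
#' @param n_cohort_a,n_cohort_b Sample counts.
#' @param n_genes Total genes simulated (must cover the marker panel plus the
#'   immune gene pool).
#' @param baseline_log_mean Mean of the per-gene baseline log2 expression.
#' @param baseline_log_sd Within-gene between-sample SD on the log2 scale.
#' @param gene_mean_sd SD of per-gene baseline means around
#'   `baseline_log_mean`.
#' @param immune_effect_delta log2 shift added to immune genes in cohort A.
#' @param n_immune_genes Size of the immune gene pool; the marker panel genes
#'   are its first members, the remainder are named `IMMG...`.
#' @param tmb_rate_a,tmb_rate_b Expected nonsynonymous SNVs per Mb.
#' @param capture_size_mb Capture footprint (Mb).
#' @param driver_fraction Fraction of nonsynonymous variants injected with
#'   driver-qualifying annotation in cancer genes.
#' @param aberrant_fraction_a,aberrant_fraction_b Mean fraction of the genome
#'   at non-ploidy copy number.
#' @param aberrant_concentration Beta concentration of per-sample aberrant
#'   fractions around the cohort mean; `Inf` makes every sample exact.
#' @param ploidy Sample ploidy (real-valued; reference CN is its round).
#' @param n_chromosomes,chromosome_length Toy genome: autosome count and
#'   common length in bp.
#' @param signature_weights Named list with elements `a` and `b`: per-cohort
#'   exposure vectors over the catalog signatures, each summing to 1.
#' @param cancer_type_labels_b Named multinomial weights over cohort-B cancer
#'   types.
#' @param cohort_names Length-2 character vector naming cohorts A and B.
#' @param marker_panel A `marker_panel` whose genes anchor the immune pool.
#' @param seed Integer seed; identical design + seed gives identical output.
#' @return Validated list of class `simulation_design`.
#' @export
simulation_design <- function(n_cohort_a = 44L,
                              n_cohort_b = 213L,
                              n_genes = 2000L,
                              baseline_log_mean = 3,
                              baseline_log_sd = 1,
                              gene_mean_sd = 1.5,
                              immune_effect_delta = 1,
                              n_immune_genes = 150L,
                              tmb_rate_a = 2.5,
                              tmb_rate_b = 2.5,
                              capture_size_mb = 71.6,
                              driver_fraction = 0.1,
                              aberrant_fraction_a = 0.25,
                              aberrant_fraction_b = 0.30,
                              aberrant_concentration = 10,
                              ploidy = 2,
                              n_chromosomes = 22L,
                              chromosome_length = 1e8,
                              signature_weights = list(
                                a = c(TOYSIG1 = 0.4, TOYSIG2 = 0.3,
                                      TOYSIG3 = 0.2, TOYSIG4 = 0.1),
                                b = c(TOYSIG1 = 0.4, TOYSIG2 = 0.3,
                                      TOYSIG3 = 0.2, TOYSIG4 = 0.1)),
                              cancer_type_labels_b = c(
                                colorectal = 0.16, esophagogastric = 0.10,
                                biliary = 0.08, pancreatic = 0.08,
                                breast = 0.10, nsclc = 0.10,
                                melanoma = 0.07, glioma = 0.06, other = 0.25),
                              cohort_names = c("cohort_a", "cohort_b"),
                              marker_panel = default_marker_panel(),
                              seed = 1L) {
  design <- list(
    n_cohort_a = as.integer(n_cohort_a), n_cohort_b = as.integer(n_cohort_b),
    n_genes = as.integer(n_genes),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    gene_mean_sd = gene_mean_sd,
    immune_effect_delta = immune_effect_delta,
    n_immune_genes = as.integer(n_immune_genes),
    tmb_rate_a = tmb_rate_a, tmb_rate_b = tmb_rate_b,
    capture_size_mb = capture_size_mb, driver_fraction = driver_fraction,
    aberrant_fraction_a = aberrant_fraction_a,
    aberrant_fraction_b = aberrant_fraction_b,
    aberrant_concentration = aberrant_concentration,
    ploidy = ploidy,
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length,
    signature_weights = signature_weights,
    cancer_type_labels_b = cancer_type_labels_b,
    cohort_names = cohort_names,
    marker_panel = marker_panel,
    seed = as.integer(seed))
  validate_design(design)
  structure(design, class = "simulation_design")
}

validate_design <- function(d) {
  for (nm in c("n_cohort_a", "n_cohort_b", "n_genes", "baseline_log_sd",
               "gene_mean_sd", "tmb_rate_a", "tmb_rate_b", "capture_size_mb",
               "ploidy", "n_chromosomes", "chromosome_length"))
    assert_scalar_number(d[[nm]], nm, positive = nm != "tmb_rate_a" &&
                           nm != "tmb_rate_b")
  if (d$tmb_rate_a < 0 || d$tmb_rate_b < 0)
    validation_error("TMB rates must be non-negative")
  assert_fraction(d$driver_fraction, "driver_fraction")
  assert_fraction(d$aberrant_fraction_a, "aberrant_fraction_a")
  assert_fraction(d$aberrant_fraction_b, "aberrant_fraction_b")
  for (side in c("a", "b")) {
    w <- d$signature_weights[[side]]
    if (is.null(names(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-9)
      validation_error(sprintf(
        "signature_weights$%s must be named, non-negative and sum to 1", side))
  }
  if (any(d$cancer_type_labels_b < 0) || sum(d$cancer_type_labels_b) <= 0)
    validation_error("cancer_type_labels_b weights must be non-negative")
  n_panel <- length(unique(unlist(d$marker_panel)))
  if (d$n_immune_genes < n_panel)
    validation_error("n_immune_genes smaller than the marker panel")
  if (d$n_genes < d$n_immune_genes)
    validation_error("n_genes smaller than the immune gene pool")
  invisible(d)
}

design_genes <- function(design) {
  panel_genes <- unique(unlist(design$marker_panel))
  extra <- design$n_immune_genes - length(panel_genes)
  immune <- c(panel_genes,
              if (extra > 0) sprintf("IMMG%04d", seq_len(extra)))
  background <- sprintf("GENE%04d", seq_len(design$n_genes - length(immune)))
  list(immune = immune, background = background,
       all = c(immune, background))
}

design_samples <- function(design) {
  list(a = sprintf("%s_s%03d", design$cohort_names[1],
                   seq_len(design$n_cohort_a)),
       b = sprintf("%s_s%03d", design$cohort_names[2],
                   seq_len(design$n_cohort_b)))
}

design_labels <- function(design) {
  s <- design_samples(design)
  stats::setNames(rep(design$cohort_names, c(design$n_cohort_a, design$n_cohort_b)),
                  c(s$a, s$b))
}

# independent substreams: each simulate_* call is reproducible on its own
with_design_seed <- function(design, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((design$seed * 7L + offset) %% .Machine$integer.max)
  expr
}

#' Simulate a cohort expression matrix
#'
#' Per-gene baseline means are drawn from
#' `N(baseline_log_mean, gene_mean_sd)`; expression values are normal on the
#' log2 scale around the gene mean with SD `baseline_log_sd` (a log-normal
#' model on the TPM scale), truncated at 0 as log2(TPM + 1) values are.
#' Immune genes (marker panel plus `IMMG` pool) receive
#' `+immune_effect_delta` in cohort A.
#'
#' @param design A [simulation_design].
#' @return List: `expr` (an [expr_matrix] with cohort and cancer-type labels)
#'   and `shifted_genes` (ground truth: the genes that received the shift).
#' @export
simulate_expression <- function(design) {
  genes <- design_genes(design)
  samples <- design_samples(design)
  with_design_seed(design, 1L, {
    n <- design$n_cohort_a + design$n_cohort_b
    mu <- stats::rnorm(design$n_genes, design$baseline_log_mean,
                       design$gene_mean_sd)
    m <- matrix(stats::rnorm(design$n_genes * n, mean = mu,
                             sd = design$baseline_log_sd),
                nrow = design$n_genes, ncol = n,
                dimnames = list(genes$all, c(samples$a, samples$b)))
    shifted <- if (design$immune_effect_delta != 0) genes$immune else character()
    m[genes$immune, samples$a] <- m[genes$immune, samples$a] +
      design$immune_effect_delta
    m <- pmax(m, 0)
    types_b <- sample(names(design$cancer_type_labels_b), design$n_cohort_b,
                      replace = TRUE,
                      prob = design$cancer_type_labels_b)
    expr <- expr_matrix(
      m,
      cohort = rep(design$cohort_names, c(design$n_cohort_a, design$n_cohort_b)),
      cancer_type = c(rep("unknown_primary", design$n_cohort_a), types_b))
    list(expr = expr, shifted_genes = shifted)
  })
}

#' Simulate a gene-set collection matched to a design
#'
#' Builds an artificial Hallmark-like collection: `n_immune_sets` sets drawn
#' from the design's immune gene pool (flagged immune) and `n_other_sets`
#' sets drawn from the background genes, with sizes uniform on
#' `size_range`.
#'
#' @param design A [simulation_design].
#' @param n_immune_sets,n_other_sets Set counts (default 10 + 40, echoing a
#'   50-set Hallmark-style collection).
#' @param size_range Inclusive set-size range.
#' @return A `gene_set_collection`.
#' @export
simulate_gene_sets <- function(design, n_immune_sets = 10L,
                               n_other_sets = 40L,
                               size_range = c(15L, 40L)) {
  genes <- design_genes(design)
  with_design_seed(design, 5L, {
    draw <- function(pool, prefix, k, flag) {
      sets <- lapply(seq_len(k), function(i) {
        sz <- sample(size_range[1]:size_range[2], 1L)
        sample(pool, min(sz, length(pool)))
      })
      names(sets) <- sprintf("%s_%02d", prefix, seq_len(k))
      sets
    }
    sets <- c(draw(genes$immune, "IMMUNE_SET", n_immune_sets),
              draw(genes$background, "SET", n_other_sets))
    gene_set_collection(sets, immune = c(rep(TRUE, n_immune_sets),
                                         rep(FALSE, n_other_sets)))
  })
}

design_role_table <- function(design) {
  genes <- design_genes(design)
  n_cancer <- 60L
  pool <- genes$background[seq_len(min(n_cancer, length(genes$background)))]
  roles <- rep(c("TSG", "oncogene", "both"), length.out = length(pool))
  # a subset of cancer genes doubles as immune-system members, plus the
  # immune pool itself (non-cancer immune genes never yield drivers)
  immune_flag <- seq_along(pool) %% 6 == 0
  data.frame(gene = pool, role = roles, immune_gene = immune_flag,
             stringsAsFactors = FALSE)
}

#' Simulate a somatic variant table
#'
#' Per-sample exonic nonsynonymous SNV counts are Poisson with mean
#' `tmb_rate x capture_size_mb`; a `driver_fraction` of them is placed in
#' cancer genes with driver-qualifying annotation (truncating TSG variants,
#' deleterious TSG missense, COSMIC-recurrent oncogene missense), the rest in
#' passenger genes with non-qualifying annotation. Synonymous SNVs (30% of
#' the nonsynonymous rate) and frameshift indels (10%) are added so burden
#' filters are exercised.
#'
#' @param design A [simulation_design].
#' @return List: `variants` (a `variant_table`), `role_table` (gene roles
#'   consistent with the injected drivers), and ground truth
#'   `driver_count` / `nonsyn_count` per sample.
#' @export
simulate_variants <- function(design) {
  role_table <- design_role_table(design)
  genes <- design_genes(design)
  labels <- design_labels(design)
  passenger_pool <- setdiff(genes$all, role_table$gene)
  rate <- ifelse(labels == design$cohort_names[1], design$tmb_rate_a,
                 design$tmb_rate_b)
  with_design_seed(design, 2L, {
    rows <- list()
    driver_truth <- nonsyn_truth <- stats::setNames(integer(length(labels)),
                                                    names(labels))
    tsg_pool <- role_table$gene[role_table$role %in% c("TSG", "both")]
    onc_pool <- role_table$gene[role_table$role %in% c("oncogene", "both")]
    for (sid in names(labels)) {
      n_nonsyn <- stats::rpois(1L, rate[sid] * design$capture_size_mb)
      n_driver <- stats::rbinom(1L, n_nonsyn, design$driver_fraction)
      n_pass <- n_nonsyn - n_driver
      nonsyn_truth[sid] <- n_nonsyn
      driver_truth[sid] <- n_driver
      mk <- function(n, gene, class, sift, polyphen, cosmic, cosmic_driver) {
        if (n == 0L) return(NULL)
        data.frame(sample_id = sid, gene = gene, variant_class = class,
                   sift_call = sift, polyphen_call = polyphen,
                   cosmic_count = cosmic, cosmic_driver_count = cosmic_driver,
                   exonic = TRUE, stringsAsFactors = FALSE)
      }
      if (n_driver > 0L) {
        kind <- sample(3L, n_driver, replace = TRUE)
        rows[[length(rows) + 1L]] <- rbind(
          mk(sum(kind == 1L), sample(tsg_pool, sum(kind == 1L), replace = TRUE),
             "nonsense", NA, NA, 0L, 0L),
          mk(sum(kind == 2L), sample(tsg_pool, sum(kind == 2L), replace = TRUE),
             "missense", "deleterious", "possibly_damaging", 0L, 0L),
          mk(sum(kind == 3L), sample(onc_pool, sum(kind == 3L), replace = TRUE),
             "missense", "tolerated", "benign", 5L, 0L))
      }
      n_syn <- stats::rpois(1L, 0.3 * rate[sid] * design$capture_size_mb)
      n_indel <- stats::rpois(1L, 0.1 * rate[sid] * design$capture_size_mb)
      rows[[length(rows) + 1L]] <- rbind(
        mk(n_pass, sample(passenger_pool, n_pass, replace = TRUE),
           "missense", "tolerated", "benign", 0L, 0L),
        mk(n_syn, sample(passenger_pool, n_syn, replace = TRUE),
           "synonymous", NA, NA, 0L, 0L),
        mk(n_indel, sample(passenger_pool, n_indel, replace = TRUE),
           "frameshift_indel", NA, NA, 0L, 0L))
    }
    variants <- do.call(rbind, rows)
    if (is.null(variants)) {
      variants <- data.frame(sample_id = character(), gene = character(),
                             variant_class = character(), sift_call = character(),
                             polyphen_call = character(),
                             cosmic_count = integer(),
                             cosmic_driver_count = integer(),
                             exonic = logical(), stringsAsFactors = FALSE)
    }
    rownames(variants) <- NULL
    class(variants) <- c("variant_table", "data.frame")
    list(variants = variants, role_table = role_table,
         driver_count = driver_truth, nonsyn_count = nonsyn_truth)
  })
}

#' Simulate copy-number segment profiles
#'
#' The toy genome is `n_chromosomes` autosomes of `chromosome_length` bp.
#' Each sample draws an aberrant fraction from a Beta distribution centred on
#' its cohort's design fraction (exact when the fraction is 0 or 1, or the
#' concentration is infinite); on every chromosome, a prefix of that fraction
#' is set to one copy above or below the rounded ploidy, the remainder to the
#' rounded ploidy. By construction each sample's wGII equals its recorded
#' realised fraction.
#'
#' @param design A [simulation_design].
#' @return List: `profiles` (named list of `segment_profile`s) and ground
#'   truth `aberrant_fraction` per sample (after rounding to whole bases).
#' @export
simulate_segments <- function(design) {
  labels <- design_labels(design)
  f0 <- ifelse(labels == design$cohort_names[1], design$aberrant_fraction_a,
               design$aberrant_fraction_b)
  L <- design$chromosome_length
  chroms <- as.character(seq_len(design$n_chromosomes))
  ref_cn <- floor(design$ploidy + 0.5)
  with_design_seed(design, 3L, {
    truth <- stats::setNames(numeric(length(labels)), names(labels))
    profiles <- lapply(names(labels), function(sid) {
      f <- f0[sid]
      if (f > 0 && f < 1 && is.finite(design$aberrant_concentration)) {
        c0 <- design$aberrant_concentration
        f <- stats::rbeta(1L, c0 * f0[sid], c0 * (1 - f0[sid]))
      }
      n_ab <- round(f * L)
      segs <- do.call(rbind, lapply(chroms, function(ch) {
        cn_ab <- ref_cn + sample(c(-1L, 1L), 1L)
        if (cn_ab < 0L) cn_ab <- ref_cn + 1L
        if (n_ab == 0) {
          data.frame(chrom = ch, start = 0, end = L, total_cn = ref_cn)
        } else if (n_ab == L) {
          data.frame(chrom = ch, start = 0, end = L, total_cn = cn_ab)
        } else {
          data.frame(chrom = c(ch, ch), start = c(0, n_ab), end = c(n_ab, L),
                     total_cn = c(cn_ab, ref_cn))
        }
      }))
      truth[sid] <<- n_ab / L
      segment_profile(sid, segs, design$ploidy,
                      chromosome_lengths = stats::setNames(rep(L, length(chroms)),
                                                           chroms))
    })
    list(profiles = stats::setNames(profiles, names(labels)),
         aberrant_fraction = truth)
  })
}

#' Simulate trinucleotide context counts
#'
#' Per sample, `n` single-base substitutions are distributed over the 96
#' contexts as Multinomial(n, catalog %*% exposure) with the cohort's design
#' exposure vector.
#'
#' @param design A [simulation_design].
#' @param catalog A `signature_catalog` containing the signatures named in
#'   `design$signature_weights` (other catalog signatures get weight 0).
#' @param n_mutations Optional named per-sample totals; defaults to Poisson
#'   draws with mean `tmb_rate x capture_size_mb`.
#' @return List: `counts` (samples x 96 matrix) and ground truth `exposures`
#'   (samples x catalog-signatures matrix of the generating mixtures).
#' @export
simulate_contexts <- function(design, catalog = toy_signature_catalog(),
                              n_mutations = NULL) {
  labels <- design_labels(design)
  P <- unclass(catalog)
  weight_vec <- function(w) {
    miss <- setdiff(names(w), colnames(P))
    if (length(miss))
      validation_error(paste("signature_weights name(s) not in catalog:",
                             paste(miss, collapse = ", ")))
    v <- stats::setNames(numeric(ncol(P)), colnames(P))
    v[names(w)] <- w
    v
  }
  wa <- weight_vec(design$signature_weights$a)
  wb <- weight_vec(design$signature_weights$b)
  with_design_seed(design, 4L, {
    if (is.null(n_mutations)) {
      rate <- ifelse(labels == design$cohort_names[1], design$tmb_rate_a,
                     design$tmb_rate_b)
      n_mutations <- stats::setNames(
        stats::rpois(length(labels), rate * design$capture_size_mb),
        names(labels))
    }
    counts <- t(vapply(names(labels), function(sid) {
      w <- if (labels[sid] == design$cohort_names[1]) wa else wb
      p <- drop(P %*% w)
      if (n_mutations[sid] == 0) rep(0L, 96L)
      else drop(stats::rmultinom(1L, n_mutations[sid], p))
    }, numeric(96)))
    colnames(counts) <- rownames(P)
    expo <- rbind(matrix(wa, design$n_cohort_a, length(wa), byrow = TRUE),
                  matrix(wb, design$n_cohort_b, length(wb), byrow = TRUE))
    dimnames(expo) <- list(names(labels), colnames(P))
    list(counts = counts, exposures = expo)
  })
}

#' Simulate a complete analysis bundle
#'
#' Runs every generator of the design and returns all pipeline inputs plus a
#' ground-truth manifest (shifted genes, injected driver counts, realised
#' aberrant fractions, generating exposures).
#'
#' @param design A [simulation_design].
#' @param catalog Signature catalog used for the context counts.
#' @return List with elements `expr`, `collection`, `variants`, `role_table`,
#'   `profiles`, `context_counts`, `catalog`, `labels`, and `ground_truth`.
#' @export
simulate_bundle <- function(design, catalog = toy_signature_catalog()) {
  ex <- simulate_expression(design)
  sets <- simulate_gene_sets(design)
  vs <- simulate_variants(design)
  sg <- simulate_segments(design)
  cx <- simulate_contexts(design, catalog,
                          n_mutations = pmax(vs$nonsyn_count, 1L))
  list(expr = ex$expr, collection = sets,
       variants = vs$variants, role_table = vs$role_table,
       profiles = sg$profiles, context_counts = cx$counts, catalog = catalog,
       labels = design_labels(design),
       ground_truth = list(shifted_genes = ex$shifted_genes,
                           immune_genes = design_genes(design)$immune,
                           driver_count = vs$driver_count,
                           nonsyn_count = vs$nonsyn_count,
                           aberrant_fraction = sg$aberrant_fraction,
                           exposures = cx$exposures,
                           seed = design$seed))
}

#' Write a simulated bundle to disk
#'
#' Serialises every component in the package's interchange formats (TPM TSV,
#' GMT + category TSV, variant TSV, SEG + ploidy TSV, context-count TSV,
#' catalog TSV, label TSV) plus a `ground_truth.json` manifest.
#'
#' @param bundle From [simulate_bundle].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_expression(bundle$expr, fp("expression_tpm.tsv"))
  write_gmt(bundle$collection, fp("gene_sets.gmt"), fp("gene_set_categories.tsv"))
  write_variants(bundle$variants, fp("variants.tsv"))
  utils::write.table(bundle$role_table, fp("gene_roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_segments(bundle$profiles, fp("segments.tsv"), fp("ploidy.tsv"))
  write_context_counts(bundle$context_counts, fp("context_counts.tsv"))
  write_signature_catalog(bundle$catalog, fp("signature_catalog.tsv"))
  labels_df <- data.frame(sample_id = names(bundle$labels),
                          cohort = unname(bundle$labels),
                          cancer_type = unname(bundle$expr$cancer_type))
  utils::write.table(labels_df, fp("labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- bundle$ground_truth
  gt$exposures <- as.data.frame(gt$exposures)
  jsonlite::write_json(gt, fp("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
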