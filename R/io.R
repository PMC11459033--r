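# Readers and writers for the plain-text formats the pipeline exchanges.
# All genomic intervals are converted at ingest to a single internal
# convention: 0-based half-open [start, end). SEG-style input is declared
# 1-based inclusive and converted exactly once, here.

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift_indel",
                     "inframe_indel", "splice_site", "synonymous")
SNV_CLASSES <- c("missense", "nonsense", "splice_site", "synonymous")
SIFT_LEVELS <- c("deleterious", "tolerated")
POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign")

#' Expression matrix container
#'
#' A genes-by-samples matrix of `log2(TPM + pseudocount)` values with optional
#' per-sample cohort and cancer-type annotation.
#'
#' @param values Numeric matrix, rows = genes (rownames required), columns =
#'   samples (colnames required); no missing values.
#' @param cohort Optional character vector of cohort labels, one per sample.
#' @param cancer_type Optional character vector of cancer types, one per sample.
#' @param pseudocount Pseudocount used in the log transform (kept for exact
#'   round-tripping back to TPM).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, cohort = NULL, cancer_type = NULL,
                        pseudocount = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    validation_error("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    validation_error("expression matrix needs gene rownames and sample colnames")
  if (anyNA(values)) validation_error("expression matrix contains missing values")
  if (anyDuplicated(rownames(values)))
    validation_error("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    validation_error("duplicate sample identifiers in expression matrix")
  check_annot <- function(x, name) {
    if (is.null(x)) return(NULL)
    if (length(x) != ncol(values))
      validation_error(sprintf("`%s` must have one entry per sample", name))
    stats::setNames(as.character(x), colnames(values))
  }
  structure(list(values = values,
                 cohort = check_annot(cohort, "cohort"),
                 cancer_type = check_annot(cancer_type, "cancer_type"),
                 pseudocount = pseudocount),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (log2 TPM + %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  if (!is.null(x$cohort)) {
    tab <- table(x$cohort)
    cat("  cohorts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a TPM expression matrix
#'
#' Reads a genes-by-samples TSV of raw (non-negative) TPM values and returns
#' the log2-transformed matrix, `log2(TPM + pseudocount)`. The first column
#' holds gene identifiers, the header holds sample identifiers; sample order
#' is preserved.
#'
#' @param path TSV path.
#' @param pseudocount Non-negative value added before the log transform
#'   (default 1, so a TPM of zero maps to a log value of zero).
#' @param cohort,cancer_type Optional per-sample annotation, either vectors in
#'   column order or named by sample id.
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, pseudocount = 1, cohort = NULL,
                            cancer_type = NULL) {
  if (pseudocount < 0) validation_error("pseudocount must be non-negative")
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || length(strsplit(header, "\t", fixed = TRUE)[[1]]) < 2L)
    format_error("expression file needs a header with gene id plus sample columns")
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    validation_error(sprintf("duplicated gene identifier(s): %s",
                             paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) format_error("non-numeric expression values")
  if (anyNA(m)) validation_error("missing TPM values")
  if (any(m < 0)) validation_error("negative TPM values")
  rownames(m) <- genes
  reorder_annot <- function(x) {
    if (!is.null(x) && !is.null(names(x))) x[colnames(m)] else x
  }
  expr_matrix(log2(m + pseudocount), cohort = reorder_annot(cohort),
              cancer_type = reorder_annot(cancer_type), pseudocount = pseudocount)
}

#' @rdname read_expression
#' @param expr An [expr_matrix] to write back as raw TPM (inverting the log
#'   transform with the stored pseudocount), so that write then read is the
#'   identity.
#' @export
write_expression <- function(expr, path) {
  tpm <- 2^expr$values - expr$pseudocount
  tpm[abs(tpm) < 1e-12] <- 0
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample cohort labels
#'
#' TSV with columns `sample_id`, `cohort` and optionally `cancer_type`.
#'
#' @param path TSV path.
#' @return Data frame with one row per sample.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(tab)))
    format_error("label file needs columns sample_id and cohort")
  if (anyDuplicated(tab$sample_id))
    validation_error("duplicated sample_id in label file")
  tab
}

#' Gene-set collections (GMT)
#'
#' `read_gmt` parses a standard GMT file (tab-separated: set name, description,
#' member genes). An optional sidecar category table (TSV with columns
#' `set_name`, `category`) marks immune sets: any set whose category equals
#' `"immune"` (case-insensitive) is flagged.
#'
#' @param path GMT path.
#' @param category_path Optional category TSV path.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `immune` (named logical).
#' @export
read_gmt <- function(path, category_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    format_error(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]))
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    validation_error(sprintf("duplicated gene set name(s): %s",
                             paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  immune <- rep(FALSE, length(sets))
  names(immune) <- names_
  if (!is.null(category_path)) {
    cat_tab <- utils::read.delim(category_path, stringsAsFactors = FALSE)
    if (!all(c("set_name", "category") %in% names(cat_tab)))
      format_error("category file needs columns set_name and category")
    hit <- cat_tab$set_name[tolower(cat_tab$category) == "immune"]
    immune[names_ %in% hit] <- TRUE
  }
  gene_set_collection(sets, immune)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (no empty sets).
#' @param immune Logical vector flagging immune sets (recycled from FALSE).
#' @export
gene_set_collection <- function(sets, immune = NULL) {
  if (length(sets) == 0L) validation_error("empty gene set collection")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    validation_error("all gene sets must be named")
  if (any(lengths(sets) == 0L)) validation_error("empty gene set")
  if (is.null(immune)) immune <- rep(FALSE, length(sets))
  immune <- stats::setNames(as.logical(immune), names(sets))
  structure(list(sets = sets, immune = immune), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (%d immune), sizes %d-%d\n",
              length(x$sets), sum(x$immune), min(lengths(x$sets)),
              max(lengths(x$sets))))
  invisible(x)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` to serialise.
#' @export
write_gmt <- function(collection, path, category_path = NULL) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  if (!is.null(category_path)) {
    df <- data.frame(set_name = names(collection$sets),
                     category = ifelse(collection$immune, "immune", "other"))
    utils::write.table(df, category_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a somatic variant table
#'
#' MAF-like TSV with columns `sample_id`, `gene`, `variant_class`, `sift_call`,
#' `polyphen_call`, `cosmic_count`, `cosmic_driver_count`, `exonic`. Variant
#' classes are matched case-insensitively against
#' missense / nonsense / frameshift_indel / inframe_indel / splice_site /
#' synonymous; SIFT and PolyPhen calls may be NA (e.g. for indels).
#'
#' @param path TSV path.
#' @return Data frame of class `variant_table`.
#' @export
read_variants <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  validate_variants(tab)
}

validate_variants <- function(tab) {
  need <- c("sample_id", "gene", "variant_class", "sift_call", "polyphen_call",
            "cosmic_count", "cosmic_driver_count", "exonic")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    format_error(paste("variant table missing column(s):",
                       paste(miss, collapse = ", ")))
  tab$variant_class <- tolower(tab$variant_class)
  bad <- setdiff(unique(tab$variant_class), VARIANT_CLASSES)
  if (length(bad))
    validation_error(paste("unknown variant class:", paste(bad, collapse = ", ")))
  tab$sift_call <- tolower(tab$sift_call)
  if (!all(tab$sift_call %in% SIFT_LEVELS | is.na(tab$sift_call)))
    validation_error("sift_call must be deleterious / tolerated / NA")
  tab$polyphen_call <- tolower(tab$polyphen_call)
  if (!all(tab$polyphen_call %in% POLYPHEN_LEVELS | is.na(tab$polyphen_call)))
    validation_error("polyphen_call must be probably_damaging / possibly_damaging / benign / NA")
  if (any(is.na(tab$cosmic_count)) || any(tab$cosmic_count < 0) ||
      any(is.na(tab$cosmic_driver_count)) || any(tab$cosmic_driver_count < 0))
    validation_error("COSMIC recurrence counts must be non-negative integers")
  tab$exonic <- as.logical(tab$exonic)
  if (anyNA(tab$exonic)) validation_error("exonic must be TRUE/FALSE")
  class(tab) <- c("variant_table", "data.frame")
  tab
}

#' @rdname read_variants
#' @param variants A `variant_table` to write.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene role table
#'
#' TSV with columns `gene`, `role` (`TSG`, `oncogene` or `both`) and an
#' optional logical `immune_gene` column marking membership of the immune
#' system pathway category.
#'
#' @param path TSV path.
#' @return Data frame with unique genes.
#' @export
read_gene_roles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "role") %in% names(tab)))
    format_error("gene role table needs columns gene and role")
  if (anyDuplicated(tab$gene)) validation_error("duplicated gene in role table")
  if (!all(tab$role %in% c("TSG", "oncogene", "both")))
    validation_error("role must be TSG / oncogene / both")
  if (is.null(tab$immune_gene)) tab$immune_gene <- FALSE
  tab$immune_gene <- as.logical(tab$immune_gene)
  tab
}

#' Copy-number segment profiles
#'
#' `read_segments` reads a SEG-like TSV (`sample_id`, `chrom`, `start`, `end`,
#' `total_cn`; coordinates 1-based inclusive) together with a per-sample ploidy
#' TSV (`sample_id`, `ploidy`) and returns one `segment_profile` per sample.
#' Coordinates are converted once, at ingest, to the internal 0-based
#' half-open convention.
#'
#' @param path Segment TSV path.
#' @param ploidy Either the path of a ploidy TSV or a data frame with columns
#'   `sample_id`, `ploidy`.
#' @return Named list of `segment_profile` objects.
#' @export
read_segments <- function(path, ploidy) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "total_cn")
  if (!all(need %in% names(tab)))
    format_error(paste("segment file needs columns",
                       paste(need, collapse = ", ")))
  if (any(tab$end < tab$start))
    validation_error("segment end < start")
  if (any(tab$total_cn < 0) || any(tab$total_cn != round(tab$total_cn)))
    validation_error("total_cn must be non-negative integers")
  if (is.character(ploidy)) ploidy <- utils::read.delim(ploidy, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "ploidy") %in% names(ploidy)))
    format_error("ploidy table needs columns sample_id and ploidy")
  # 1-based inclusive -> 0-based half-open
  tab$start <- tab$start - 1L
  by_sample <- split(tab[c("chrom", "start", "end", "total_cn")], tab$sample_id)
  profiles <- lapply(names(by_sample), function(sid) {
    pl <- ploidy$ploidy[match(sid, ploidy$sample_id)]
    if (is.na(pl)) validation_error(sprintf("no ploidy for sample %s", sid))
    segment_profile(sid, by_sample[[sid]], pl)
  })
  stats::setNames(profiles, names(by_sample))
}

#' @rdname read_segments
#' @param sample_id Sample identifier.
#' @param segments Data frame `chrom`, `start`, `end`, `total_cn` with 0-based
#'   half-open coordinates, non-overlapping within each chromosome.
#' @param chromosome_lengths Optional named vector of autosome lengths (bp).
#' @export
segment_profile <- function(sample_id, segments, ploidy,
                            chromosome_lengths = NULL) {
  segments <- as.data.frame(segments)
  if (any(segments$end <= segments$start))
    validation_error("segments must have end > start (0-based half-open)")
  assert_scalar_number(ploidy, "ploidy", positive = TRUE)
  for (sub in split(segments, segments$chrom)) {
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)]))
      validation_error(sprintf("overlapping segments on %s (sample %s)",
                               sub$chrom[1], sample_id))
  }
  structure(list(sample_id = sample_id,
                 segments = segments[order(segments$chrom, segments$start), ],
                 ploidy = ploidy,
                 chromosome_lengths = chromosome_lengths),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("segment_profile %s: %d segments on %d chromosomes, ploidy %.2f\n",
              x$sample_id, nrow(x$segments), length(unique(x$segments$chrom)),
              x$ploidy))
  invisible(x)
}

#' @rdname read_segments
#' @param profiles Named list of `segment_profile`s to serialise (writes
#'   1-based inclusive coordinates, plus a ploidy table when `ploidy_path`
#'   is given).
#' @param ploidy_path Optional path for the companion ploidy TSV.
#' @export
write_segments <- function(profiles, path, ploidy_path = NULL) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, chrom = p$segments$chrom,
               start = p$segments$start + 1L, end = p$segments$end,
               total_cn = p$segments$total_cn)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ploidy_path)) {
    pl <- data.frame(sample_id = vapply(profiles, `[[`, "", "sample_id"),
                     ploidy = vapply(profiles, `[[`, 0, "ploidy"))
    utils::write.table(pl, ploidy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an SBS signature catalog
#'
#' TSV with a `context` column holding the 96 trinucleotide substitution
#' classes (e.g. `A[C>A]A`) and one probability column per signature. Each
#' signature column must sum to 1 (tolerance 1e-6).
#'
#' @param path TSV path.
#' @return A numeric 96-by-K matrix of class `signature_catalog` with context
#'   rownames.
#' @export
read_signature_catalog <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"context" %in% names(tab))
    format_error("signature catalog needs a context column")
  m <- as.matrix(tab[, setdiff(names(tab), "context"), drop = FALSE])
  rownames(m) <- tab$context
  signature_catalog(m)
}

#' @rdname read_signature_catalog
#' @param m Numeric matrix, 96 context rows by signature columns.
#' @export
signature_catalog <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    validation_error("signature catalog must be a numeric matrix")
  ctx <- sbs_contexts()
  if (nrow(m) != length(ctx))
    validation_error("signature catalog must have 96 context rows")
  if (is.null(rownames(m))) rownames(m) <- ctx
  if (!setequal(rownames(m), ctx))
    validation_error("signature catalog rownames are not the 96 SBS contexts")
  m <- m[ctx, , drop = FALSE]
  if (any(m < 0)) validation_error("signature probabilities must be non-negative")
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-6))
    validation_error(sprintf("signature column(s) not summing to 1: %s",
                             paste(colnames(m)[abs(sums - 1) > 1e-6],
                                   collapse = ", ")))
  structure(m, class = c("signature_catalog", "matrix"))
}

#' @rdname read_signature_catalog
#' @param catalog A `signature_catalog` to write.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(context = rownames(catalog),
                   unclass(catalog)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample trinucleotide context counts
#'
#' TSV with a `sample_id` column plus the 96 context columns (`A[C>A]A`, ...).
#'
#' @param path TSV path.
#' @return Samples-by-96 integer matrix.
#' @export
read_context_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    format_error("context count file needs a sample_id column")
  ctx <- sbs_contexts()
  miss <- setdiff(ctx, names(tab))
  if (length(miss))
    format_error(sprintf("context count file missing %d context column(s)",
                         length(miss)))
  m <- as.matrix(tab[, ctx, drop = FALSE])
  rownames(m) <- tab$sample_id
  if (any(m < 0)) validation_error("context counts must be non-negative")
  m
}

#' @rdname read_context_counts
#' @param counts Samples-by-96 count matrix to write.
#' @export
write_context_counts <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TIL marker panel
#'
#' TSV with columns `cell_type` and `gene`; returns the panel as a named list
#' mapping each cell type to its marker genes. Marker genes may be shared
#' between cell types.
#'
#' @param path TSV path.
#' @return Named list of character vectors of class `marker_panel`.
#' @export
read_marker_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(tab)))
    format_error("marker panel needs columns cell_type and gene")
  panel <- split(tab$gene, tab$cell_type)
  marker_panel(panel)
}

#' @rdname read_marker_panel
#' @param panel Named list of marker gene vectors.
#' @export
marker_panel <- function(panel) {
  if (length(panel) == 0L || is.null(names(panel)))
    validation_error("marker panel must be a named list")
  if (any(lengths(panel) == 0L))
    validation_error("marker panel has an empty cell type")
  structure(lapply(panel, as.character), class = "marker_panel")
}

#' The bundled tumor-infiltrating leukocyte marker panel
#'
#' Marker-gene panel for immune cell scoring after Danaher and colleagues:
#' 14 marker-based immune cell populations defined by 60 genes (the CD4 T-cell
#' population of that method is derived by subtraction, not from markers, and
#' is not part of the panel). [til_scores] adds a total-TIL row over all panel
#' genes, giving 15 score rows.
#'
#' @return A `marker_panel`.
#' @export
default_marker_panel <- function() {
  path <- system.file("extdata", "danaher_til_panel.tsv",
                      package = "immunocompare")
  read_marker_panel(path)
}
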