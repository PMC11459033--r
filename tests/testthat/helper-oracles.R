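# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, per-base expansion, brute force) kept separate
# from the package's code paths.

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (valid without ties: null distribution is symmetric)
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  na <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  ws <- apply(utils::combn(n, na), 2, function(idx) sum(r[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

# two-sided Fisher p by enumerating the hypergeometric support
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# one-sided hypergeometric tail P(overlap >= k)
oracle_hyper_tail <- function(k, set_size, universe_size, query_size) {
  support <- k:min(set_size, query_size)
  sum(stats::dhyper(support, set_size, universe_size - set_size, query_size))
}

# driver call re-derived with independent nested-if logic
oracle_driver_call <- function(class, sift, polyphen, cosmic, cosmic_driver,
                               role) {
  if (is.na(role)) return(FALSE)
  snv_classes <- c("missense", "nonsense", "splice_site", "synonymous")
  hit <- FALSE
  if (role == "TSG" || role == "both") {
    if (class %in% c("frameshift_indel", "nonsense", "splice_site")) hit <- TRUE
    if (class == "missense") {
      if (!is.na(sift) && sift == "deleterious") hit <- TRUE
      if (!is.na(polyphen) && polyphen == "probably_damaging") hit <- TRUE
    }
    if (cosmic_driver >= 10) hit <- TRUE
  }
  if (role == "oncogene" || role == "both") {
    if ((class == "inframe_indel" || class %in% snv_classes) && cosmic >= 3)
      hit <- TRUE
  }
  hit
}

# wGII by literal per-base expansion of every segment
oracle_wgii_per_base <- function(profile) {
  segs <- profile$segments
  segs$chrom <- sub("^chr", "", as.character(segs$chrom))
  segs <- segs[segs$chrom %in% as.character(1:22), ]
  ref <- floor(profile$ploidy + 0.5)
  fr <- vapply(split(segs, segs$chrom), function(s) {
    per_base <- unlist(lapply(seq_len(nrow(s)), function(i) {
      rep(s$total_cn[i], s$end[i] - s$start[i])
    }))
    mean(per_base != ref)
  }, 0)
  mean(fr)
}

# random toy segment profile on 22 short autosomes; gaps and multi-segment
# chromosomes included
random_toy_profile <- function(sample_id, chrom_length = 1e4, ploidy = 2) {
  segs <- do.call(rbind, lapply(1:22, function(ch) {
    k <- sample(1:4, 1)
    cuts <- sort(sample(seq(0, chrom_length, by = 50), k + 1))
    if (cuts[1] > 0 && stats::runif(1) < 0.5) cuts[1] <- 0  # sometimes a gap
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1]
    keep <- ends > starts
    data.frame(chrom = as.character(ch), start = starts[keep],
               end = ends[keep], total_cn = sample(0:5, sum(keep), replace = TRUE))
  }))
  segment_profile(sample_id, segs, ploidy)
}

# NNLS refit of a context spectrum, normalised to fractions
oracle_nnls_fractions <- function(counts_row, catalog) {
  t_vec <- counts_row / sum(counts_row)
  w <- pracma::lsqnonneg(unclass(catalog), t_vec)$x
  w / sum(w)
}

# internal design helpers (not part of the exported surface)
design_genes_for_test <- function(d) immunocompare:::design_genes(d)
design_labels_for_test <- function(d) immunocompare:::design_labels(d)

# small deterministic expression fixture
toy_expr <- function(n_genes = 30, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, 4, 1), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  expr_matrix(abs(m))
}
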