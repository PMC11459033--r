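# Single-base-substitution mutational signature refitting. Each sample's
# 96-context mutation spectrum is decomposed as a nonnegative mixture of
# catalog signatures by iterative forward selection (the deconstructSigs
# approach): starting from the empty mixture, the weight update that most
# reduces the squared reconstruction error is applied until convergence, then
# weights below a reporting cutoff are zeroed and the remainder renormalised.

#' The 96 SBS trinucleotide contexts
#'
#' COSMIC ordering: substitutions C>A, C>G, C>T, T>A, T>C, T>G, each with the
#' 16 flanking-base combinations in alphabetical order, written e.g.
#' `A[C>A]A`.
#'
#' @return Character vector of length 96.
#' @export
sbs_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))
  }))
}

#' Estimate signature exposures by forward-selection refitting
#'
#' For each sample the normalised 96-context spectrum is approximated by a
#' nonnegative combination of catalog signatures. Weights are built up by
#' coordinate-wise exact line search: at every iteration the single-signature
#' weight change (bounded below so weights stay nonnegative) that most reduces
#' the squared error is applied; iteration stops when the relative error
#' improvement falls below `tol`. Weights are then normalised to fractions,
#' fractions below `min_fraction` are set to zero, and the rest renormalised
#' to sum to 1. Exposures are invariant to scaling a sample's counts.
#'
#' @param counts Samples-by-96 count matrix (rownames = sample ids, colnames
#'   = contexts as in [sbs_contexts]). All-zero samples are skipped with a
#'   message.
#' @param catalog A `signature_catalog` (96 x K).
#' @param min_fraction Reporting cutoff on fractions (default 0.06, the
#'   reference refitting tool's default); must be in `[0, 1)`.
#' @param tol Relative error-improvement threshold stopping the iteration.
#' @param max_iter Iteration cap.
#' @return List with `exposures` (samples x K fraction matrix, rows summing
#'   to 1 for fitted samples) and `residual` (per-sample Euclidean norm of
#'   the final reconstruction error).
#' @export
estimate_exposures <- function(counts, catalog, min_fraction = 0.06,
                               tol = 1e-8, max_iter = 1000L) {
  if (min_fraction < 0 || min_fraction >= 1)
    validation_error("min_fraction must be in [0, 1)")
  ctx <- sbs_contexts()
  if (is.null(colnames(counts)) || !setequal(colnames(counts), ctx))
    validation_error("count columns must be the 96 SBS contexts")
  counts <- counts[, ctx, drop = FALSE]
  P <- unclass(catalog)[ctx, , drop = FALSE]
  K <- ncol(P)
  nsamp <- nrow(counts)
  expo <- matrix(0, nsamp, K, dimnames = list(rownames(counts), colnames(P)))
  resid <- stats::setNames(rep(NA_real_, nsamp), rownames(counts))
  cross <- crossprod(P)               # K x K Gram matrix
  norms <- diag(cross)
  for (s in seq_len(nsamp)) {
    tot <- sum(counts[s, ])
    if (tot == 0) {
      log_note("estimate_exposures: skipping all-zero sample %s",
               rownames(counts)[s] %||% as.character(s))
      next
    }
    t_vec <- counts[s, ] / tot
    w <- rep(0, K)
    err <- sum(t_vec^2)
    Pt <- drop(crossprod(P, t_vec))   # P' t
    for (it in seq_len(max_iter)) {
      grad <- Pt - drop(cross %*% w)  # P'(t - Pw)
      d <- grad / norms               # unconstrained optimal step per signature
      d <- pmax(d, -w)                # keep weights nonnegative
      red <- grad * d - 0.5 * norms * d^2   # error reduction per choice
      j <- which.max(red)
      if (red[j] <= tol * max(err, 1e-12)) break
      w[j] <- w[j] + d[j]
      err <- err - red[j]
    }
    frac <- if (sum(w) > 0) w / sum(w) else w
    frac[frac < min_fraction] <- 0
    if (sum(frac) > 0) frac <- frac / sum(frac)
    expo[s, ] <- frac
    # residual of the reconstruction with the reported fractions
    resid[s] <- sqrt(sum((t_vec - drop(P %*% frac))^2))
  }
  list(exposures = expo, residual = resid)
}

#' Filter signatures by patient support
#'
#' Keeps a signature when at least `min_patients` samples carry a nonzero
#' exposure fraction, removing signatures with predominantly zero values from
#' the downstream statistics.
#'
#' @param exposures Samples-by-signatures fraction matrix.
#' @param min_patients Inclusive patient-count threshold (default 10).
#' @return Character vector of retained signature names.
#' @export
filter_signatures <- function(exposures, min_patients = 10L) {
  support <- colSums(exposures > 0)
  colnames(exposures)[support >= min_patients]
}

#' Per-signature mutation counts
#'
#' Converts exposure fractions to signature-attributed mutation loads by
#' multiplying each sample's fractions with its TMB.
#'
#' @param exposures Samples-by-signatures fraction matrix.
#' @param tmb_per_sample Named TMB vector (must cover the exposure rows).
#' @return Samples-by-signatures matrix of `fraction * TMB`.
#' @export
signature_counts <- function(exposures, tmb_per_sample) {
  miss <- setdiff(rownames(exposures), names(tmb_per_sample))
  if (length(miss))
    validation_error(paste("no TMB for sample(s):", paste(miss, collapse = ", ")))
  exposures * tmb_per_sample[rownames(exposures)]
}

#' Toy SBS signature catalog
#'
#' A deterministic synthetic catalog of well-separated signatures for testing
#' and simulation: signature k concentrates ~90% of its mass on its own block
#' of 19 contexts, with a small uniform floor everywhere. Not a real COSMIC
#' catalog (those are user-supplied via [read_signature_catalog]).
#'
#' @param n_signatures Number of signatures (2--5).
#' @return A `signature_catalog`.
#' @export
toy_signature_catalog <- function(n_signatures = 5L) {
  if (n_signatures < 2L || n_signatures > 5L)
    validation_error("toy catalog supports 2 to 5 signatures")
  ctx <- sbs_contexts()
  m <- vapply(seq_len(n_signatures), function(k) {
    w <- rep(0.1 / 96, 96)
    block <- ((k - 1) * 19 + 1):(k * 19)
    # triangular profile within the block so contexts are distinguishable
    w[block] <- w[block] + 0.9 * (20 - abs(block - block[10])) /
      sum(20 - abs(block - block[10]))
    w / sum(w)
  }, numeric(96))
  dimnames(m) <- list(ctx, paste0("TOYSIG", seq_len(n_signatures)))
  signature_catalog(m)
}
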