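---
title: "Comparative immunogenomics of two tumor cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative immunogenomics of two tumor cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunocompare)
```

# What the package computes

`immunocompare` compares the immunogenomic landscape of two tumor cohorts of
unequal size — the motivating use case is a cancer-of-unknown-primary (CUP)
cohort of a few dozen patients against a mixed metastatic reference cohort
several times larger. The comparison runs on four layers:

1. **Transcriptome.** Genes are ranked by the standard deviation of their
   log2(TPM + 1) values across all samples of both cohorts pooled; the most
   variant genes (default 2000) enter a per-gene two-sided Wilcoxon rank-sum
   test with Benjamini–Hochberg adjustment. The reported effect is the
   difference of cohort means on the log2 scale, i.e. the log fold change of
   geometric mean TPM. Significant genes (default q < 0.25) feed a
   hypergeometric over-representation analysis against a user-supplied
   gene-set collection.
2. **Pathways.** Gene set variation analysis (GSVA) turns the expression
   matrix into per-sample pathway scores: each gene's expression is
   transformed through a cumulative density estimated across samples
   (Gaussian kernel, bandwidth sd/4, or the empirical CDF), genes are ranked
   within each sample, and a weighted Kolmogorov–Smirnov-like random walk
   over each gene set yields a score in [-1, 1] (sum of the largest positive
   and largest negative walk deviation). Sets with fewer than 10 or more
   than 500 matched genes are skipped. Pathway scores are compared between
   cohorts exactly like genes (Wilcoxon + BH, default q < 0.05), and each
   set carries an immune flag so the immune share of the significant sets
   can be read off.
3. **Immune cells.** Tumor-infiltrating leukocyte (TIL) scores follow the
   Danaher marker-gene approach: the score of a cell type in a sample is the
   arithmetic mean of its marker genes' log2 expression. The bundled panel
   has 14 marker-based cell populations over 60 genes; a total-TIL row (mean
   over all panel genes) makes 15 score rows. The original method defines a
   15th, CD4 T-cell, population by subtraction of scores rather than by
   markers, so it has no marker list to ship; and it computed scores on log2
   counts, whereas this pipeline scores log2 TPM like every other analysis
   layer — both differences are deliberate and documented here.
4. **Genome.** Tumor mutation burden (TMB) is the count of exonic
   non-synonymous single-nucleotide variants (missense, nonsense,
   splice-site; indels and synonymous SNVs excluded) per megabase of capture
   footprint (default 71.6 Mb). Driver mutations are called by role-specific
   rules: in tumor suppressors, truncating variants, missense variants
   called deleterious by SIFT or probably damaging by PolyPhen, and variants
   recurring ≥ 10 times in the COSMIC driver category; in oncogenes,
   non-frameshift indels and SNVs with ≥ 3 COSMIC occurrences; deletions in
   tumor suppressors and amplifications in oncogenes for copy-number events.
   Driver load is normalised per patient by dividing the driver count by
   TMB. Chromosomal instability is summarised by the weighted genome
   integrity index (wGII): per autosome, the covered fraction at total copy
   number different from the rounded sample ploidy, averaged over the 22
   autosomes. Mutational signature exposures are refit per sample from
   96-context spectra by iterative forward selection against a signature
   catalog, with a 0.06 reporting cutoff on fractions and a cohort-level
   filter keeping signatures carried by ≥ 10 patients.

Cohort contrasts everywhere use the same statistical kernel: two-sided
Wilcoxon rank-sum tests, BH-FDR across the features of each analysis layer,
and Fisher's exact test for per-gene mutation prevalence. Pairwise analyses
against individual cancer types of the reference cohort include only types
with at least 10 patients, with BH applied within each pairwise comparison
(matching per-panel displays rather than a global adjustment).

# The synthetic cohort generator

Patient-level data of the kind this pipeline targets is generally not
shareable, so the package ships a generator
(`simulation_design()` / `simulate_bundle()`) whose defaults define the
reference study conditions:

* cohort sizes 44 vs 213;
* log-normal expression: per-gene baseline means ~ N(3, 1.5²) on the log2
  scale, within-gene between-sample SD 1 (values truncated at 0, as
  log2(TPM + 1) values are);
* an immune-hot effect: +1 log2 on every immune gene (the marker panel plus
  an `IMMG` pool, 100–150 genes) in cohort A only;
* equal mutation rates of 2.5 non-synonymous SNVs/Mb in both cohorts over a
  71.6 Mb capture (per-sample counts Poisson), reflecting a null TMB
  contrast; 10% of non-synonymous variants are injected into cancer genes
  with driver-qualifying annotation, the rest are passengers, plus
  synonymous SNVs (30% of the rate) and frameshift indels (10%) to exercise
  the burden filters;
* a toy genome of 22 autosomes × 100 Mb; per-sample aberrant genome
  fractions drawn from a Beta distribution (concentration 10) centred at
  0.25 in cohort A and 0.30 in cohort B — cohort A slightly more stable, the
  direction the motivating comparison reported; by construction each
  sample's wGII equals its recorded ground-truth fraction exactly;
* trinucleotide spectra Multinomial(n, catalog × exposure) with identical
  exposure mixtures in both cohorts (no signature difference), over a
  deterministic 5-signature toy catalog of well-separated block signatures
  (`toy_signature_catalog()`; real COSMIC catalogs are user-supplied, none
  is bundled);
* cohort-B cancer types drawn from a nine-type multinomial in which eight
  named types typically exceed the 10-patient pairwise threshold.

Every generator is a pure function of the design (including its seed); each
stage uses its own seed substream so the pieces are individually
reproducible, and each bundle carries a ground-truth manifest (shifted
genes, injected driver counts, realised aberrant fractions, generating
exposures) that the tests consume.

What the generator deliberately does **not** model: gene–gene correlation,
batch and purity effects, overdispersed (non-Poisson) mutation counts, and
cancer-type-specific expression structure. Passing tests therefore
demonstrate that the pipeline recovers effects of the designed kind and
calibrates its error rates under exchangeable nulls — not that it is robust
to every artefact of real tumor data.

# Numerical and design choices

* **Pseudocount.** TPM values contain zeros; the log transform uses
  log2(TPM + 1) by default (zero maps to zero), configurable in
  `read_expression()`.
* **Coordinates.** Segment input is declared 1-based inclusive (the common
  SEG convention) and converted exactly once at ingest to 0-based half-open;
  all internal arithmetic uses widths `end - start`.
* **Wilcoxon implementation.** The kernel wraps `stats::wilcox.test`: exact
  enumeration when both groups have ≤ 25 observations and there are no
  ties, otherwise a tie-corrected normal approximation with continuity
  correction; constant pooled data returns p = 1. The exact path is pinned
  against a from-scratch enumeration oracle in the tests. Both modes are
  exposed because published analyses rarely state which was used.
* **GSVA settings.** Gaussian kernel on log2 expression, tau = 1, and the
  max-diff enrichment statistic — the defaults of the published algorithm
  for continuous expression; the ECDF kernel is available and is the one
  under which scores are exactly invariant to per-gene monotone transforms.
  Size bounds default to 10–500.
* **ORA universe.** Defaults to all genes of the expression matrix — the
  natural offline choice; curated database universes differ and can be
  supplied explicitly.
* **Top-gene lists.** "Top most significant" lists are sorted by ascending
  q-value; the sort order is a flag, since figure legends sometimes state
  the opposite of what they display.
* **Driver rules.** The deleterious-SNV clause applies to missense variants
  only (truncating classes are already captured, and take precedence in the
  rule tag); the COSMIC driver-category recurrence clause applies to any
  variant class in a tumor suppressor; genes with both roles fire on either
  path and the tag records which.
* **TMB-normalised driver load** divides by TMB per megabase; dividing by
  the raw mutation count is obtained by setting `capture_size_mb = 1`.
  Samples with TMB 0 yield a missing value rather than a division by zero.
* **wGII.** Reference copy number is the round-half-up of the real-valued
  ploidy; uncovered genome is excluded from the denominators; autosomes
  only. Oracle tests compare against literal per-base enumeration on
  profiles with short declared chromosome lengths (10–100 kb), where
  per-base expansion is exact and fast; chromosome length is a property of
  the profile, not of the method.
* **Signature refitting** uses coordinate-wise forward selection with exact
  line search, stopping when the relative error improvement falls below
  1e-8, then applies the 0.06 fraction cutoff and renormalises; with the
  cutoff at 0 the solution agrees with nonnegative least squares (checked
  against an independent NNLS oracle). Exposures are invariant to scaling a
  sample's counts; all-zero samples are skipped with a message.
* **UMAP** is visualisation-only plumbing: seeded, single-threaded, and
  duplicate expression profiles are embedded once and share coordinates
  (the stochastic layout would otherwise scatter exact duplicates
  arbitrarily). Nothing downstream consumes the embedding.

# Problem sizes used in the shipped checks

The package's own test suite and acceptance script run the full pipeline on
generated cohorts of 44 vs 213 samples with 250–500 genes (of which 80–100
immune), 50 gene sets, and 20–100 Monte-Carlo replicates for the power and
calibration checks; the wGII oracle uses 100 random 22-autosome profiles.
These sizes were chosen so that each statistical check has clear resolution
(effects of the designed magnitude are detected with margin, null
calibration bounds use binomial/Monte-Carlo standard errors) while the whole
suite remains quick to run; all of them are function arguments, and nothing
in the implementation depends on the matrix sizes.

# Known limitations

* The GSVA and signature-refitting implementations follow the published
  algorithms but are independent implementations; third-party score files
  produced by other tools may differ in tie handling and stopping rules.
* The marker panel ships with 14 marker-based cell types (plus the total-TIL
  row); analyses that require a subtraction-defined CD4 population should
  supply a custom panel and compute it downstream.
* Driver annotation consumes precomputed functional annotations (SIFT,
  PolyPhen, COSMIC counts) from the variant table; the package does not
  annotate variants itself.
* Fisher tests of per-gene prevalence collapse to sample-level
  presence/absence; multiplicity within a sample is ignored by design.
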