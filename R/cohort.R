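# The in-memory cohort container shared by the simulator, QC and the
# association harness.

#' Construct a rare-variant cohort object
#'
#' Bundles a sample-by-variant dosage matrix with the variant annotation and
#' sample phenotype tables. Dosages are minor-allele counts in \{0, 1, 2\};
#' missing calls are stored as zeros in `G` with the missing pattern kept in
#' `miss` and summarized per variant as `call_rate`.
#'
#' @param G Sample-by-variant dosage matrix (`Matrix` sparse or dense);
#'   rownames = sample ids, colnames = variant ids.
#' @param variants Data frame with one row per variant: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `exonic_function`, `cadd`,
#'   `af_public`, `call_rate` and optionally `population`, `spiked`.
#' @param samples Data frame with one row per sample: `sample`, `status`
#'   (0 = control, 1 = case) and optional covariate / `population` columns.
#' @param miss Optional logical sparse matrix (same shape as `G`) marking
#'   missing genotype calls.
#' @return Object of class `rv_cohort`.
#' @export
rv_cohort <- function(G, variants, samples, miss = NULL) {
  G <- methods::as(methods::as(G, "CsparseMatrix"), "generalMatrix")
  stopifnot(nrow(G) == nrow(samples), ncol(G) == nrow(variants))
  if (is.null(rownames(G))) rownames(G) <- samples$sample
  if (is.null(colnames(G))) colnames(G) <- variants$variant_id
  stopifnot(identical(rownames(G), as.character(samples$sample)),
            identical(colnames(G), as.character(variants$variant_id)))
  structure(list(G = G, variants = variants, samples = samples, miss = miss),
            class = "rv_cohort")
}

#' @export
print.rv_cohort <- function(x, ...) {
  cat(sprintf("rv_cohort: %d samples (%d cases / %d controls), %d variants, %d genes\n",
              nrow(x$samples), sum(x$samples$status == 1),
              sum(x$samples$status == 0), nrow(x$variants),
              length(unique(x$variants$gene))))
  invisible(x)
}

#' Assemble the model design for one gene of a cohort
#'
#' Thin wrapper around [assemble_design()] drawing genotypes, covariates and
#' annotations from an `rv_cohort`.
#'
#' @inheritParams test_gene
#' @return A `gene_design`.
#' @export
design_for_gene <- function(cohort, gene_id, config = bati_config()) {
  stopifnot(inherits(cohort, "rv_cohort"))
  vids <- cohort$variants$variant_id[cohort$variants$gene == gene_id]
  Gsub <- as.matrix(cohort$G[, as.character(vids), drop = FALSE])
  rownames(Gsub) <- rownames(cohort$G)
  assemble_design(Gsub, cohort$samples, cohort$variants, gene_id, config)
}

# Control-group allele frequency per variant (dosage-based, missing entries
# counted as reference, matching the zero-imputation rule).
control_af <- function(cohort) {
  ctrl <- cohort$samples$status == 0
  n_ctrl <- sum(ctrl)
  if (n_ctrl == 0L) return(rep(0, nrow(cohort$variants)))
  as.numeric(Matrix::colSums(cohort$G[ctrl, , drop = FALSE])) / (2 * n_ctrl)
}

# Restrict a cohort to a subset of variants (logical or index vector).
subset_variants <- function(cohort, keep) {
  rv_cohort(cohort$G[, keep, drop = FALSE],
            cohort$variants[keep, , drop = FALSE],
            cohort$samples,
            miss = if (!is.null(cohort$miss)) cohort$miss[, keep, drop = FALSE])
}
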