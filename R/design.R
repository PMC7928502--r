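#' Assemble the per-gene model design
#'
#' Builds the quantities needed to fit the hierarchical logistic model for
#' one gene: the binary phenotype vector y, the individual covariate matrix
#' X (with intercept), the genotype dosage matrix G (0/1/2 minor-allele
#' counts, missing entries imputed), and the variant-characteristic matrix Z
#' holding one indicator column per observed functional category plus one
#' column per configured numeric score.
#'
#' @param genotypes Numeric matrix (or `Matrix` sparse matrix) of dosages,
#'   samples in rows (rownames = sample ids), variants in columns (colnames =
#'   variant ids). `NA` entries are treated as missing calls and imputed
#'   according to `config$impute`.
#' @param covariates Data frame with columns `sample` (matching rownames of
#'   `genotypes`) and `status` (0 = control, 1 = case) plus any covariate
#'   columns named in `config$covariate_cols`.
#' @param annotations Data frame with columns `variant_id`, `gene`, the
#'   category column and the score columns named in `config`.
#' @param gene_id Gene to assemble; its variants are the annotation rows with
#'   `gene == gene_id` (a gene with no variants yields an empty-G design,
#'   p = 0).
#' @param config A [bati_config()].
#'
#' @return An object of class `gene_design`: a list with elements `y`, `X`,
#'   `G`, `Z`, `variant_ids`, `categories`, `gene_id` and the dimensions
#'   `n`, `m`, `p`, `q`.
#' @export
assemble_design <- function(genotypes, covariates, annotations, gene_id,
                            config = bati_config()) {
  stopifnot(is.data.frame(covariates), is.data.frame(annotations))
  if (!all(c("sample", "status") %in% names(covariates))) {
    stopf("covariate table must have 'sample' and 'status' columns")
  }
  samp <- rownames(genotypes)
  if (is.null(samp)) stopf("genotype matrix must have sample rownames")
  idx <- match(samp, covariates$sample)
  if (anyNA(idx)) {
    stopf("unknown sample id(s): %s",
          paste(head(samp[is.na(idx)], 5), collapse = ", "))
  }
  cov <- covariates[idx, , drop = FALSE]
  if (anyNA(cov$status)) {
    stopf("sample(s) without phenotype: %s",
          paste(head(cov$sample[is.na(cov$status)], 5), collapse = ", "))
  }
  n <- nrow(cov)
  if (n == 0L) stopf("gene '%s': zero samples in design", gene_id)
  y <- as.numeric(cov$status)
  if (!all(y %in% c(0, 1))) stopf("status must be coded 0/1")

  miss_cov <- setdiff(config$covariate_cols, names(cov))
  if (length(miss_cov)) {
    stopf("covariate column(s) not found: %s", paste(miss_cov, collapse = ", "))
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  for (cc in config$covariate_cols) {
    X <- cbind(X, as.numeric(cov[[cc]]))
    colnames(X)[ncol(X)] <- cc
  }

  ann <- annotations[annotations$gene == gene_id, , drop = FALSE]
  vids <- as.character(ann$variant_id)
  if (length(vids)) {
    missing_g <- setdiff(vids, colnames(genotypes))
    if (length(missing_g)) {
      stopf("gene '%s': variant(s) absent from genotype matrix: %s",
            gene_id, paste(head(missing_g, 5), collapse = ", "))
    }
  }
  p <- length(vids)

  if (p > 0L) {
    G <- as.matrix(genotypes[, vids, drop = FALSE])
    if (anyNA(G)) {
      if (config$impute == "zero") {
        G[is.na(G)] <- 0
      } else {
        for (j in seq_len(ncol(G))) {
          nas <- is.na(G[, j])
          if (any(nas)) G[nas, j] <- mean(G[!nas, j]) %||% 0
        }
        G[is.na(G)] <- 0
      }
    }
    if (any(G < 0 | G > 2)) stopf("dosages must lie in [0, 2]")

    cats <- sort(unique(as.character(ann[[config$category_col]])))
    Z <- matrix(0, nrow = p, ncol = 0)
    for (ct in cats) {
      Z <- cbind(Z, as.numeric(ann[[config$category_col]] == ct))
      colnames(Z)[ncol(Z)] <- ct
    }
    for (sc in config$score_cols) {
      if (!sc %in% names(ann)) stopf("score column '%s' not in annotations", sc)
      v <- as.numeric(ann[[sc]])
      if (anyNA(v)) {
        stopf("gene '%s': missing %s score for variant(s) %s", gene_id, sc,
              paste(head(vids[is.na(v)], 5), collapse = ", "))
      }
      if (config$center_scores) v <- v - mean(v)
      Z <- cbind(Z, v)
      colnames(Z)[ncol(Z)] <- sc
    }
  } else {
    G <- matrix(0, nrow = n, ncol = 0)
    Z <- matrix(0, nrow = 0, ncol = 0)
    cats <- character()
  }

  des <- structure(list(
    y = y, X = X, G = G, Z = Z,
    variant_ids = vids,
    categories = if (p) as.character(ann[[config$category_col]]) else character(),
    gene_id = gene_id,
    n = n, m = ncol(X), p = p, q = ncol(Z)
  ), class = "gene_design")
  validate_design(des)
  des
}

validate_design <- function(design) {
  stopifnot(inherits(design, "gene_design"))
  with(design, {
    stopifnot(length(y) == n, nrow(X) == n, nrow(G) == n,
              ncol(G) == p, ncol(Z) == q)
    if (p > 0) stopifnot(nrow(Z) == p)
  })
  invisible(design)
}

# Latent-field design matrix W = [X, G Z, G]; columns ordered alpha (m),
# omega (q), delta (p). Returns W plus the block index map.
design_matrix <- function(design) {
  W <- design$X
  if (design$p > 0L && design$q > 0L) W <- cbind(W, design$G %*% design$Z)
  W <- cbind(W, design$G)
  blocks <- list(
    alpha = seq_len(design$m),
    omega = if (design$q) design$m + seq_len(design$q) else integer(),
    delta = if (design$p) design$m + design$q + seq_len(design$p) else integer()
  )
  colnames(W) <- c(colnames(design$X),
                   if (design$q) colnames(design$Z),
                   design$variant_ids)
  list(W = W, blocks = blocks, d = ncol(W))
}

#' Convert VCF genotype strings to minor-allele dosages
#'
#' `"0/1"` and `"0|1"` count one alternate allele, `"1/1"` two; `"./."`,
#' `".|."` and `"."` yield `NA` (missing call, imputed later at design
#' assembly). For split multi-allelic records, pass the alternate-allele
#' index to count via `allele`.
#'
#' @param gt Character vector of VCF GT fields.
#' @param allele Alternate allele index counted as the minor allele
#'   (default 1).
#' @return Numeric vector of dosages in \{0, 1, 2\} or `NA`.
#' @export
dosage_from_gt <- function(gt, allele = 1L) {
  parts <- strsplit(as.character(gt), "[/|]")
  vapply(parts, function(a) {
    if (all(a %in% ".")) return(NA_real_)
    sum(a == as.character(allele))
  }, numeric(1))
}

#' @export
print.gene_design <- function(x, ...) {
  cat(sprintf("gene_design '%s': n = %d samples, m = %d covariates, p = %d variants, q = %d characteristics\n",
              x$gene_id, x$n, x$m, x$p, x$q))
  invisible(x)
}
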