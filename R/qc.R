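# Variant filtering and sample quality control preceding association
# testing.

#' Filter variants on frequency, deleteriousness and functional category
#'
#' Keeps a variant iff its largest allele frequency (public panels and,
#' when supplied, the randomized control group) is at most `af_max`, its
#' deleteriousness score is at least `score_min`, and it is not annotated
#' as synonymous (when `drop_synonymous`). `NA` panel frequencies count as
#' unobserved (frequency 0); a missing score or category is an error naming
#' the variant.
#'
#' @param records Variant data frame with columns `variant_id`, the category
#'   column, the score column, and one or more frequency columns matching
#'   `^af_` (e.g. `af_public`).
#' @param af_max Maximum allele frequency retained (default 0.01).
#' @param score_min Minimum score retained (default 10).
#' @param drop_synonymous Drop variants annotated `synonymous`.
#' @param control_af Optional numeric vector of control-group allele
#'   frequencies (same order as `records`), e.g. from a cohort's randomized
#'   control split.
#' @param score_col,category_col Column names (defaults `cadd`,
#'   `exonic_function`).
#' @return The kept rows of `records`.
#' @export
filter_variants <- function(records, af_max = 0.01, score_min = 10,
                            drop_synonymous = TRUE, control_af = NULL,
                            score_col = "cadd",
                            category_col = "exonic_function") {
  stopifnot(is.data.frame(records))
  for (cc in c(score_col, category_col)) {
    if (!cc %in% names(records)) stopf("annotation column '%s' missing", cc)
  }
  score <- as.numeric(records[[score_col]])
  category <- as.character(records[[category_col]])
  bad <- is.na(score) | is.na(category)
  if (any(bad)) {
    stopf("missing annotation for variant(s): %s",
          paste(head(records$variant_id[bad], 5), collapse = ", "))
  }
  af_cols <- grep("^af_", names(records), value = TRUE)
  af <- if (length(af_cols)) {
    m <- as.matrix(records[af_cols])
    m[is.na(m)] <- 0
    do.call(pmax, c(as.data.frame(m), list(0)))
  } else rep(0, nrow(records))
  if (!is.null(control_af)) {
    stopifnot(length(control_af) == nrow(records))
    af <- pmax(af, control_af)
  }
  keep <- af <= af_max & score >= score_min
  if (drop_synonymous) keep <- keep & category != "synonymous"
  records[keep, , drop = FALSE]
}

#' Filter variants on call rate
#'
#' Default is the strict rule `call_rate > min_rate` (call rate "higher
#' than" the threshold, as used for simulation cohorts); set
#' `strict = FALSE` for `call_rate >= min_rate` (the "at least" rule used
#' in application settings, conventionally at 0.95).
#'
#' @param records Variant data frame with a `call_rate` column in [0, 1].
#' @param min_rate Call-rate threshold in [0, 1] (default 0.85).
#' @param strict Use strict inequality (default TRUE).
#' @return The kept rows of `records`.
#' @export
call_rate_filter <- function(records, min_rate = 0.85, strict = TRUE) {
  stopifnot(min_rate >= 0, min_rate <= 1, "call_rate" %in% names(records))
  cr <- records$call_rate
  keep <- if (strict) cr > min_rate else cr >= min_rate
  records[keep, , drop = FALSE]
}

#' Classify single-nucleotide changes as transition or transversion
#'
#' @param ref,alt Reference and alternate alleles.
#' @return `"ti"` (A<->G, C<->T), `"tv"` (other SNV) or `NA` for non-SNVs.
#' @export
titv_class <- function(ref, alt) {
  out <- rep(NA_character_, length(ref))
  snv <- nchar(ref) == 1 & nchar(alt) == 1 & ref != alt &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  ti <- snv & ((ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
                 (ref == "C" & alt == "T") | (ref == "T" & alt == "C"))
  out[snv] <- "tv"
  out[ti] <- "ti"
  out
}

#' Per-sample transition/transversion ratio
#'
#' Counts transitions and transversions among the SNVs each sample carries
#' (dosage > 0; indels are excluded from the ratio). Samples with zero
#' transversions get an `NA` ratio with the `titv_undefined` flag set.
#'
#' @param cohort An [rv_cohort()].
#' @return Data frame: `sample`, `n_variants` (all carried variants),
#'   `n_ti`, `n_tv`, `titv`, `titv_undefined`.
#' @export
compute_titv <- function(cohort) {
  stopifnot(inherits(cohort, "rv_cohort"))
  cls <- titv_class(cohort$variants$ref, cohort$variants$alt)
  carrier <- cohort$G
  carrier@x <- rep(1, length(carrier@x))
  n_var <- as.numeric(Matrix::rowSums(carrier))
  n_ti <- as.numeric(carrier %*% as.numeric(!is.na(cls) & cls == "ti"))
  n_tv <- as.numeric(carrier %*% as.numeric(!is.na(cls) & cls == "tv"))
  ratio <- ifelse(n_tv > 0, n_ti / n_tv, NA_real_)
  data.frame(sample = cohort$samples$sample, n_variants = n_var,
             n_ti = n_ti, n_tv = n_tv, titv = ratio,
             titv_undefined = n_tv == 0, stringsAsFactors = FALSE)
}

#' Flag sample outliers on variant count, Ti/Tv and PCA projection
#'
#' A sample is flagged when its z-score exceeds `k_sd` in absolute value on
#' the number of called variants or the Ti/Tv ratio, or `pc_sd` on the
#' first two principal components. Z-scores are leave-one-out (each
#' sample's statistic is standardized against the mean and sd of the other
#' samples), so a single gross outlier cannot mask itself by inflating the
#' spread. Zero-variance statistics produce no flags; samples with
#' undefined Ti/Tv are ignored for that statistic.
#'
#' @param sample_stats Data frame with columns `sample`, `n_variants` and
#'   optionally `titv`, `PC1`, `PC2`.
#' @param k_sd Z-score threshold for variant count and Ti/Tv (default 3).
#' @param pc_sd Z-score threshold for PC1/PC2 (default 6).
#' @return Data frame: `sample`, `outlier` (logical), `reasons` (comma
#'   separated; empty when not flagged).
#' @export
detect_sample_outliers <- function(sample_stats, k_sd = 3, pc_sd = 6) {
  stopifnot(is.data.frame(sample_stats), "sample" %in% names(sample_stats))
  n <- nrow(sample_stats)
  if (n < 3L) stopf("need at least 3 samples to assess outliers")
  zflag <- function(x, thr) {
    flag <- rep(FALSE, n)
    ok <- which(!is.na(x))
    if (length(ok) < 3) return(flag)
    xs <- x[ok]
    for (j in seq_along(ok)) {
      rest <- xs[-j]
      s <- sd(rest)
      dev <- abs(xs[j] - mean(rest))
      if (is.finite(s) && s > 0) {
        flag[ok[j]] <- dev / s > thr
      } else {
        flag[ok[j]] <- dev > 0  # the rest agree exactly; any deviation flags
      }
    }
    flag
  }
  checks <- list()
  if ("n_variants" %in% names(sample_stats)) {
    checks$variant_count <- zflag(sample_stats$n_variants, k_sd)
  }
  if ("titv" %in% names(sample_stats)) {
    checks$titv <- zflag(sample_stats$titv, k_sd)
  }
  for (pc in c("PC1", "PC2")) {
    if (pc %in% names(sample_stats)) {
      checks[[pc]] <- zflag(sample_stats[[pc]], pc_sd)
    }
  }
  reasons <- vapply(seq_len(n), function(i) {
    paste(names(checks)[vapply(checks, `[`, logical(1), i)], collapse = ",")
  }, character(1))
  data.frame(sample = sample_stats$sample, outlier = nzchar(reasons),
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Principal components of the genotype matrix
#'
#' Restricts to variants with folded MAF at least `maf_min` (rare variants
#' carry no stable axes), mean-imputes missing entries, centres and
#' unit-scales columns, and returns the leading principal component scores
#' with the explained-variance fractions. Used to derive stratification
#' covariates.
#'
#' @param genotypes Sample-by-variant dosage matrix (dense or `Matrix`
#'   sparse; `NA` = missing call) or an [rv_cohort()].
#' @param n_components Number of components (default 10).
#' @param maf_min Minimum folded MAF of variants entering the PCA.
#' @return List with `scores` (samples x components), `explained_variance`
#'   (fractions) and `n_variants_used`.
#' @export
genotype_pca <- function(genotypes, n_components = 10, maf_min = 0.01) {
  if (inherits(genotypes, "rv_cohort")) genotypes <- genotypes$G
  X <- as.matrix(genotypes)
  n <- nrow(X)
  stopifnot(n >= 2)
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[!nas, j]) %||% 0
    }
    X[is.na(X)] <- 0
  }
  af <- colMeans(X) / 2
  maf <- pmin(af, 1 - af)
  X <- X[, maf >= maf_min, drop = FALSE]
  if (ncol(X) == 0L) stopf("no variants with MAF >= %g for PCA", maf_min)
  k <- min(n_components, n - 1, ncol(X))
  sds <- apply(X, 2, sd)
  Xc <- sweep(X, 2, colMeans(X))
  use <- sds > 0
  Xc[, use] <- sweep(Xc[, use, drop = FALSE], 2, sds[use], "/")
  Xc[, !use] <- 0
  total_var <- sum(apply(Xc, 2, var))
  if (total_var <= 0) {
    scores <- matrix(0, n, k,
                     dimnames = list(rownames(X), paste0("PC", seq_len(k))))
    return(list(scores = scores, explained_variance = rep(0, k),
                n_variants_used = ncol(X)))
  }
  pc <- prcomp(Xc, center = FALSE, scale. = FALSE, rank. = k)
  ev <- pc$sdev^2 / total_var
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, explained_variance = ev[seq_len(k)],
       n_variants_used = ncol(X))
}

#' Per-sample QC statistics table
#'
#' Combines carried-variant counts, Ti/Tv ratios and the first two genotype
#' principal components into one table, ready for
#' [detect_sample_outliers()].
#'
#' @param cohort An [rv_cohort()].
#' @param n_components Components computed by [genotype_pca()] (at least 2
#'   are attached).
#' @return Data frame of per-sample statistics.
#' @export
qc_sample_stats <- function(cohort, n_components = 10) {
  stats <- compute_titv(cohort)
  pca <- tryCatch(genotype_pca(cohort, n_components = n_components),
                  error = function(e) NULL)
  if (!is.null(pca)) {
    stats$PC1 <- pca$scores[, 1]
    if (ncol(pca$scores) >= 2) stats$PC2 <- pca$scores[, 2]
  }
  stats
}
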