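# Gene-level model selection by DIC difference and permutation-calibrated
# significance thresholds.

#' DIC difference between the covariate-only and the genetic model
#'
#' Returns DIC(H0) - DIC(H1); positive values favour the genetic model.
#'
#' @param fit_null,fit_full [fit_model()] results for the null and full
#'   hypothesis.
#' @return Numeric; `NA` if either fit is degenerate.
#' @export
delta_dic <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "fit_result"), inherits(fit_full, "fit_result"))
  if (isTRUE(fit_null$degenerate) || isTRUE(fit_full$degenerate)) {
    return(NA_real_)
  }
  fit_null$dic$DIC - fit_full$dic$DIC
}

#' Test one gene for rare-variant association
#'
#' Assembles the gene design from the (already filtered) cohort, fits the
#' null and full models and returns the DIC difference together with the
#' variant-characteristic effect summaries. Genes with no qualifying
#' variants are returned with status `"skipped"`; fit failures yield status
#' `"degenerate"` with the diagnostic message.
#'
#' @param cohort An `rv_cohort` (see [simulate_background()] /
#'   [read_cohort()]) whose variants have already passed QC and filtering.
#' @param gene_id Gene to test.
#' @param config A [bati_config()].
#' @param null_fit Optional precomputed null [fit_model()] result for this
#'   cohort (the null model depends only on phenotype and covariates, so it
#'   can be shared across genes).
#' @param dic_method DIC estimator passed to [fit_model()].
#' @param effects Compute the variant-characteristic effect summaries
#'   (skipped in DIC-only scans).
#' @return Object of class `gene_result`: list with `gene`, `delta_dic`,
#'   `n_variants`, `n_by_category`, `effects`, `status`, `message`.
#' @export
test_gene <- function(cohort, gene_id, config = bati_config(),
                      null_fit = NULL, dic_method = config$dic_method,
                      effects = TRUE) {
  res <- tryCatch({
    design <- design_for_gene(cohort, gene_id, config)
    if (design$p == 0L) {
      return(structure(list(gene = gene_id, delta_dic = NA_real_,
                            n_variants = 0L, n_by_category = integer(),
                            effects = NULL, status = "skipped",
                            message = "no qualifying variants"),
                       class = "gene_result"))
    }
    if (is.null(null_fit)) {
      null_fit <- fit_model(design, config, "null", dic_method = dic_method,
                            marginals = FALSE)
    }
    full_fit <- fit_model(design, config, "full", dic_method = dic_method,
                          marginals = effects)
    eff <- full_fit$effects
    if (!is.null(eff)) {
      eff <- eff[eff$block == "characteristic", , drop = FALSE]
    }
    structure(list(
      gene = gene_id,
      delta_dic = delta_dic(null_fit, full_fit),
      n_variants = design$p,
      n_by_category = table(design$categories),
      effects = eff,
      status = "ok",
      message = NULL
    ), class = "gene_result")
  }, error = function(e) {
    structure(list(gene = gene_id, delta_dic = NA_real_,
                   n_variants = NA_integer_, n_by_category = integer(),
                   effects = NULL, status = "degenerate",
                   message = conditionMessage(e)),
              class = "gene_result")
  })
  res
}

# Order statistic used for the empirical threshold: the DeltaDIC at
# descending rank ceiling(K * level); ties resolved towards the larger
# value by taking the sorted order statistic.
threshold_order_stat <- function(ddic, level) {
  ddic <- ddic[is.finite(ddic)]
  K <- length(ddic)
  if (K == 0L) return(NA_real_)
  r <- min(max(ceiling(K * level), 1L), K)
  sort(ddic, decreasing = TRUE)[r]
}

#' Permutation-calibrated DeltaDIC significance thresholds
#'
#' For each of `S` shuffles, case/control labels are randomly permuted
#' (preserving the original group sizes), every gene is tested, and the
#' empirical threshold for type-I-error level `a` is the DeltaDIC of the
#' gene at descending rank `ceiling(K * a)` among the K tested genes. The
#' final threshold per level is the median over the S shuffles.
#'
#' Permutation fits default to the deterministic plug-in DIC estimator to
#' keep the S x K x 2 fits tractable.
#'
#' @param cohort Filtered `rv_cohort`.
#' @param gene_ids Genes to scan (default: all genes in the cohort).
#' @param levels Type-I-error levels (default 0.05, 0.001, 1e-4).
#' @param S Number of label shuffles (default 10).
#' @param seed Integer seed for the permutations.
#' @param config A [bati_config()].
#' @param dic_method DIC estimator for the permutation fits (default
#'   `"plugin"`).
#' @param prefilter Optional function applied to the cohort after each label
#'   shuffle (e.g. [apply_filters()]). Variant filters that depend on the
#'   randomized control group must be re-applied per shuffle so the
#'   filter/test-label alignment matches a real analysis of that split.
#' @param progress Print per-shuffle progress to stderr.
#' @return Object of class `tier_thresholds`: list with `levels`,
#'   `per_shuffle` (S x length(levels) matrix), `median`, `S`, `seed`,
#'   `n_genes`.
#' @export
estimate_tier_thresholds <- function(cohort, gene_ids = NULL,
                                     levels = c(0.05, 0.001, 1e-4),
                                     S = 10L, seed = 1L,
                                     config = bati_config(),
                                     dic_method = "plugin",
                                     prefilter = NULL,
                                     progress = FALSE) {
  stopifnot(S >= 1, all(levels > 0 & levels < 1))
  levels <- sort(levels, decreasing = TRUE)
  auto_genes <- is.null(gene_ids)
  if (auto_genes) gene_ids <- unique(cohort$variants$gene)
  K <- length(gene_ids)
  if (K < 1 / min(levels)) {
    warning(sprintf(
      "only %d genes for level %g; threshold rests on the extreme order statistic",
      K, min(levels)), call. = FALSE)
  }
  thr <- matrix(NA_real_, nrow = S, ncol = length(levels),
                dimnames = list(NULL, format(levels, scientific = TRUE)))
  with_seed(seed, {
    for (s in seq_len(S)) {
      shuffled <- cohort
      shuffled$samples$status <- sample(cohort$samples$status)
      if (!is.null(prefilter)) shuffled <- prefilter(shuffled)
      ids_s <- if (auto_genes && !is.null(prefilter)) {
        unique(shuffled$variants$gene)
      } else gene_ids
      ddic <- scan_genes(shuffled, ids_s, config, dic_method = dic_method)
      if (all(!is.finite(ddic))) stopf("all genes skipped in shuffle %d", s)
      for (l in seq_along(levels)) {
        thr[s, l] <- threshold_order_stat(ddic, levels[l])
      }
      if (progress) {
        message(sprintf("shuffle %d/%d: thresholds %s", s, S,
                        paste(signif(thr[s, ], 4), collapse = " / ")))
      }
    }
  })
  med <- apply(thr, 2, median)
  structure(list(levels = levels, per_shuffle = thr,
                 median = setNames(med, names(med)), S = as.integer(S),
                 seed = as.integer(seed), n_genes = K),
            class = "tier_thresholds")
}

# Fit all genes of a cohort and return the DeltaDIC vector (NA where
# skipped/degenerate). The null fit is computed once and shared.
scan_genes <- function(cohort, gene_ids, config, dic_method = "plugin") {
  null_fit <- null_fit_for(cohort, config, dic_method)
  vapply(gene_ids, function(g) {
    r <- test_gene(cohort, g, config, null_fit = null_fit,
                   dic_method = dic_method, effects = FALSE)
    if (identical(r$status, "ok")) r$delta_dic else NA_real_
  }, numeric(1))
}

# Null model fit shared across genes of one cohort (depends only on y, X).
null_fit_for <- function(cohort, config, dic_method = config$dic_method) {
  design <- design_for_gene(cohort, "__none__", config)
  fit_model(design, config, "null", dic_method = dic_method)
}

#' Classify genes against a TIER threshold
#'
#' A gene is called significant iff its DeltaDIC strictly exceeds the median
#' permutation threshold at the requested level.
#'
#' @param results A data frame with columns `gene` and `delta_dic` (e.g.
#'   from [run_rvas()]), or a list of `gene_result` objects.
#' @param thresholds A [estimate_tier_thresholds()] result.
#' @param level One of `thresholds$levels`.
#' @return Character vector of significant gene ids.
#' @export
classify_genes <- function(results, thresholds, level) {
  stopifnot(inherits(thresholds, "tier_thresholds"))
  li <- which(abs(thresholds$levels - level) < 1e-12)
  if (!length(li)) stopf("level %g not present in thresholds", level)
  thr <- thresholds$median[li]
  if (is.list(results) && !is.data.frame(results)) {
    genes <- vapply(results, `[[`, character(1), "gene")
    ddic <- vapply(results, function(r) r$delta_dic %||% NA_real_, numeric(1))
  } else {
    genes <- results$gene
    ddic <- results$delta_dic
  }
  genes[!is.na(ddic) & ddic > thr]
}

#' @export
print.tier_thresholds <- function(x, ...) {
  cat(sprintf("DeltaDIC thresholds (S = %d shuffles, %d genes):\n",
              x$S, x$n_genes))
  for (l in seq_along(x$levels)) {
    cat(sprintf("  level %-8g median %.4f  (range %.4f .. %.4f)\n",
                x$levels[l], x$median[l], min(x$per_shuffle[, l]),
                max(x$per_shuffle[, l])))
  }
  invisible(x)
}
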