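# End-to-end harness: QC + genome-wide association scan, permutation
# thresholds, power scoring and a minimal burden baseline.

#' Apply the variant QC filters to a cohort
#'
#' Runs [filter_variants()] (public panel and randomized-control allele
#' frequencies, deleteriousness score, synonymous drop) followed by
#' [call_rate_filter()] and returns the restricted cohort.
#'
#' @param cohort An [rv_cohort()].
#' @param af_max,score_min,drop_synonymous See [filter_variants()].
#' @param call_rate_min,call_rate_strict See [call_rate_filter()].
#' @param use_control_af Include the cohort's control-group allele
#'   frequencies in the frequency filter (default TRUE).
#' @return The filtered cohort.
#' @export
apply_filters <- function(cohort, af_max = 0.01, score_min = 10,
                          drop_synonymous = TRUE, call_rate_min = 0.85,
                          call_rate_strict = TRUE, use_control_af = TRUE) {
  ctrl_af <- if (use_control_af) control_af(cohort) else NULL
  kept <- filter_variants(cohort$variants, af_max = af_max,
                          score_min = score_min,
                          drop_synonymous = drop_synonymous,
                          control_af = ctrl_af)
  kept <- call_rate_filter(kept, min_rate = call_rate_min,
                           strict = call_rate_strict)
  subset_variants(cohort, match(kept$variant_id, cohort$variants$variant_id))
}

#' Genome-wide rare-variant association scan
#'
#' Applies the variant filters, optionally computes genotype principal
#' components (from the unfiltered cohort, where the common variants that
#' carry the stratification axes still are) and appends them as covariates,
#' fits the null and full model for every gene, and returns the per-gene
#' table ranked by DeltaDIC. Genes whose variants are all removed by the
#' filters appear with status `"skipped"` and no rank. Fully deterministic
#' given the configuration seed.
#'
#' @param cohort An [rv_cohort()].
#' @param config A [bati_config()].
#' @param thresholds Optional [estimate_tier_thresholds()] result; adds one
#'   significance column per level.
#' @param n_pcs Number of genotype principal components appended to the
#'   covariates (default 0).
#' @param filters Named list overriding [apply_filters()] defaults; `NULL`
#'   to skip filtering (cohort already filtered).
#' @param dic_method DIC estimator for the fits.
#' @param progress Print per-gene progress to stderr.
#' @return Object of class `rvas_result`: list with `results` (one row per
#'   gene), `effects` (named list of per-gene effect tables), `thresholds`,
#'   `config`.
#' @export
run_rvas <- function(cohort, config = bati_config(), thresholds = NULL,
                     n_pcs = 0, filters = list(), dic_method = config$dic_method,
                     progress = FALSE) {
  stopifnot(inherits(cohort, "rv_cohort"))
  all_genes <- unique(cohort$variants$gene)
  if (!length(all_genes)) stopf("cohort has no genes")

  if (n_pcs > 0) {
    pca <- genotype_pca(cohort, n_components = n_pcs)
    pcs <- pca$scores
    for (j in seq_len(ncol(pcs))) cohort$samples[[colnames(pcs)[j]]] <- pcs[, j]
    config$covariate_cols <- union(config$covariate_cols, colnames(pcs))
  }
  fcoh <- if (is.null(filters)) cohort else {
    do.call(apply_filters, c(list(cohort), filters))
  }
  if (nrow(fcoh$variants) == 0L) stopf("no variants left after filtering")

  null_fit <- null_fit_for(fcoh, config, dic_method)
  res_rows <- vector("list", length(all_genes))
  effects <- list()
  for (gi in seq_along(all_genes)) {
    g <- all_genes[gi]
    r <- test_gene(fcoh, g, config, null_fit = null_fit,
                   dic_method = dic_method)
    nbc <- r$n_by_category
    res_rows[[gi]] <- data.frame(
      gene = g,
      n_variants = r$n_variants,
      n_lof = as.integer(nbc["LoF"] %||% 0) %|NA|% 0L,
      n_missense = as.integer(nbc["missense"] %||% 0) %|NA|% 0L,
      n_indel = as.integer(nbc["indel"] %||% 0) %|NA|% 0L,
      delta_dic = r$delta_dic,
      status = r$status,
      stringsAsFactors = FALSE
    )
    if (!is.null(r$effects)) effects[[g]] <- r$effects
    if (progress && gi %% 200 == 0) {
      message(sprintf("tested %d/%d genes", gi, length(all_genes)))
    }
  }
  results <- do.call(rbind, res_rows)
  ord <- order(results$delta_dic, decreasing = TRUE, na.last = TRUE)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  results$rank <- NA_integer_
  ok <- !is.na(results$delta_dic)
  results$rank[ok] <- seq_len(sum(ok))

  if (!is.null(thresholds)) {
    for (l in seq_along(thresholds$levels)) {
      col <- paste0("sig_", format(thresholds$levels[l]))
      results[[col]] <- !is.na(results$delta_dic) &
        results$delta_dic > thresholds$median[l]
    }
  }
  structure(list(results = results, effects = effects,
                 thresholds = thresholds, config = config),
            class = "rvas_result")
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' @export
print.rvas_result <- function(x, ...) {
  cat(sprintf("rvas_result: %d genes (%d tested, %d skipped)\n",
              nrow(x$results), sum(x$results$status == "ok"),
              sum(x$results$status != "ok")))
  print(head(x$results, 10), digits = 4)
  invisible(x)
}

#' Write an association scan result to disk
#'
#' Emits the ranked per-gene table as TSV and the per-gene
#' variant-characteristic effect summaries as a JSON sidecar.
#'
#' @param x An [run_rvas()] result.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_rvas <- function(x, dir) {
  stopifnot(inherits(x, "rvas_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "gene_results.tsv")
  write.table(x$results, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "gene_effects.json")
  jsonlite::write_json(x$effects, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(results = tsv, effects = js))
}

#' Score statistical power across benchmark replicates
#'
#' Power per (spiked gene, VE level, TIER level) is the fraction of
#' replicates in which the gene's DeltaDIC strictly exceeds the median
#' permutation threshold at that level.
#'
#' @param results Data frame with columns `replicate`, `gene`, `delta_dic`
#'   (stacked per-replicate association results for the spiked genes).
#' @param thresholds A [estimate_tier_thresholds()] result.
#' @param truth Data frame with columns `replicate`, `gene`, `ve` (the truth
#'   manifest of spiked genes per replicate).
#' @return Data frame: `gene`, `ve`, `level`, `threshold`, `n_replicates`,
#'   `n_significant`, `power`.
#' @export
estimate_power <- function(results, thresholds, truth) {
  stopifnot(inherits(thresholds, "tier_thresholds"),
            all(c("replicate", "gene", "delta_dic") %in% names(results)),
            all(c("replicate", "gene", "ve") %in% names(truth)))
  key_r <- paste(results$replicate, results$gene)
  key_t <- paste(truth$replicate, truth$gene)
  missing <- setdiff(key_t, key_r)
  if (length(missing)) {
    stopf("no association result for replicate/gene: %s",
          paste(head(missing, 5), collapse = "; "))
  }
  dd <- results$delta_dic[match(key_t, key_r)]
  out <- list()
  i <- 0L
  for (grp in split(seq_len(nrow(truth)),
                    list(truth$gene, truth$ve), drop = TRUE)) {
    for (l in seq_along(thresholds$levels)) {
      thr <- thresholds$median[l]
      sig <- !is.na(dd[grp]) & dd[grp] > thr
      i <- i + 1L
      out[[i]] <- data.frame(
        gene = truth$gene[grp[1]], ve = truth$ve[grp[1]],
        level = thresholds$levels[l], threshold = unname(thr),
        n_replicates = length(grp), n_significant = sum(sig),
        power = mean(sig), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Minimal burden baseline test
#'
#' Regresses the phenotype on the per-sample minor-allele count of the
#' gene's variants (plus the individual covariates) and reports the
#' likelihood-ratio p-value against the covariate-only logistic model. A
#' sanity baseline only, not a replacement for dedicated burden tests.
#'
#' @param design A [assemble_design()] result.
#' @return List with `p_value`, `statistic` (LR chi-square), `degenerate`
#'   (TRUE when the burden is constant, in which case `p_value` is 1).
#' @export
burden_baseline <- function(design) {
  stopifnot(inherits(design, "gene_design"))
  burden <- if (design$p > 0) rowSums(design$G) else rep(0, design$n)
  if (length(unique(burden)) < 2L) {
    return(list(p_value = 1, statistic = 0, degenerate = TRUE))
  }
  X <- design$X
  f0 <- glm(design$y ~ X - 1, family = binomial())
  f1 <- glm(design$y ~ X + burden - 1, family = binomial())
  stat <- as.numeric(f0$deviance - f1$deviance)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(p_value = p, statistic = stat, degenerate = FALSE)
}
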