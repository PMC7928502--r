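# Desk-scale benchmark experiments: empirical type-I-error calibration and
# power on synthetic cohorts. These drive both the validation suite and the
# reproduction script.

#' Type-I-error calibration on synthetic null cohorts
#'
#' Simulates a null background cohort (no spiked risk variants), estimates
#' the permutation DeltaDIC thresholds on it, then simulates an independent
#' null cohort of the same design (different seed) and reports, per level,
#' the fraction of genes whose DeltaDIC strictly exceeds the threshold —
#' the empirical type I error rate of the calibrated test.
#'
#' @param n_samples,n_genes Cohort design (split 1:1 cases:controls).
#' @param levels Type-I-error levels to calibrate.
#' @param S Number of label shuffles for threshold estimation.
#' @param seed Master seed (cohorts and permutations derive from it).
#' @param config A [bati_config()].
#' @param dic_method DIC estimator (default the fast deterministic plug-in).
#' @param progress Emit progress messages.
#' @return List with `thresholds` ([estimate_tier_thresholds()] result),
#'   `delta_dic` (independent-replicate DeltaDIC vector), `n_tested`,
#'   `n_exceed` and `empirical_rate` per level.
#' @export
benchmark_null_calibration <- function(n_samples, n_genes,
                                       levels = c(0.05, 0.001, 1e-4),
                                       S = 3L, seed = 1L,
                                       config = bati_config(),
                                       dic_method = "plugin",
                                       progress = FALSE) {
  spec_a <- background_cohort_spec(n_samples = n_samples, n_genes = n_genes,
                                   seed = derive_seed(seed, 1L))
  spec_b <- background_cohort_spec(n_samples = n_samples, n_genes = n_genes,
                                   seed = derive_seed(seed, 2L))
  coh_a <- simulate_background(spec_a)
  if (progress) message("threshold cohort simulated")
  # filters depending on the randomized control group are re-applied per
  # shuffle, matching a full analysis of each split
  thr <- estimate_tier_thresholds(coh_a, levels = levels, S = S,
                                  seed = derive_seed(seed, 3L),
                                  config = config, dic_method = dic_method,
                                  prefilter = apply_filters,
                                  progress = progress)
  coh_b <- apply_filters(simulate_background(spec_b))
  if (progress) message("independent null replicate simulated")
  ddic <- scan_genes(coh_b, unique(coh_b$variants$gene), config,
                     dic_method = dic_method)
  ddic <- ddic[is.finite(ddic)]
  n_exceed <- vapply(seq_along(thr$levels),
                     function(l) sum(ddic > thr$median[l]), integer(1))
  list(thresholds = thr, delta_dic = ddic, n_tested = length(ddic),
       n_exceed = setNames(n_exceed, format(thr$levels)),
       empirical_rate = setNames(n_exceed / length(ddic),
                                 format(thr$levels)))
}

#' Power benchmark for a spiked risk-gene architecture
#'
#' Simulates a background cohort, estimates the permutation DeltaDIC
#' threshold at `level` on it, then for each replicate re-randomizes the
#' case/control assignment, builds a fresh risk architecture targeting
#' `target_ve` (MAF-dependent relative risks, liability-scale VE
#' accumulation), spikes the cases (zero or one variant per case) and tests
#' the spiked gene. Power is the fraction of replicates whose DeltaDIC
#' exceeds the threshold.
#'
#' @param n_samples,n_genes Background cohort design (1:1 cases:controls).
#' @param target_ve Target variance explained of the spiked architecture.
#' @param n_replicates Number of spiking replicates.
#' @param level Type-I-error level of the threshold used for calling.
#' @param S Label shuffles for threshold estimation.
#' @param seed Master seed.
#' @param config A [bati_config()].
#' @param mode Architecture category mode (`"any"`, `"missense"`, `"LoF"`).
#' @param prevalence Disease prevalence for the liability-threshold VE.
#' @param pool_size Risk-variant pool size.
#' @param dic_method DIC estimator.
#' @param progress Emit progress messages.
#' @return List with `power` (fraction in [0, 1]), `threshold`,
#'   `delta_dic` per replicate, `n_replicates`, `thresholds`.
#' @export
benchmark_power <- function(n_samples, n_genes = 400, target_ve = 0.02,
                            n_replicates = 50, level = 0.05, S = 3L,
                            seed = 1L, config = bati_config(),
                            mode = "any", prevalence = 0.0066,
                            pool_size = 400, dic_method = "plugin",
                            progress = FALSE) {
  spec <- background_cohort_spec(n_samples = n_samples, n_genes = n_genes,
                                 seed = derive_seed(seed, 11L))
  background <- simulate_background(spec)
  thr <- estimate_tier_thresholds(background, levels = level, S = S,
                                  seed = derive_seed(seed, 12L),
                                  config = config, dic_method = dic_method,
                                  prefilter = apply_filters,
                                  progress = progress)
  threshold <- thr$median[1]
  target_gene <- unique(background$variants$gene)[1]
  pool <- with_seed(derive_seed(seed, 13L), simulate_risk_pool(pool_size))

  ddic <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    ddic[r] <- with_seed(derive_seed(seed, 100L + r), {
      coh <- background
      coh$samples$status <- sample(coh$samples$status)
      arch <- build_architecture(pool, target_gene, target_ve, mode = mode,
                                 prevalence = prevalence)
      spiked <- spike_cases(coh, arch)
      fcoh <- apply_filters(spiked)
      res <- test_gene(fcoh, target_gene, config,
                       dic_method = dic_method, effects = FALSE)
      if (identical(res$status, "ok")) res$delta_dic else NA_real_
    })
    if (progress && r %% 10 == 0) {
      message(sprintf("replicate %d/%d: DeltaDIC %.2f", r, n_replicates,
                      ddic[r]))
    }
  }
  sig <- !is.na(ddic) & ddic > threshold
  list(power = mean(sig), threshold = unname(threshold), delta_dic = ddic,
       n_replicates = n_replicates, thresholds = thr)
}
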