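test_that("the simulator is reproducible and honours the case:control ratio", {
  spec <- background_cohort_spec(n_samples = 120, n_genes = 10, seed = 42)
  c1 <- simulate_background(spec)
  c2 <- simulate_background(spec)
  expect_identical(c1, c2)
  expect_equal(sum(c1$samples$status == 1), 60)
  spec12 <- background_cohort_spec(n_samples = 120, n_genes = 10,
                                   case_control_ratio = c(1, 2), seed = 42)
  c3 <- simulate_background(spec12)
  expect_equal(sum(c3$samples$status == 1), 40)
})

test_that("genotypes follow Hardy-Weinberg proportions at nominal rates", {
  # common variants so the chi-square approximation is valid
  spec <- background_cohort_spec(n_samples = 500, n_genes = 60,
                                 gene_mean_meanlog = log(20),
                                 maf_range = c(0.05, 0.5),
                                 missing_rate = 0, seed = 101)
  coh <- simulate_background(spec)
  G <- as.matrix(coh$G)
  pvals <- apply(G, 2, function(g) {
    n <- length(g)
    af <- mean(g) / 2
    if (af <= 0 || af >= 1) return(NA_real_)
    obs <- tabulate(g + 1, nbins = 3)
    expct <- n * c((1 - af)^2, 2 * af * (1 - af), af^2)
    if (any(expct < 5)) return(NA_real_)
    stat <- sum((obs - expct)^2 / expct)
    pchisq(stat, df = 1, lower.tail = FALSE)
  })
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 800)
  rej <- mean(pvals < 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(abs(rej - 0.05), ci + 0.01)
})

test_that("per-sample variant counts are approximately normal", {
  coh <- small_cohort(n_samples = 200, n_genes = 300, seed = 77)
  counts <- as.numeric(Matrix::rowSums(coh$G > 0))
  expect_gt(stats::shapiro.test(counts)$p.value, 0.01)
})

test_that("relative risks are truncated and anticorrelated with frequency", {
  maf <- withr::with_seed(5, 10^runif(1e4, -5, -2))
  rr <- withr::with_seed(6, sample_rr(maf))
  expect_true(all(rr >= 1.1))
  ct <- cor.test(maf, rr, method = "spearman", exact = FALSE)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-6)
  med_lo <- median(withr::with_seed(7, sample_rr(rep(1e-5, 1e4))))
  med_hi <- median(withr::with_seed(8, sample_rr(rep(0.01, 1e4))))
  expect_lt(abs(med_lo - 8), 1)
  expect_lt(abs(med_hi - 1.5), 0.25)
  expect_error(sample_rr(0.02), "maf")
})

test_that("liability-threshold VE behaves like the underlying model", {
  expect_equal(variance_explained(0.0066, 0.005, 1), 0)
  ves <- vapply(c(1.5, 2, 3, 5, 8), function(r) {
    variance_explained(0.0066, 0.001, r)
  }, numeric(1))
  expect_true(all(diff(ves) > 0))
  expect_error(variance_explained(0.5, 0.001, 10), "penetrance")
})

test_that("architectures stop exactly when the VE target is reached", {
  pool <- withr::with_seed(12, simulate_risk_pool(500))
  for (target in c(0.02, 0.01, 0.005)) {
    arch <- withr::with_seed(13, build_architecture(pool, "gX", target))
    v <- arch$variants
    # independent re-summation of the per-variant VE
    ve_re <- vapply(seq_len(nrow(v)), function(i) {
      variance_explained(arch$prevalence, v$maf[i], v$rr[i])
    }, numeric(1))
    expect_equal(cumsum(ve_re), v$cum_ve, tolerance = 1e-12)
    expect_gte(sum(ve_re), target)
    expect_lt(sum(ve_re) - ve_re[length(ve_re)], target)
  }
  empty <- build_architecture(pool, "gX", 0)
  expect_equal(nrow(empty$variants), 0)
  tiny_pool <- pool[1:2, ]
  expect_error(withr::with_seed(14,
    build_architecture(tiny_pool, "gX", 0.5)), "exhausted")
})

test_that("population assignment follows the argmax rule", {
  pool <- withr::with_seed(15, simulate_risk_pool(50))
  pops <- c("EUR+AMR", "SAS", "EAS")
  afs <- withr::with_seed(16,
    matrix(runif(150, 0, 0.01), ncol = 3))
  afs[1:10, ] <- NA  # unobserved variants
  lab <- withr::with_seed(17, assign_populations(pool, afs, pops))
  obs <- 11:50
  expect_equal(lab$population[obs],
               pops[apply(afs[obs, ], 1, which.max)])
  expect_true(all(lab$population[1:10] %in% pops))
  one <- assign_populations(pool, populations = "IBS")
  expect_true(all(one$population == "IBS"))
})

test_that("spiking is case-only, heterozygous, at most one variant per case", {
  coh <- small_cohort(n_samples = 300, n_genes = 10, seed = 19)
  pool <- withr::with_seed(20, simulate_risk_pool(300))
  arch <- withr::with_seed(21, build_architecture(pool, "G00001", 0.02))
  spiked <- withr::with_seed(22, spike_cases(coh, arch))
  new_cols <- setdiff(colnames(spiked$G), colnames(coh$G))
  expect_gt(length(new_cols), 0)
  Gn <- as.matrix(spiked$G[, new_cols, drop = FALSE])
  ctrl <- spiked$samples$status == 0
  expect_true(all(Gn[ctrl, ] == 0))
  expect_true(all(Gn %in% c(0, 1)))
  expect_true(all(rowSums(Gn) <= 1))
  # original genotypes untouched
  expect_identical(spiked$G[, colnames(coh$G)], coh$G)
})

test_that("spiked carrier counts match the binomial design on average", {
  coh <- small_cohort(n_samples = 400, n_genes = 4, seed = 25)
  n_case <- sum(coh$samples$status == 1)
  pool <- data.frame(variant_id = "r1", maf = 0.004, rr = 4,
                     category = "missense", score = 25)
  arch <- structure(list(gene = "G00001", target_ve = 0.001, mode = "any",
                         prevalence = 0.0066,
                         variants = cbind(pool, ve = 0.001, cum_ve = 0.001)),
                    class = "architecture_spec")
  counts <- withr::with_seed(26, vapply(1:300, function(i) {
    sum(attr(spike_cases(coh, arch), "spike_log")$n_carriers)
  }, numeric(1)))
  expected <- n_case * 2 * 0.004 * 4
  se <- sqrt(n_case * 2 * 0.004 * 4 / 300)  # approx Poisson-scale SE
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("benchmark replicates re-randomize labels and fill the inventory", {
  spec <- background_cohort_spec(n_samples = 80, n_genes = 6, seed = 31)
  pool <- withr::with_seed(32, simulate_risk_pool(200))
  archs <- list(list(gene = "G00001", target_ve = 0.01),
                list(gene = "G00002", target_ve = 0.005, mode = "missense"))
  bundle <- generate_benchmark_dataset(spec, archs, pool, n_replicates = 3,
                                       seed = 33, keep_cohorts = TRUE)
  expect_equal(nrow(bundle$inventory), 2 * 3)
  s1 <- bundle$cohorts[[1]]$samples$status
  s2 <- bundle$cohorts[[2]]$samples$status
  expect_false(identical(s1, s2))
  expect_equal(sum(s1), sum(s2))
  expect_true(all(bundle$inventory$achieved_ve >=
                    bundle$inventory$target_ve))
})

test_that("stratified backgrounds separate populations along PC1/PC2", {
  spec <- background_cohort_spec(
    n_samples = 150, n_genes = 80, maf_range = c(0.02, 0.5), fst = 0.05,
    populations = c("EUR", "SAS", "EAS"), missing_rate = 0, seed = 35)
  coh <- simulate_background(spec)
  pca <- genotype_pca(coh, n_components = 2, maf_min = 0.05)
  sil <- cluster::silhouette(as.integer(factor(coh$samples$population)),
                             dist(pca$scores[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
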