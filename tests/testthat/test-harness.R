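test_that("a cohort round-trips through VCF + tables", {
  coh <- small_cohort(n_samples = 15, n_genes = 3, seed = 71,
                      missing_rate = 0.05)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(file.path(dir, "cohort.vcf"),
                      file.path(dir, "annotations.tsv"),
                      file.path(dir, "phenotypes.tsv"))
  expect_equal(as.matrix(back$G), as.matrix(coh$G))
  expect_equal(as.matrix(back$miss) * 1, as.matrix(coh$miss) * 1)
  expect_equal(back$samples$status, coh$samples$status)
  expect_equal(back$variants$gene, coh$variants$gene)
  expect_equal(back$variants$cadd, coh$variants$cadd, tolerance = 1e-12)
})

test_that("multi-allelic records split into biallelic dosages", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", "sB", sep = "\t"),
    paste("1", "100", ".", "A", "G,T", ".", "PASS", ".", "GT",
          "1/2", "0/1", sep = "\t")
  ), vcf)
  ann <- file.path(dir, "a.tsv")
  write.table(data.frame(chrom = "1", pos = 100, ref = "A",
                         alt = c("G", "T"), gene = "g1",
                         exonic_function = "missense", cadd = 20,
                         af_public = 0.001),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  phe <- file.path(dir, "p.tsv")
  write.table(data.frame(sample = c("sA", "sB"), status = c(1, 0)),
              phe, sep = "\t", quote = FALSE, row.names = FALSE)
  coh <- read_cohort(vcf, ann, phe)
  expect_equal(ncol(coh$G), 2)
  expect_equal(as.numeric(coh$G["sA", ]), c(1, 1))
  expect_equal(as.numeric(coh$G["sB", ]), c(1, 0))
})

test_that("loading errors name offending variants and drops phenotype-less samples", {
  coh <- small_cohort(n_samples = 6, n_genes = 2, seed = 72,
                      maf_range = c(0.01, 0.05))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  ann <- read.delim(paths["annotations"])
  ann2 <- ann[-1, ]
  write.table(ann2, paths["annotations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_cohort(paths["vcf"], paths["annotations"],
                           paths["phenotypes"]),
               coh$variants$variant_id[1], fixed = TRUE)
  write.table(ann, paths["annotations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  phe <- read.delim(paths["phenotypes"])
  phe2 <- phe[-3, ]
  write.table(phe2, paths["phenotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_warning(coh2 <- read_cohort(paths["vcf"], paths["annotations"],
                                     paths["phenotypes"]),
                 "without phenotype")
  expect_equal(nrow(coh2$samples), 5)
})

test_that("the genome-wide scan ranks genes and reruns identically", {
  coh <- small_cohort(n_samples = 150, n_genes = 20, seed = 73)
  cfg <- bati_config()
  res1 <- run_rvas(coh, cfg, dic_method = "plugin")
  res2 <- run_rvas(coh, cfg, dic_method = "plugin")
  expect_identical(res1$results, res2$results)
  expect_equal(nrow(res1$results), 20)
  ok <- res1$results$status == "ok"
  dd <- res1$results$delta_dic[ok]
  expect_true(all(diff(dd) <= 0))
  expect_true(all(is.na(res1$results$rank[!ok])))
  # results write cleanly
  dir <- withr::local_tempdir()
  paths <- write_rvas(res1, dir)
  expect_true(all(file.exists(paths)))
})

test_that("power tallies agree with a brute-force count", {
  thr <- structure(list(levels = c(0.05, 0.001),
                        median = c(2, 9),
                        per_shuffle = matrix(rep(c(2, 9), each = 3), 3),
                        S = 3L, seed = 1L, n_genes = 100L),
                   class = "tier_thresholds")
  withr::with_seed(81, {
    results <- data.frame(replicate = rep(1:20, each = 2),
                          gene = rep(c("gA", "gB"), 20),
                          delta_dic = c(rnorm(20, 12, 3), rnorm(20, 1, 2)))
  })
  truth <- data.frame(replicate = rep(1:20, each = 2),
                      gene = rep(c("gA", "gB"), 20),
                      ve = 0.02)
  pw <- estimate_power(results, thr, truth)
  for (i in seq_len(nrow(pw))) {
    sub <- results[results$gene == pw$gene[i], ]
    expect_equal(pw$n_significant[i],
                 sum(sub$delta_dic > pw$threshold[i]))
    expect_equal(pw$power[i], pw$n_significant[i] / pw$n_replicates[i])
  }
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  # every truth entry needs a result
  expect_error(estimate_power(results[-1, ], thr, truth), "no association")
  # all-significant edge
  res_hi <- transform(results, delta_dic = 100)
  pw_hi <- estimate_power(res_hi, thr, truth)
  expect_true(all(pw_hi$power == 1))
})

test_that("the burden baseline matches an exact test and is null-uniform", {
  # no carriers at all: degenerate, p = 1
  G <- matrix(0, 20, 1, dimnames = list(sprintf("S%02d", 1:20), "v1"))
  cov <- data.frame(sample = rownames(G), status = rep(c(0, 1), 10))
  ann <- data.frame(variant_id = "v1", gene = "g",
                    exonic_function = "missense", cadd = 20)
  d0 <- assemble_design(G, cov, ann, "g", bati_config())
  b0 <- burden_baseline(d0)
  expect_true(b0$degenerate)
  expect_equal(b0$p_value, 1)

  # 2x2 toy: 20/100 case carriers vs 5/100 control carriers
  carrier <- c(rep(1, 20), rep(0, 80), rep(1, 5), rep(0, 95))
  y <- c(rep(1, 100), rep(0, 100))
  G2 <- matrix(carrier, ncol = 1,
               dimnames = list(sprintf("S%03d", 1:200), "v1"))
  cov2 <- data.frame(sample = rownames(G2), status = y)
  d2 <- assemble_design(G2, cov2, ann, "g", bati_config())
  b2 <- burden_baseline(d2)
  fisher_p <- fisher.test(matrix(c(20, 80, 5, 95), 2))$p.value
  expect_lt(abs(log10(b2$p_value) - log10(fisher_p)), 1)

  # permutation null: p-values approximately uniform (the test statistic is
  # discrete, so check calibration at two reference points rather than KS)
  ps <- withr::with_seed(82, vapply(1:200, function(i) {
    dperm <- d2
    dperm$y <- sample(d2$y)
    burden_baseline(dperm)$p_value
  }, numeric(1)))
  expect_lte(mean(ps < 0.05), 0.10)
  expect_gt(median(ps), 0.3)
  expect_lt(median(ps), 0.7)
})

test_that("YAML run configurations parse with defaults", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "run.yaml")
  writeLines(c(
    "filters:",
    "  af_max: 0.005",
    "model:",
    "  covariate_cols: [age]",
    "  seed: 9",
    "levels: [0.05, 0.001]",
    "S: 4",
    "n_pcs: 2"
  ), yml)
  rc <- read_run_config(yml)
  expect_equal(rc$filters$af_max, 0.005)
  expect_equal(rc$filters$score_min, 10)
  expect_equal(rc$config$covariate_cols, "age")
  expect_equal(rc$S, 4L)
  expect_equal(rc$levels, c(0.05, 0.001))
})
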