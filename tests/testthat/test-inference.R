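cfg0 <- bati_config(score_cols = character())

test_that("intercept-only mode sits at zero for balanced outcomes", {
  G <- matrix(numeric(0), nrow = 4, ncol = 0,
              dimnames = list(sprintf("S%d", 1:4), NULL))
  cov <- data.frame(sample = rownames(G), status = c(0, 1, 0, 1))
  ann <- data.frame(variant_id = character(), gene = character(),
                    exonic_function = character(), cadd = numeric())
  d <- assemble_design(G, cov, ann, "g", cfg0)
  ap <- find_conditional_mode(d, cfg0, log_precision = 0)
  expect_lt(abs(ap$mode[1]), 1e-6)
})

test_that("Newton mode matches a dense grid-search maximizer", {
  d <- toy_design(n = 5, seed = 11, maf = 0.3, config = cfg0)
  d <- drop_characteristics(d)
  psi <- 1
  ap <- find_conditional_mode(d, cfg0, psi)
  lam <- cfg0$fixed_effect_prior_precision
  g <- as.numeric(d$G[, 1])
  penal <- function(a, de) {
    eta <- a + g * de
    sum(d$y * eta - log1p(exp(eta))) - 0.5 * lam * a^2 - 0.5 * exp(psi) * de^2
  }
  als <- seq(-3, 3, by = 5e-4)
  # profile maximization: exhaustive over alpha x delta on a coarse-fine grid
  dels <- seq(-2, 2, by = 5e-4)
  best <- c(NA, NA); best_v <- -Inf
  for (a in seq(-3, 3, by = 0.01)) {
    v <- vapply(dels, function(de) penal(a, de), numeric(1))
    if (max(v) > best_v) { best_v <- max(v); best <- c(a, dels[which.max(v)]) }
  }
  va <- vapply(als, function(a) penal(a, best[2]), numeric(1))
  best[1] <- als[which.max(va)]
  expect_lt(abs(ap$mode[1] - best[1]), 1e-4 + 5e-4)
  expect_lt(abs(ap$mode[2] - best[2]), 1e-4 + 5e-4)
})

test_that("random effects shrink to zero as the precision grows", {
  d <- toy_design(n = 60, seed = 2, maf = 0.2, beta = 1.2, config = cfg0)
  d <- drop_characteristics(d)
  mags <- vapply(c(-2, 0, 2, 4, 6, 8, 10), function(psi) {
    abs(find_conditional_mode(d, cfg0, psi)$mode[2])
  }, numeric(1))
  expect_true(all(diff(mags) <= 1e-10))
  expect_lt(mags[length(mags)], 1e-3)
})

test_that("Laplace log marginal agrees with 2-D quadrature", {
  d <- toy_design(n = 30, seed = 3, config = cfg0)
  d <- drop_characteristics(d)
  for (psi in c(-1, 2, 6)) {
    lm_pkg <- log_marginal_tau(d, cfg0, psi)
    lm_orc <- quadrature_log_marginal(d, cfg0, psi,
                                      als = seq(-4.5, 3.5, length.out = 561),
                                      dels = seq(-5, 5, length.out = 1201))
    expect_lt(abs(lm_pkg - lm_orc), 0.05)
  }
})

test_that("an all-zero genotype column integrates out of the marginal exactly", {
  d1 <- drop_characteristics(toy_design(n = 25, seed = 7, config = cfg0))
  d2 <- d1
  d2$G <- cbind(d1$G, v0 = 0)
  d2$Z <- matrix(0, 2, 0)
  d2$p <- 2L
  d2$variant_ids <- c("v1", "v0")
  d2$categories <- c("missense", "missense")
  base <- log_marginal_tau(d1, cfg0, 1.3)
  aug <- log_marginal_tau(d2, cfg0, 1.3)
  expect_lt(abs(aug - base), 1e-8)
})

test_that("the marginal is invariant to variant column order", {
  withr::with_seed(19, {
    G <- matrix(rbinom(80, 2, 0.1), nrow = 40,
                dimnames = list(sprintf("S%02d", 1:40), c("v1", "v2")))
    y <- rbinom(40, 1, 0.5)
  })
  cov <- data.frame(sample = rownames(G), status = y)
  ann <- data.frame(variant_id = c("v1", "v2"), gene = "g1",
                    exonic_function = c("missense", "LoF"),
                    cadd = c(12, 30))
  cfg <- bati_config()
  d12 <- assemble_design(G, cov, ann, "g1", cfg)
  d21 <- assemble_design(G[, 2:1], cov, ann[2:1, ], "g1", cfg)
  expect_lt(abs(log_marginal_tau(d12, cfg, 0.7) -
                  log_marginal_tau(d21, cfg, 0.7)), 1e-8)
})

test_that("grid integration normalizes, peaks at the mode and is refinement-stable", {
  d <- toy_design(n = 80, seed = 13, maf = 0.15, beta = 1, config = cfg0)
  gi <- integrate_tau(d, cfg0)
  tp <- gi$tau_posterior
  expect_lt(abs(sum(tp$weights) - 1), 1e-12)
  expect_true(all(diff(tp$psi) > 0))
  k_max <- which.max(tp$weights)
  expect_gt(k_max, 1)
  expect_lt(k_max, length(tp$psi))
  eff <- latent_marginals(d, tp, gi$approxes, cfg0)

  cfg_fine <- bati_config(score_cols = character(), grid_step_mult = 0.25,
                          grid_max_points = 71)
  gi2 <- integrate_tau(d, cfg_fine)
  eff2 <- latent_marginals(d, gi2$tau_posterior, gi2$approxes, cfg_fine)
  expect_lt(max(abs(eff$mean - eff2$mean)), 1e-3)
})

test_that("marginal summaries reduce to the single Gaussian on a 1-point grid", {
  d <- toy_design(n = 40, seed = 4, config = cfg0)
  ap <- find_conditional_mode(d, cfg0, 2)
  tp <- structure(list(psi = 2, log_density = 0, weights = 1),
                  class = "tau_posterior")
  eff <- latent_marginals(d, tp, list(ap), cfg0, strategy = "gaussian")
  sds <- sqrt(diag(chol2inv(chol(ap$H))))
  expect_equal(eff$mean, ap$mode[seq_len(nrow(eff))], tolerance = 1e-9)
  expect_equal(eff$sd, sds[seq_len(nrow(eff))], tolerance = 1e-9)
  expect_lt(max(abs(eff$q025 - (eff$mean + qnorm(0.025) * eff$sd))), 1e-6)
  expect_lt(max(abs(eff$q975 - (eff$mean + qnorm(0.975) * eff$sd))), 1e-6)
})

test_that("mixture quantiles match Monte-Carlo draws from the same mixture", {
  means <- c(-0.4, 0.1, 0.6); sds <- c(0.3, 0.5, 0.25)
  w <- c(0.25, 0.5, 0.25)
  q_lo <- rvbati:::mixture_quantile(0.025, means, sds, w)
  q_hi <- rvbati:::mixture_quantile(0.975, means, sds, w)
  draws <- withr::with_seed(99, {
    k <- sample.int(3, 1e6, replace = TRUE, prob = w)
    rnorm(1e6, means[k], sds[k])
  })
  expect_lt(abs(q_lo - quantile(draws, 0.025)), 0.005)
  expect_lt(abs(q_hi - quantile(draws, 0.975)), 0.005)
})

test_that("plug-in deviance at the balanced-mode equals the closed form", {
  G <- matrix(numeric(0), nrow = 10, ncol = 0,
              dimnames = list(sprintf("S%02d", 1:10), NULL))
  cov <- data.frame(sample = rownames(G), status = rep(c(0, 1), 5))
  ann <- data.frame(variant_id = character(), gene = character(),
                    exonic_function = character(), cadd = numeric())
  d <- assemble_design(G, cov, ann, "g", cfg0)
  fit <- fit_model(d, cfg0, "null", dic_method = "plugin")
  # D(u = 0) = -2 * 10 * log(0.5)
  expect_equal(fit$dic$Dbar - fit$dic$pD, -2 * 10 * log(0.5),
               tolerance = 1e-4)
})

test_that("effective parameter count is near one for the intercept model", {
  G <- matrix(numeric(0), nrow = 10, ncol = 0,
              dimnames = list(sprintf("S%02d", 1:10), NULL))
  cov <- data.frame(sample = rownames(G), status = rep(c(0, 1), 5))
  ann <- data.frame(variant_id = character(), gene = character(),
                    exonic_function = character(), cadd = numeric())
  d <- assemble_design(G, cov, ann, "g", cfg0)
  cfg <- bati_config(score_cols = character(), dic_samples = 1e4, seed = 21)
  fit <- fit_model(d, cfg, "null", dic_method = "mc")
  expect_lt(abs(fit$dic$pD - 1), 0.15)
  expect_equal(fit$dic$DIC, fit$dic$Dbar + fit$dic$pD)
})

test_that("Monte-Carlo DIC converges across seeds at large M", {
  d <- toy_design(n = 20, seed = 8, maf = 0.25, config = cfg0)
  cfg_a <- bati_config(score_cols = character(), dic_samples = 1e5, seed = 1)
  cfg_b <- bati_config(score_cols = character(), dic_samples = 1e5, seed = 2)
  f_a <- fit_model(d, cfg_a, "full", marginals = FALSE)
  f_b <- fit_model(d, cfg_b, "full", marginals = FALSE)
  expect_lt(abs(f_a$dic$DIC - f_b$dic$DIC), 0.1)
  expect_gt(f_a$dic$pD, -0.5)
})

test_that("a variant-free full fit reduces to the null fit", {
  G <- matrix(numeric(0), nrow = 12, ncol = 0,
              dimnames = list(sprintf("S%02d", 1:12), NULL))
  cov <- data.frame(sample = rownames(G), status = rep(c(0, 1), 6))
  ann <- data.frame(variant_id = character(), gene = character(),
                    exonic_function = character(), cadd = numeric())
  d <- assemble_design(G, cov, ann, "g", cfg0)
  f_null <- fit_model(d, cfg0, "null")
  f_full <- fit_model(d, cfg0, "full")
  expect_true(f_full$degenerate)
  expect_lt(abs(f_full$dic$DIC - f_null$dic$DIC), 1e-6)
})

test_that("fits are byte-identical across repeated runs", {
  d <- toy_design(n = 50, seed = 6, config = cfg0)
  f1 <- fit_model(d, cfg0, "full")
  f2 <- fit_model(d, cfg0, "full")
  expect_identical(f1, f2)
})

test_that("reported summaries are invariant to sample reordering", {
  cfg <- bati_config()
  withr::with_seed(31, {
    G <- matrix(rbinom(120, 2, 0.12), nrow = 60,
                dimnames = list(sprintf("S%02d", 1:60), c("v1", "v2")))
    y <- rbinom(60, 1, 0.5)
  })
  cov <- data.frame(sample = rownames(G), status = y)
  ann <- data.frame(variant_id = c("v1", "v2"), gene = "g1",
                    exonic_function = c("missense", "missense"),
                    cadd = c(14, 22))
  d1 <- assemble_design(G, cov, ann, "g1", cfg)
  perm <- withr::with_seed(32, sample(60))
  d2 <- assemble_design(G[perm, ], cov[perm, ], ann, "g1", cfg)
  f1 <- fit_model(d1, cfg, "full", dic_method = "plugin")
  f2 <- fit_model(d2, cfg, "full", dic_method = "plugin")
  expect_lt(max(abs(f1$effects$mean - f2$effects$mean)), 1e-8)
  expect_lt(abs(f1$dic$DIC - f2$dic$DIC), 1e-8)
})
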