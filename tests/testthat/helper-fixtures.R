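# Small fixtures and independent oracles used across the suite.

# A tiny hand-built design: n samples, one variant, optional category /
# score columns.
toy_design <- function(n = 30, seed = 3, maf = 0.15, beta = 0.9,
                       alpha = -0.3, config = bati_config()) {
  withr::with_seed(seed, {
    G <- matrix(rbinom(n, 2, maf), ncol = 1)
    y <- rbinom(n, 1, plogis(alpha + beta * G[, 1]))
    rownames(G) <- sprintf("S%03d", seq_len(n))
    colnames(G) <- "v1"
    cov <- data.frame(sample = rownames(G), status = y)
    ann <- data.frame(variant_id = "v1", gene = "g1",
                      exonic_function = "missense", cadd = 12)
    assemble_design(G, cov, ann, "g1", config)
  })
}

# Drop the variant-characteristic block (q = 0) from a design.
drop_characteristics <- function(design) {
  design$Z <- matrix(0, design$p, 0)
  design$q <- 0L
  design
}

# Exact posterior moments for the (m=1, q<=1, p=1) hierarchical model by
# exhaustive grid quadrature, collapsing (omega, delta) to b = omega + delta
# (prior b | psi ~ N(0, 1/lambda_q + e^-psi); omega | b, psi is conjugate
# Gaussian). Independent of the Laplace pipeline.
quadrature_oracle <- function(design, config,
                              als, bs, psis) {
  stopifnot(design$m == 1, design$p == 1, design$q <= 1)
  lam <- config$fixed_effect_prior_precision
  a_sh <- config$hyperprior_shape
  b_ra <- config$hyperprior_rate
  y <- design$y
  g <- as.numeric(design$G[, 1])
  has_omega <- design$q == 1
  E0 <- outer(g, bs)
  ll <- matrix(NA_real_, length(als), length(bs))
  for (ai in seq_along(als)) {
    E <- E0 + als[ai]
    ll[ai, ] <- colSums(y * E - log1p(exp(E)))
  }
  pri_a <- dnorm(als, 0, 1 / sqrt(lam), log = TRUE)
  S <- 0; sum_a <- 0; sum_a2 <- 0; sum_o <- 0; sum_o2 <- 0
  lpmax <- -Inf
  slices <- vector("list", length(psis))
  for (k in seq_along(psis)) {
    psi <- psis[k]
    sb2 <- exp(-psi) + if (has_omega) 1 / lam else 0
    lp <- ll + pri_a +
      rep(dnorm(bs, 0, sqrt(sb2), log = TRUE), each = length(als)) +
      (a_sh * log(b_ra) - lgamma(a_sh) + a_sh * psi - b_ra * exp(psi))
    slices[[k]] <- lp
    lpmax <- max(lpmax, max(lp))
  }
  for (k in seq_along(psis)) {
    psi <- psis[k]
    w <- exp(slices[[k]] - lpmax)
    S <- S + sum(w)
    wa <- rowSums(w)
    sum_a <- sum_a + sum(wa * als)
    sum_a2 <- sum_a2 + sum(wa * als^2)
    if (has_omega) {
      prec_o <- lam + exp(psi)
      m_o <- exp(psi) * bs / prec_o
      v_o <- 1 / prec_o
      wb <- colSums(w)
      sum_o <- sum_o + sum(wb * m_o)
      sum_o2 <- sum_o2 + sum(wb * (v_o + m_o^2))
    }
  }
  out <- list(alpha_mean = sum_a / S,
              alpha_sd = sqrt(sum_a2 / S - (sum_a / S)^2))
  if (has_omega) {
    out$omega_mean <- sum_o / S
    out$omega_sd <- sqrt(sum_o2 / S - (sum_o / S)^2)
  }
  out
}

# Exact log marginal of psi by 2-D quadrature over (alpha, b = delta) for
# the (m=1, q=0, p=1) model, including the hyperprior — the oracle for
# log_marginal_tau.
quadrature_log_marginal <- function(design, config, psi, als, dels) {
  lam <- config$fixed_effect_prior_precision
  a_sh <- config$hyperprior_shape
  b_ra <- config$hyperprior_rate
  y <- design$y
  g <- as.numeric(design$G[, 1])
  E0 <- outer(g, dels)
  lp <- matrix(NA_real_, length(als), length(dels))
  for (ai in seq_along(als)) {
    E <- E0 + als[ai]
    lp[ai, ] <- colSums(y * E - log1p(exp(E)))
  }
  lp <- lp + dnorm(als, 0, 1 / sqrt(lam), log = TRUE) +
    rep(dnorm(dels, 0, exp(-psi / 2), log = TRUE), each = length(als)) +
    (a_sh * log(b_ra) - lgamma(a_sh) + a_sh * psi - b_ra * exp(psi))
  da <- diff(als)[1]; dd <- diff(dels)[1]
  max(lp) + log(sum(exp(lp - max(lp)))) + log(da * dd)
}

# A small synthetic cohort for harness-level tests.
small_cohort <- function(n_samples = 200, n_genes = 20, seed = 5, ...) {
  simulate_background(background_cohort_spec(n_samples = n_samples,
                                             n_genes = n_genes,
                                             seed = seed, ...))
}
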