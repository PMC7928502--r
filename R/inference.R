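# Laplace-approximate inference for the hierarchical logistic GLMM.
#
# Latent field u = (alpha, omega, delta): individual-covariate effects,
# variant-characteristic effects and per-variant random effects. Conditional
# on the random-effect log-precision psi = log(1/tau), the posterior of u is
# approximated by a Gaussian centred at its mode (Laplace approximation);
# psi itself is integrated over a mode-centred grid, INLA-style.

# Diagonal prior precision of the latent field at log-precision psi.
prior_precisions <- function(blocks, config, psi) {
  d <- length(blocks$alpha) + length(blocks$omega) + length(blocks$delta)
  prec <- rep(config$fixed_effect_prior_precision, d)
  if (length(blocks$delta)) prec[blocks$delta] <- exp(psi)
  prec
}

# Log density of the hyperprior expressed in psi = log(precision):
# precision ~ Gamma(shape, rate), with the change-of-variable Jacobian.
log_hyperprior_psi <- function(psi, config) {
  a <- config$hyperprior_shape
  b <- config$hyperprior_rate
  a * log(b) - lgamma(a) + a * psi - b * exp(psi)
}

#' Gaussian (Laplace) approximation of the latent field at fixed precision
#'
#' Finds the mode of the joint log-density of the latent field u = (alpha,
#' omega, delta) conditional on the random-effect log-precision, by damped
#' Newton iterations with step-halving, and returns the Gaussian
#' approximation (mode and negative Hessian) used by all downstream
#' computations.
#'
#' @param design A [assemble_design()] result.
#' @param config A [bati_config()].
#' @param log_precision psi = log(1/tau), the log of the random-effect
#'   precision.
#' @param u0 Optional starting value (warm start).
#' @return Object of class `gaussian_approx`: list with `psi`, `mode`, `H`
#'   (negative Hessian at the mode), `logdet`, `logjoint`, `loglik`,
#'   `niter`.
#' @export
find_conditional_mode <- function(design, config, log_precision, u0 = NULL) {
  dm <- design_matrix(design)
  .conditional_mode(dm, design$y, config, log_precision, u0)
}

.conditional_mode <- function(dm, y, config, psi, u0 = NULL) {
  stopifnot(is.finite(psi))
  prec <- prior_precisions(dm$blocks, config, psi)
  if (is.null(u0)) u0 <- numeric(dm$d)
  res <- .cpp_newton_mode(dm$W, y, prec, u0, config$newton_tol,
                          config$newton_maxit, numeric(length(y)))
  if (!isTRUE(res$converged)) {
    stopf("Newton solver failed to converge in %d iterations (trace: %s)",
          config$newton_maxit,
          paste(signif(utils::tail(res$trace, 5), 6), collapse = ", "))
  }
  structure(list(psi = psi, mode = as.numeric(res$u), H = res$H,
                 logdet = res$logdet, logjoint = res$logjoint,
                 loglik = res$loglik, niter = res$niter,
                 prec = prec),
            class = "gaussian_approx")
}

#' Unnormalized log posterior of the random-effect log-precision
#'
#' Laplace approximation of log p(psi | y) up to a constant:
#' joint log-density at the conditional mode, plus the hyperprior in psi,
#' minus half the log-determinant of the negative Hessian, plus
#' d/2 * log(2*pi). All normalization constants are kept so that latent
#' coordinates without data support (e.g. an all-zero genotype column)
#' cancel exactly.
#'
#' @inheritParams find_conditional_mode
#' @param approx Optionally a precomputed [find_conditional_mode()] result
#'   for this `log_precision`.
#' @return Scalar log density (unnormalized).
#' @export
log_marginal_tau <- function(design, config, log_precision, approx = NULL) {
  if (is.null(approx)) {
    approx <- find_conditional_mode(design, config, log_precision)
  }
  d <- length(approx$mode)
  approx$logjoint + log_hyperprior_psi(log_precision, config) -
    0.5 * approx$logdet + 0.5 * d * log(2 * pi)
}

.log_marginal_from_approx <- function(approx, config) {
  d <- length(approx$mode)
  approx$logjoint + log_hyperprior_psi(approx$psi, config) -
    0.5 * approx$logdet + 0.5 * d * log(2 * pi)
}

#' Grid integration over the random-effect log-precision
#'
#' Locates the mode of the (Laplace-approximated) log posterior of psi =
#' log(1/tau), builds a symmetric grid with step proportional to the local
#' curvature-based standard deviation, extends each direction until the log
#' density has dropped `config$grid_drop` units below the mode (capped at
#' `config$grid_max_points` points), and normalizes the grid weights.
#'
#' @inheritParams find_conditional_mode
#' @param psi_range Search interval for the posterior mode of psi.
#' @return List with `tau_posterior` (class `tau_posterior`: `psi`,
#'   `log_density`, `weights`) and `approxes` (list of `gaussian_approx`,
#'   one per grid point, in grid order).
#' @export
integrate_tau <- function(design, config, psi_range = c(-8, 16)) {
  dm <- design_matrix(design)
  .integrate_tau(dm, design$y, config, psi_range)
}

.integrate_tau <- function(dm, y, config, psi_range = c(-8, 16)) {
  warm <- new.env(parent = emptyenv())
  warm$u <- numeric(dm$d)
  eval_point <- function(psi) {
    ap <- .conditional_mode(dm, y, config, psi, warm$u)
    warm$u <- ap$mode
    list(approx = ap, ld = .log_marginal_from_approx(ap, config))
  }

  opt <- optimize(function(psi) eval_point(psi)$ld,
                  interval = psi_range, maximum = TRUE, tol = 0.01)
  psi0 <- opt$maximum
  center <- eval_point(psi0)
  ld0 <- center$ld

  h <- 0.5
  ld_m <- eval_point(psi0 - h)$ld
  ld_p <- eval_point(psi0 + h)$ld
  fpp <- (ld_p + ld_m - 2 * ld0) / h^2
  sdev <- if (is.finite(fpp) && fpp < -1e-8) 1 / sqrt(-fpp) else 2
  step <- min(max(config$grid_step_mult * sdev, 0.05), 2)

  pts <- list(list(psi = psi0, out = center))
  extend <- function(dir) {
    res <- list()
    k <- 1L
    warm$u <- center$approx$mode
    repeat {
      psi <- psi0 + dir * k * step
      if (psi < psi_range[1] - 4 || psi > psi_range[2] + 4) break
      out <- eval_point(psi)
      res[[k]] <- list(psi = psi, out = out)
      if (ld0 - out$ld >= config$grid_drop) break
      k <- k + 1L
      if (length(res) >= (config$grid_max_points - 1) %/% 2) break
    }
    res
  }
  up <- extend(+1)
  down <- extend(-1)
  pts <- c(rev(down), pts, up)
  if (length(pts) > config$grid_max_points) {
    pts <- pts[seq_len(config$grid_max_points)]
  }

  psi <- vapply(pts, `[[`, numeric(1), "psi")
  ord <- order(psi)
  pts <- pts[ord]
  psi <- psi[ord]
  ld <- vapply(pts, function(p) p$out$ld, numeric(1))
  w <- exp(ld - max(ld))
  w <- w / sum(w)
  approxes <- lapply(pts, function(p) p$out$approx)

  tp <- structure(list(psi = psi, log_density = ld, weights = w),
                  class = "tau_posterior")
  validate_tau_posterior(tp)
  list(tau_posterior = tp, approxes = approxes)
}

validate_tau_posterior <- function(tp) {
  stopifnot(inherits(tp, "tau_posterior"),
            length(tp$psi) >= 1,
            all(diff(tp$psi) > 0),
            abs(sum(tp$weights) - 1) < 1e-12)
  invisible(tp)
}

# Per-coordinate Laplace marginal at a fixed grid point: profile the joint
# log-density over the remaining coordinates on a 1-D grid around the
# conditional mode, then moment-match. Corrects the mean shift that the
# plain Gaussian-at-the-mode marginal misses for skewed logistic
# posteriors.
.laplace_marginal_1d <- function(dm, y, config, approx, s, sd_s,
                                 half_width = 4.5, n_points = 19L) {
  d <- dm$d
  xs <- approx$mode[s] + seq(-half_width, half_width,
                             length.out = n_points) * sd_s
  prec <- approx$prec
  lp <- numeric(n_points)
  if (d == 1L) {
    for (t in seq_len(n_points)) {
      eta <- dm$W[, 1] * xs[t]
      ll <- sum(y * eta - log1p(exp(eta)))
      lp[t] <- ll + 0.5 * (log(prec[1]) - log(2 * pi)) -
        0.5 * prec[1] * xs[t]^2
    }
  } else {
    Wm <- dm$W[, -s, drop = FALSE]
    ws <- dm$W[, s]
    u0 <- approx$mode[-s]
    for (t in seq_len(n_points)) {
      res <- .cpp_newton_mode(Wm, y, prec[-s], u0, config$newton_tol,
                              config$newton_maxit, ws * xs[t])
      u0 <- as.numeric(res$u)
      lp[t] <- res$logjoint +
        0.5 * (log(prec[s]) - log(2 * pi)) - 0.5 * prec[s] * xs[t]^2 -
        0.5 * res$logdet + 0.5 * (d - 1) * log(2 * pi)
    }
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m <- sum(w * xs)
  v <- sum(w * xs^2) - m^2
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Quantile of a mixture of Gaussians via root finding on the mixture CDF.
mixture_quantile <- function(prob, means, sds, weights) {
  lo <- min(means - 10 * sds)
  hi <- max(means + 10 * sds)
  if (hi - lo < 1e-300) return(means[1])
  f <- function(x) sum(weights * pnorm(x, means, sds)) - prob
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Posterior marginals of the fixed effects
#'
#' Each fixed-effect coefficient's marginal posterior is the grid-weight
#' mixture of the per-grid-point Gaussian conditionals. Reports the mixture
#' mean, standard deviation, and 2.5%/97.5% quantiles per coefficient:
#' individual covariates (alpha), one row per functional-category indicator
#' and one per numeric score (omega).
#'
#' With `strategy = "gaussian"` (fast; used in genome-wide scans) the
#' per-grid-point conditionals are the Gaussian approximations at the mode.
#' With `strategy = "laplace"` each fixed-effect coordinate's conditional is
#' re-profiled by a one-dimensional Laplace approximation and
#' moment-matched, correcting the mean shift of skewed logistic posteriors;
#' recommended for final effect reports.
#'
#' @inheritParams find_conditional_mode
#' @param tau_posterior,approxes Output of [integrate_tau()].
#' @param include_random Also report the per-variant random effects delta.
#' @param strategy Marginal approximation strategy, `"gaussian"` or
#'   `"laplace"` (default from `config`).
#' @return Data frame with columns `term`, `block`, `mean`, `sd`, `q025`,
#'   `q975`.
#' @export
latent_marginals <- function(design, tau_posterior, approxes, config,
                             include_random = FALSE,
                             strategy = config$marginal_strategy) {
  dm <- design_matrix(design)
  .latent_marginals(dm, tau_posterior, approxes, include_random,
                    strategy = strategy, y = design$y, config = config)
}

.latent_marginals <- function(dm, tau_posterior, approxes,
                              include_random = FALSE,
                              strategy = "gaussian", y = NULL,
                              config = NULL) {
  blocks <- dm$blocks
  idx <- c(blocks$alpha, blocks$omega)
  block_lab <- c(rep("covariate", length(blocks$alpha)),
                 rep("characteristic", length(blocks$omega)))
  if (include_random) {
    idx <- c(idx, blocks$delta)
    block_lab <- c(block_lab, rep("random", length(blocks$delta)))
  }
  w <- tau_posterior$weights
  K <- length(approxes)
  mu <- vapply(approxes, function(a) a$mode[idx], numeric(length(idx)))
  mu <- matrix(mu, nrow = length(idx))
  sdm <- vapply(approxes, function(a) {
    sqrt(diag(chol2inv(chol(a$H)))[idx])
  }, numeric(length(idx)))
  sdm <- matrix(sdm, nrow = length(idx))

  if (identical(strategy, "laplace")) {
    stopifnot(!is.null(y), !is.null(config))
    fixed <- which(block_lab != "random")
    for (r in fixed) {
      for (k in seq_len(K)) {
        ms <- .laplace_marginal_1d(dm, y, config, approxes[[k]], idx[r],
                                   sdm[r, k])
        mu[r, k] <- ms["mean"]
        sdm[r, k] <- ms["sd"]
      }
    }
  }

  mean_mix <- as.numeric(mu %*% w)
  var_mix <- as.numeric((sdm^2 + mu^2) %*% w) - mean_mix^2
  sd_mix <- sqrt(pmax(var_mix, 0))
  q025 <- q975 <- numeric(length(idx))
  for (s in seq_along(idx)) {
    if (K == 1L) {
      q025[s] <- mu[s, 1] + qnorm(0.025) * sdm[s, 1]
      q975[s] <- mu[s, 1] + qnorm(0.975) * sdm[s, 1]
    } else {
      q025[s] <- mixture_quantile(0.025, mu[s, ], sdm[s, ], w)
      q975[s] <- mixture_quantile(0.975, mu[s, ], sdm[s, ], w)
    }
  }
  data.frame(term = colnames(dm$W)[idx], block = block_lab,
             mean = mean_mix, sd = sd_mix, q025 = q025, q975 = q975,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Deviance information criterion of a fitted model
#'
#' Dbar is the posterior expectation of the Bernoulli deviance
#' D(u) = -2 log p(y | u); pD = Dbar - D(ubar) with ubar the posterior mean;
#' DIC = Dbar + pD. With `method = "mc"`, Dbar is a seeded Monte-Carlo
#' average over M draws from the mixture-of-Gaussians posterior; with
#' `method = "plugin"`, a deterministic second-order expansion
#' (deviance at each conditional mode plus the trace correction
#' tr(W' Lambda W Sigma)) is used instead, as in fast permutation scans.
#' Probabilities of exactly 0/1 under a draw are clamped to
#' [1e-12, 1 - 1e-12] with a warning.
#'
#' @inheritParams latent_marginals
#' @param method Overrides `config$dic_method`.
#' @return List with `Dbar`, `pD`, `DIC`, `method`.
#' @export
compute_dic <- function(design, tau_posterior, approxes, config,
                        method = config$dic_method) {
  dm <- design_matrix(design)
  .compute_dic(dm, design$y, tau_posterior, approxes, config, method)
}

.compute_dic <- function(dm, y, tau_posterior, approxes, config,
                         method = config$dic_method) {
  w <- tau_posterior$weights
  K <- length(approxes)
  d <- dm$d
  modes <- vapply(approxes, `[[`, numeric(d), "mode")
  modes <- matrix(modes, nrow = d)
  ubar <- as.numeric(modes %*% w)
  dev_bar <- .cpp_deviance(dm$W, y, ubar)
  clamped <- dev_bar$clamped

  if (method == "plugin") {
    dbar <- 0
    for (k in seq_len(K)) {
      ch <- chol(approxes[[k]]$H)
      dSig <- diag(chol2inv(ch))
      pd_k <- d - sum(approxes[[k]]$prec * dSig)
      dv <- .cpp_deviance(dm$W, y, modes[, k])
      clamped <- clamped || dv$clamped
      dbar <- dbar + w[k] * (dv$deviance + pd_k)
    }
  } else {
    chols <- lapply(approxes, function(a) chol(a$H))
    M <- config$dic_samples
    devs <- numeric(M)
    ks <- sample.int(K, M, replace = TRUE, prob = w)
    for (i in seq_len(M)) {
      k <- ks[i]
      z <- rnorm(d)
      u <- modes[, k] + backsolve(chols[[k]], z)
      dv <- .cpp_deviance(dm$W, y, u)
      clamped <- clamped || dv$clamped
      devs[i] <- dv$deviance
    }
    dbar <- mean(devs)
  }
  if (clamped) {
    warning("fitted probabilities numerically 0 or 1 were clamped in deviance",
            call. = FALSE)
  }
  pD <- dbar - dev_bar$deviance
  list(Dbar = dbar, pD = pD, DIC = dbar + pD, method = method)
}

#' Fit the null or full hierarchical model for one gene
#'
#' The null hypothesis is a Bayesian logistic regression of the phenotype on
#' the individual covariates only (single Laplace fit, no precision grid).
#' The full hypothesis adds the genetic term G(Z omega + delta) and runs the
#' log-precision grid pipeline. Both return posterior summaries of the fixed
#' effects and the DIC. A full fit of a gene with no variants (p = 0)
#' reduces to the null fit and is flagged `degenerate`.
#'
#' Monte-Carlo DIC draws are seeded from `config$seed`, so repeated calls
#' with identical inputs are reproducible.
#'
#' @inheritParams find_conditional_mode
#' @param hypothesis `"full"` (covariates + genetic term) or `"null"`.
#' @param dic_method Overrides `config$dic_method` (e.g. `"plugin"` for fast
#'   permutation scans).
#' @param marginals Compute fixed-effect posterior summaries (`FALSE` skips
#'   them; DIC-only fits in genome-wide scans).
#' @return Object of class `fit_result`: list with `hypothesis`, `effects`
#'   (fixed-effect posterior summaries, `NULL` when `marginals = FALSE`),
#'   `hyper` (psi posterior summary, full model only), `dic` (`Dbar`, `pD`,
#'   `DIC`), `degenerate`, `dims`.
#' @export
fit_model <- function(design, config = bati_config(),
                      hypothesis = c("full", "null"),
                      dic_method = config$dic_method,
                      marginals = TRUE) {
  hypothesis <- match.arg(hypothesis)
  if (hypothesis == "null" || design$p == 0L) {
    null_design <- design
    null_design$G <- matrix(0, design$n, 0)
    null_design$Z <- matrix(0, 0, 0)
    null_design$p <- 0L
    null_design$q <- 0L
    null_design$variant_ids <- character()
    dm <- design_matrix(null_design)
    ap <- .conditional_mode(dm, design$y, config, psi = 0)
    tp <- structure(list(psi = 0, log_density = 0, weights = 1),
                    class = "tau_posterior")
    approxes <- list(ap)
    eff <- if (marginals) {
      .latent_marginals(dm, tp, approxes,
                        strategy = config$marginal_strategy,
                        y = design$y, config = config)
    } else NULL
    dic <- with_seed(config$seed,
                     .compute_dic(dm, design$y, tp, approxes, config, dic_method))
    return(structure(list(
      hypothesis = hypothesis,
      effects = eff, hyper = NULL, dic = dic,
      degenerate = (hypothesis == "full"),
      dims = c(n = design$n, m = design$m, p = 0L, q = 0L)
    ), class = "fit_result"))
  }

  dm <- design_matrix(design)
  gi <- .integrate_tau(dm, design$y, config)
  tp <- gi$tau_posterior
  eff <- if (marginals) {
    .latent_marginals(dm, tp, gi$approxes,
                      strategy = config$marginal_strategy,
                      y = design$y, config = config)
  } else NULL
  dic <- with_seed(config$seed,
                   .compute_dic(dm, design$y, tp, gi$approxes, config, dic_method))
  psi_mean <- sum(tp$weights * tp$psi)
  psi_sd <- sqrt(max(sum(tp$weights * tp$psi^2) - psi_mean^2, 0))
  structure(list(
    hypothesis = "full",
    effects = eff,
    hyper = list(psi_mean = psi_mean, psi_sd = psi_sd,
                 psi_mode = tp$psi[which.max(tp$weights)],
                 precision_mean = sum(tp$weights * exp(tp$psi)),
                 tau_mean = sum(tp$weights * exp(-tp$psi)),
                 n_grid = length(tp$psi)),
    dic = dic,
    degenerate = FALSE,
    dims = c(n = design$n, m = design$m, p = design$p, q = design$q)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s%s): DIC = %.3f (Dbar %.3f, pD %.2f)\n",
              x$hypothesis, if (x$degenerate) ", degenerate" else "",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  if (!is.null(x$effects)) {
    print(x$effects, digits = 3)
  }
  invisible(x)
}
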