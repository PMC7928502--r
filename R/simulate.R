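# Synthetic cohort simulator: rare-variant WES-like background cohorts plus
# liability-threshold risk architectures spiked into cases.

#' Specification of a synthetic background cohort
#'
#' Describes a fully synthetic stand-in for a filtered whole-exome
#' case-control background: per-gene rare-variant counts, a rare-skewed
#' minor-allele-frequency spectrum, functional annotation categories with
#' category-specific deleteriousness scores, per-entry missingness and
#' optional population stratification (Balding-Nichols divergence of
#' per-population allele frequencies).
#'
#' @param n_samples Number of samples N.
#' @param case_control_ratio Two integers, cases : controls (1:1 or 1:2).
#' @param n_genes Number of genes.
#' @param gene_mean_meanlog,gene_mean_sdlog Per-gene expected variant counts
#'   are LogNormal(`gene_mean_meanlog`, `gene_mean_sdlog`); realized counts
#'   are Poisson around them.
#' @param maf_range Range of the 1/x-skewed MAF spectrum; the lower bound
#'   defaults to a singleton frequency 1/(2N).
#' @param category_probs Named probabilities of the annotation categories.
#' @param score_means,score_sds Per-category score (CADD-like) normal
#'   parameters, truncated at 0.
#' @param missing_rate Per-entry missing-call probability.
#' @param populations Optional character vector of population labels; `NULL`
#'   for a homogeneous cohort.
#' @param population_props Mixture proportions of the populations.
#' @param fst Balding-Nichols divergence parameter in [0, 1).
#' @param seed Integer seed.
#' @return Object of class `background_cohort_spec`.
#' @export
background_cohort_spec <- function(n_samples = 1000,
                                   case_control_ratio = c(1, 1),
                                   n_genes = 100,
                                   gene_mean_meanlog = log(25),
                                   gene_mean_sdlog = 0.5,
                                   maf_range = c(NA, 0.05),
                                   category_probs = c(synonymous = 0.45,
                                                      missense = 0.45,
                                                      LoF = 0.04,
                                                      indel = 0.06),
                                   score_means = c(synonymous = 5,
                                                   missense = 18,
                                                   LoF = 32, indel = 22),
                                   score_sds = c(synonymous = 3, missense = 6,
                                                 LoF = 5, indel = 6),
                                   missing_rate = 0.01,
                                   populations = NULL,
                                   population_props = NULL,
                                   fst = 0.01,
                                   seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 1,
            length(case_control_ratio) == 2, all(case_control_ratio > 0),
            abs(sum(category_probs) - 1) < 1e-8,
            missing_rate >= 0, missing_rate < 1,
            fst >= 0, fst < 1)
  if (is.na(maf_range[1])) maf_range[1] <- 1 / (2 * n_samples)
  stopifnot(maf_range[1] > 0, maf_range[2] > maf_range[1])
  if (!is.null(populations)) {
    if (is.null(population_props)) {
      population_props <- rep(1 / length(populations), length(populations))
    }
    stopifnot(length(population_props) == length(populations),
              abs(sum(population_props) - 1) < 1e-8)
  }
  structure(as.list(environment()), class = "background_cohort_spec")
}

# Transition partner of a base; used to draw realistic ref/alt pairs.
.ti_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate a synthetic background cohort
#'
#' Per gene, the variant count is Poisson with a log-normal gene-specific
#' mean; per variant, the MAF is drawn from a 1/x-skewed spectrum and
#' genotypes follow Hardy-Weinberg proportions (per-population frequencies
#' via a Balding-Nichols perturbation when stratification is enabled).
#' Functional categories and scores are sampled from the configured
#' distributions; missing calls are applied per entry and recorded in the
#' per-variant call rate. Reproducible for a fixed spec seed.
#'
#' @param spec A [background_cohort_spec()].
#' @return An [rv_cohort()].
#' @export
simulate_background <- function(spec) {
  stopifnot(inherits(spec, "background_cohort_spec"))
  with_seed(spec$seed, .simulate_background(spec))
}

.simulate_background <- function(spec) {
  N <- spec$n_samples
  rr <- spec$case_control_ratio
  n_case <- round(N * rr[1] / sum(rr))
  status <- sample(rep(c(1L, 0L), c(n_case, N - n_case)))
  sample_ids <- sprintf("S%05d", seq_len(N))

  pops <- spec$populations %||% "POP1"
  n_pop <- length(pops)
  pop_of <- if (n_pop > 1) {
    sample(pops, N, replace = TRUE, prob = spec$population_props)
  } else rep(pops, N)
  pop_idx <- lapply(pops, function(k) which(pop_of == k))

  gene_means <- rlnorm(spec$n_genes, spec$gene_mean_meanlog,
                       spec$gene_mean_sdlog)
  counts <- rpois(spec$n_genes, gene_means)
  P <- sum(counts)
  if (P == 0L) stopf("simulated cohort has zero variants; increase gene means")
  gene_of <- rep(sprintf("G%05d", seq_len(spec$n_genes)), counts)

  lo <- spec$maf_range[1]; hi <- spec$maf_range[2]
  maf <- lo * (hi / lo)^runif(P)

  cats <- names(spec$category_probs)
  category <- sample(cats, P, replace = TRUE, prob = spec$category_probs)
  score <- rtruncnorm_lower(P, spec$score_means[category],
                            spec$score_sds[category], 0)

  is_indel <- category == "indel"
  ref <- sample(c("A", "C", "G", "T"), P, replace = TRUE)
  alt <- character(P)
  is_ti <- runif(P) < 0.7
  alt[!is_indel & is_ti] <- .ti_partner[ref[!is_indel & is_ti]]
  tv_pick <- function(b) {
    others <- setdiff(c("A", "C", "G", "T"), c(b, .ti_partner[b]))
    others[sample.int(2, 1)]
  }
  idx_tv <- which(!is_indel & !is_ti)
  alt[idx_tv] <- vapply(ref[idx_tv], tv_pick, character(1))
  alt[is_indel] <- paste0(ref[is_indel],
                          sample(c("A", "C", "G", "T"), sum(is_indel),
                                 replace = TRUE))

  pos <- seq_len(P) * 10L
  variant_id <- sprintf("1:%d:%s:%s", pos, ref, alt)

  # per-population allele frequencies (Balding-Nichols)
  if (n_pop > 1 && spec$fst > 0) {
    f <- spec$fst
    pf <- vapply(seq_len(n_pop), function(k) {
      rbeta(P, maf * (1 - f) / f, (1 - maf) * (1 - f) / f)
    }, numeric(P))
    pf <- pmin(pmax(pf, 1e-6), 0.5)
  } else {
    pf <- matrix(maf, nrow = P, ncol = n_pop)
  }

  gi <- vector("list", P)  # carrier sample indices per variant
  gx <- vector("list", P)  # dosages
  mi <- vector("list", P)  # missing sample indices
  call_rate <- numeric(P)
  for (j in seq_len(P)) {
    ii <- integer(0); xx <- numeric(0)
    for (k in seq_len(n_pop)) {
      sidx <- pop_idx[[k]]
      nk <- length(sidx)
      if (nk == 0L) next
      m <- pf[j, k]
      p1 <- 2 * m * (1 - m); p2 <- m * m
      n1 <- rbinom(1L, nk, p1)
      n2 <- rbinom(1L, nk - n1, min(p2 / (1 - p1), 1))
      if (n1 + n2 > 0L) {
        pick <- sidx[sample.int(nk, n1 + n2)]
        ii <- c(ii, pick)
        xx <- c(xx, rep(c(1, 2), c(n1, n2)))
      }
    }
    nmiss <- rbinom(1L, N, spec$missing_rate)
    call_rate[j] <- 1 - nmiss / N
    if (nmiss > 0L) {
      midx <- sample.int(N, nmiss)
      mi[[j]] <- midx
      drop <- ii %in% midx
      if (any(drop)) { ii <- ii[!drop]; xx <- xx[!drop] }
    } else {
      mi[[j]] <- integer(0)
    }
    gi[[j]] <- ii
    gx[[j]] <- xx
  }

  nnz <- lengths(gi)
  G <- Matrix::sparseMatrix(i = unlist(gi), j = rep(seq_len(P), nnz),
                            x = unlist(gx), dims = c(N, P),
                            dimnames = list(sample_ids, variant_id))
  nnm <- lengths(mi)
  miss <- Matrix::sparseMatrix(i = unlist(mi), j = rep(seq_len(P), nnm),
                               x = rep(TRUE, sum(nnm)), dims = c(N, P),
                               dimnames = list(sample_ids, variant_id))

  variants <- data.frame(
    variant_id = variant_id, chrom = "1", pos = pos, ref = ref, alt = alt,
    gene = gene_of, exonic_function = category, cadd = score,
    af_public = maf, call_rate = call_rate, spiked = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_pop > 1) {
    for (k in seq_len(n_pop)) variants[[paste0("af_", pops[k])]] <- pf[, k]
  }
  samples <- data.frame(sample = sample_ids, status = status,
                        population = pop_of, stringsAsFactors = FALSE)
  rv_cohort(G, variants, samples, miss = miss)
}

#' Sample a genotype relative risk given the risk-allele frequency
#'
#' Draws log RR from a normal whose mean decreases linearly in MAF from
#' log(8) as MAF tends to 0 down to log(1.5) at MAF = 0.01 (sd 0.3),
#' truncated below at RR = 1.1, encoding the negative correlation between
#' effect size and allele frequency typical of rare risk variants.
#'
#' @param maf Risk-allele frequencies in (0, 0.01].
#' @return Relative risks, one per element of `maf` (all >= 1.1).
#' @export
sample_rr <- function(maf) {
  if (any(maf <= 0 | maf > 0.01)) stopf("maf must lie in (0, 0.01]")
  mu <- log(8) + (maf / 0.01) * (log(1.5) - log(8))
  exp(rtruncnorm_lower(length(maf), mu, 0.3, log(1.1)))
}

#' Liability-threshold variance explained by one risk variant
#'
#' Computes the fraction of liability-scale phenotypic variance explained by
#' a biallelic risk variant under the liability threshold model: genotype
#' frequencies follow Hardy-Weinberg, genotype risks are multiplicative
#' (relative risks 1, rr, rr^2), the baseline penetrance is scaled so the
#' population risk equals the prevalence, each genotype's liability mean is
#' mu_g = qnorm(1 - prevalence) - qnorm(1 - penetrance_g), and
#' VE = Var_g(mu_g) / (Var_g(mu_g) + 1).
#'
#' @param prevalence Disease prevalence K in (0, 1).
#' @param maf Risk-allele frequency in (0, 1).
#' @param rr Genotype relative risk (>= 1).
#' @return VE fraction in [0, 1).
#' @export
variance_explained <- function(prevalence, maf, rr) {
  stopifnot(prevalence > 0, prevalence < 1, maf > 0, maf < 1, rr >= 1)
  f <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  lam <- c(1, rr, rr^2)
  base <- prevalence / sum(f * lam)
  pen <- base * lam
  if (pen[2] >= 1) {
    stopf("implied heterozygote penetrance >= 1 (prevalence %g, maf %g, rr %g)",
          prevalence, maf, rr)
  }
  # the rare homozygote class can saturate at very large RR; its frequency
  # (maf^2) makes the clamp numerically irrelevant
  pen <- pmin(pen, 1 - 1e-12)
  thr <- qnorm(1 - prevalence)
  mu <- thr - qnorm(1 - pen)
  v <- sum(f * mu^2) - sum(f * mu)^2
  v / (v + 1)
}

#' Simulate a pool of candidate risk variants
#'
#' Synthetic stand-in for a database-derived pool of known pathogenic
#' variants: rare risk-allele frequencies (log-uniform on
#' `maf_range`), MAF-dependent relative risks via [sample_rr()], damaging
#' functional categories and high deleteriousness scores. Uses the caller's
#' RNG state.
#'
#' @param n_variants Pool size.
#' @param maf_range Risk-allele frequency range, within (0, 0.01].
#' @param category_probs Named probabilities over missense / LoF / indel.
#' @param score_means,score_sds Per-category truncated-normal score
#'   parameters (truncated at 10, the conventional deleteriousness filter).
#' @return Data frame: `variant_id`, `maf`, `rr`, `category`, `score`.
#' @export
simulate_risk_pool <- function(n_variants = 200,
                               maf_range = c(1e-5, 0.01),
                               category_probs = c(missense = 0.5,
                                                  LoF = 0.35, indel = 0.15),
                               score_means = c(missense = 25, LoF = 35,
                                               indel = 28),
                               score_sds = c(missense = 4, LoF = 3,
                                             indel = 5)) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.01,
            abs(sum(category_probs) - 1) < 1e-8)
  maf <- maf_range[1] * (maf_range[2] / maf_range[1])^runif(n_variants)
  category <- sample(names(category_probs), n_variants, replace = TRUE,
                     prob = category_probs)
  data.frame(
    variant_id = sprintf("risk%04d", seq_len(n_variants)),
    maf = maf,
    rr = sample_rr(maf),
    category = category,
    score = rtruncnorm_lower(n_variants, score_means[category],
                             score_sds[category], 10),
    stringsAsFactors = FALSE
  )
}

#' Assign risk-pool variants to populations
#'
#' Variants observed in a reference frequency panel are labelled with the
#' population of their largest panel allele frequency; unobserved variants
#' (all frequencies `NA`) are assigned uniformly at random. With a single
#' population every variant receives that label (homogeneous-cohort mode).
#'
#' @param pool A [simulate_risk_pool()] data frame.
#' @param population_afs Optional numeric matrix, one row per pool variant
#'   and one column per population, of reference-panel allele frequencies
#'   (`NA` = not observed).
#' @param populations Character vector of population labels (column order of
#'   `population_afs`).
#' @return `pool` with a `population` column added.
#' @export
assign_populations <- function(pool, population_afs = NULL, populations) {
  stopifnot(length(populations) >= 1)
  if (length(populations) == 1L) {
    pool$population <- populations
    return(pool)
  }
  n <- nrow(pool)
  lab <- character(n)
  if (is.null(population_afs)) {
    lab <- sample(populations, n, replace = TRUE)
  } else {
    stopifnot(nrow(population_afs) == n,
              ncol(population_afs) == length(populations))
    for (i in seq_len(n)) {
      afs <- population_afs[i, ]
      if (all(is.na(afs))) {
        lab[i] <- sample(populations, 1)
      } else {
        lab[i] <- populations[which.max(afs)]
      }
    }
  }
  pool$population <- lab
  pool
}

#' Build a risk-gene architecture targeting a variance-explained level
#'
#' Draws variants from the pool (without replacement, respecting the
#' category mode), accumulating per-variant liability-scale VE additively
#' until the cumulative VE reaches the target. Uses the caller's RNG state.
#'
#' @param pool A [simulate_risk_pool()] data frame (optionally with a
#'   `population` column).
#' @param gene Target gene id.
#' @param target_ve Target cumulative VE (the benchmark levels are 0.02,
#'   0.01 and 0.005).
#' @param mode `"any"`, `"missense"` (missense-only) or `"LoF"` (LoF-only).
#' @param prevalence Disease prevalence (default 0.0066).
#' @return Object of class `architecture_spec`: list with `gene`,
#'   `target_ve`, `mode`, `prevalence` and `variants` (selected pool rows
#'   plus `ve` and `cum_ve`).
#' @export
build_architecture <- function(pool, gene, target_ve,
                               mode = c("any", "missense", "LoF"),
                               prevalence = 0.0066) {
  mode <- match.arg(mode)
  elig <- if (mode == "any") pool else pool[pool$category == mode, , drop = FALSE]
  if (target_ve > 0 && nrow(elig) == 0L) {
    stopf("risk pool has no variants for mode '%s'", mode)
  }
  sel <- elig[0, , drop = FALSE]
  cum <- 0
  if (target_ve > 0) {
    ord <- sample.int(nrow(elig))
    for (i in ord) {
      v <- elig[i, , drop = FALSE]
      v$ve <- variance_explained(prevalence, v$maf, v$rr)
      cum <- cum + v$ve
      v$cum_ve <- cum
      sel <- rbind(sel, v)
      if (cum >= target_ve) break
    }
    if (cum < target_ve) {
      stopf("risk pool exhausted before reaching VE %g (achieved %.5f)",
            target_ve, cum)
    }
  }
  structure(list(gene = gene, target_ve = target_ve, mode = mode,
                 prevalence = prevalence, variants = sel,
                 achieved_ve = cum),
            class = "architecture_spec")
}

#' Spike risk variants into the cases of a cohort
#'
#' For each selected variant, the number of case carriers is drawn as
#' Binomial(number of eligible cases, 2 * MAF * RR) — the rare-variant
#' case-frequency approximation — capped by availability. Carriers are
#' heterozygous, each case receives at most one spiked variant across the
#' whole architecture, and controls are left untouched. In a stratified
#' cohort only cases of the variant's population are eligible. Uses the
#' caller's RNG state.
#'
#' @param cohort An [rv_cohort()].
#' @param architecture A [build_architecture()] result.
#' @return The cohort with the spiked variant columns appended; the
#'   attribute `"spike_log"` records per-variant carrier counts.
#' @export
spike_cases <- function(cohort, architecture) {
  stopifnot(inherits(cohort, "rv_cohort"),
            inherits(architecture, "architecture_spec"))
  av <- architecture$variants
  nv <- nrow(av)
  if (nv == 0L) return(cohort)
  case_idx <- which(cohort$samples$status == 1)
  if (length(case_idx) == 0L) stopf("cohort has no cases to spike")
  N <- nrow(cohort$samples)
  used <- logical(N)
  ii <- vector("list", nv)
  n_carriers <- integer(nv)
  stratified <- !is.null(av$population) &&
    length(unique(cohort$samples$population)) > 1
  for (v in seq_len(nv)) {
    elig <- case_idx
    if (stratified) {
      elig <- elig[cohort$samples$population[elig] == av$population[v]]
    }
    if (length(elig) == 0L) stopf("no eligible cases for spiked variant %s",
                                  av$variant_id[v])
    prob <- min(2 * av$maf[v] * av$rr[v], 1)
    k <- rbinom(1L, length(elig), prob)
    free <- elig[!used[elig]]
    k <- min(k, length(free))
    carriers <- if (k > 0L) free[sample.int(length(free), k)] else integer(0)
    used[carriers] <- TRUE
    ii[[v]] <- carriers
    n_carriers[v] <- k
  }
  base_pos <- max(cohort$variants$pos) + 10L
  pos <- base_pos + seq_len(nv) * 10L
  ref <- rep("A", nv)
  alt <- ifelse(av$category == "indel", "AT", "G")
  vid <- sprintf("1:%d:%s:%s", pos, ref, alt)
  newG <- Matrix::sparseMatrix(i = unlist(ii),
                               j = rep(seq_len(nv), lengths(ii)),
                               x = rep(1, sum(lengths(ii))),
                               dims = c(N, nv),
                               dimnames = list(rownames(cohort$G), vid))
  new_variants <- data.frame(
    variant_id = vid, chrom = "1", pos = pos, ref = ref, alt = alt,
    gene = architecture$gene, exonic_function = av$category,
    cadd = av$score, af_public = av$maf, call_rate = 1, spiked = TRUE,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(cohort$variants), names(new_variants))
  for (cc in extra) {
    new_variants[[cc]] <- if (cc == "population" && !is.null(av$population)) {
      av$population
    } else NA
  }
  new_variants <- new_variants[names(cohort$variants)]
  miss <- cohort$miss
  if (!is.null(miss)) {
    zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = logical(0),
                                 dims = c(N, nv),
                                 dimnames = list(rownames(cohort$G), vid))
    miss <- cbind(miss, zero)
  }
  out <- rv_cohort(cbind(cohort$G, newG),
                   rbind(cohort$variants, new_variants),
                   cohort$samples, miss = miss)
  attr(out, "spike_log") <- data.frame(variant_id = vid,
                                       pool_id = av$variant_id,
                                       maf = av$maf, rr = av$rr,
                                       ve = av$ve,
                                       n_carriers = n_carriers,
                                       stringsAsFactors = FALSE)
  out
}

#' Generate a replicated benchmark dataset
#'
#' Simulates one background cohort from `background_spec`, then per
#' architecture and replicate re-randomizes the case/control assignment
#' (preserving group sizes, randomizing background noise), re-draws the
#' architecture's variant selection from the pool and spikes the cases.
#' Each replicate is deterministic given `(seed, architecture, replicate)`.
#' When `out_dir` is given, each replicate is written as VCF plus annotation
#' and phenotype tables with a JSON truth manifest.
#'
#' @param background_spec A [background_cohort_spec()].
#' @param architectures List of lists with elements `gene`, `target_ve` and
#'   optionally `mode` (default `"any"`).
#' @param pool Risk-variant pool from [simulate_risk_pool()].
#' @param n_replicates Replicates per architecture (benchmark default 100).
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @param keep_cohorts Return the spiked cohorts in memory (only sensible at
#'   small scale).
#' @param prevalence Disease prevalence used for VE accumulation.
#' @return List with `inventory` (data frame: architecture, replicate, gene,
#'   target VE, achieved VE, carriers, seed, path) and, if requested,
#'   `cohorts` (list indexed as `inventory$id`).
#' @export
generate_benchmark_dataset <- function(background_spec, architectures, pool,
                                       n_replicates = 100, seed = 1L,
                                       out_dir = NULL, keep_cohorts = FALSE,
                                       prevalence = 0.0066) {
  stopifnot(n_replicates >= 1)
  background <- simulate_background(background_spec)
  inv <- list()
  cohorts <- list()
  row <- 0L
  for (a in seq_along(architectures)) {
    arch <- architectures[[a]]
    for (r in seq_len(n_replicates)) {
      rep_seed <- derive_seed(seed, a * 100000L + r)
      bundle <- with_seed(rep_seed, {
        coh <- background
        coh$samples$status <- sample(coh$samples$status)
        spec_a <- build_architecture(pool, arch$gene, arch$target_ve,
                                     mode = arch$mode %||% "any",
                                     prevalence = prevalence)
        list(cohort = spike_cases(coh, spec_a), arch = spec_a)
      })
      row <- row + 1L
      id <- sprintf("arch%02d_rep%03d", a, r)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, id)
        dir.create(path, recursive = TRUE, showWarnings = FALSE)
        write_cohort(bundle$cohort, path)
        manifest <- list(
          architecture = a, replicate = r, gene = arch$gene,
          target_ve = arch$target_ve, mode = arch$mode %||% "any",
          achieved_ve = bundle$arch$achieved_ve,
          seed = rep_seed,
          spiked = attr(bundle$cohort, "spike_log")
        )
        jsonlite::write_json(manifest, file.path(path, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      inv[[row]] <- data.frame(
        id = id, architecture = a, replicate = r, gene = arch$gene,
        target_ve = arch$target_ve,
        achieved_ve = bundle$arch$achieved_ve,
        n_spiked = nrow(bundle$arch$variants),
        n_carriers = sum(attr(bundle$cohort, "spike_log")$n_carriers),
        seed = rep_seed, path = path, stringsAsFactors = FALSE
      )
      if (keep_cohorts) cohorts[[id]] <- bundle$cohort
    }
  }
  out <- list(inventory = do.call(rbind, inv))
  if (keep_cohorts) out$cohorts <- cohorts
  out
}
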