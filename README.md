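# rvbati

Gene-level **rare-variant association testing** for case-control
sequencing cohorts, built around a hierarchical Bayesian logistic
generalized linear mixed model. The package is aimed at statistical
geneticists running whole-exome / whole-genome case-control studies in
which single-variant tests are powerless and gene-level aggregation must
exploit *variant characteristics* — functional category and
deleteriousness scores — to recover weak signals.

## The model

For samples $i = 1,\dots,N$ with binary phenotype $Y_i$, covariates
$X_i$ and rare-variant dosages $G_i \in \{0,1,2\}^p$ within one gene:

$$
Y_i \sim \mathrm{Bernoulli}(\mu_i), \quad
\mathrm{logit}(\mu_i) = X_i^t\alpha + G_i^t\beta, \quad
\beta = Z\omega + \delta, \quad \delta \sim N(0, \tau I),
$$

where $Z$ holds one indicator column per functional category (missense,
LoF, indel, ...) plus numeric scores (e.g. CADD), $\omega$ their
effects, and $\delta$ per-variant heterogeneity. Inference is
deterministic: a Laplace (Gaussian) approximation of the latent field
combined with grid integration over the random-effect log-precision, in
the style of integrated nested Laplace approximation. Each gene is
scored by

$$
\Delta\mathrm{DIC} = \mathrm{DIC}_{H_0} - \mathrm{DIC}_{H_1},
$$

the deviance-information-criterion difference between the covariate-only
and the genetic model; large positive values favour a genetic effect.
Significance thresholds at chosen type-I-error (TIER) levels are
calibrated empirically by case/control label permutation: per shuffle the
top-$\lceil K a\rceil$ order statistic of the per-gene
$\Delta\mathrm{DIC}$, medianed over shuffles.

The package also ships the surrounding workflow: variant filters
(frequency, CADD, synonymous), sample QC (variant counts, Ti/Tv,
genotype PCA outliers), a synthetic WES-like cohort simulator with
liability-threshold variance-explained (VE) risk architectures, a power
benchmark harness and a minimal burden baseline.

## Worked example

Simulate a 400-sample background cohort, spike one gene with
loss-of-function risk variants explaining ~2% of liability-scale
variance, calibrate the permutation thresholds, and run the scan:

```r
library(rvbati)

coh  <- simulate_background(background_cohort_spec(
          n_samples = 400, n_genes = 50, seed = 7))
pool <- local({ set.seed(1); simulate_risk_pool(300, maf_range = c(5e-4, 0.01)) })
arch <- local({ set.seed(2)
                build_architecture(pool, "G00019", target_ve = 0.02, mode = "LoF") })
coh  <- local({ set.seed(3); spike_cases(coh, arch) })

thr  <- estimate_tier_thresholds(coh, levels = c(0.05, 0.001), S = 3,
                                 seed = 11, prefilter = apply_filters)
cfg  <- bati_config(marginal_strategy = "laplace", center_scores = TRUE)
res  <- run_rvas(coh, cfg, thresholds = thr, dic_method = "plugin")
head(res$results, 3)
res$effects[["G00019"]]
```

```
    gene n_variants n_lof n_missense n_indel delta_dic status rank sig_0.05 sig_0.001
1 G00019         32    15         13       4  109.1925     ok    1     TRUE      TRUE
2 G00018         12     2          8       2    2.1945     ok    2     TRUE     FALSE
3 G00024          5     0          4       1    1.0860     ok    3    FALSE     FALSE

      term          block  mean    sd    q025  q975
2    indel characteristic 2.600 1.585 -0.5074 5.707
3      LoF characteristic 3.645 1.408  0.8865 6.404
4 missense characteristic 1.720 0.847  0.0598 3.379
5     cadd characteristic 0.278 0.132  0.0201 0.536
```

The spiked gene tops the ranking with $\Delta\mathrm{DIC} \approx 109$ —
far beyond the 0.1%-level permutation threshold (4.47 here; the
conventional rule of thumb is $\Delta\mathrm{DIC} > 10$) — while the
background genes hover around their null thresholds. In the effect
table, the LoF category shows the strongest mean effect (3.65, 95% CI
0.89–6.40, excluding 0), exactly the behaviour expected when the spiked
risk variants are loss-of-function; `cadd` is the effect per score unit
(scores centred within the gene via `center_scores` so that category
rows read as category mean effects).

## Package layout

| Area | Entry points |
|---|---|
| Inference core | `assemble_design`, `fit_model`, `integrate_tau`, `latent_marginals`, `compute_dic` |
| Association | `test_gene`, `delta_dic`, `estimate_tier_thresholds`, `classify_genes` |
| Simulator | `simulate_background`, `simulate_risk_pool`, `build_architecture`, `spike_cases`, `generate_benchmark_dataset` |
| QC / filters | `filter_variants`, `call_rate_filter`, `compute_titv`, `detect_sample_outliers`, `genotype_pca` |
| Harness | `read_cohort`, `write_cohort`, `run_rvas`, `estimate_power`, `burden_baseline`, `benchmark_null_calibration`, `benchmark_power` |

A thin command-line front end (`inst/cli/rvbati.R`) exposes
`simulate` / `qc` / `thresholds` / `test` / `power` subcommands over a
YAML run configuration. The methods vignette
(`vignettes/rvbati-methods.Rmd`) documents the model, priors, numerical
choices and the simulator's scope in detail.
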