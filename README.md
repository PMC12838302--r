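# alphamix

Tools for asking *which population's allele frequency best predicts the
per-allele effect sizes of common genetic variants*. Genetic architectures
are usually modelled with the single-population "alpha model": the
per-allele effect-size variance of a SNP is proportional to
`[p(1-p)]^alpha`, where `p` is its minor allele frequency (MAF) in the GWAS
population and `alpha < 0` reflects negative selection. Because most common
variants predate the out-of-Africa bottleneck — which distorted non-African
frequencies — the African MAF of a variant can track selection more
faithfully than its European MAF even for European GWAS. `alphamix`
generalises the selection term to a mixture frequency

```
pmix = w * pA + (1 - w) * pE
E[beta^2 | pA, pE] = sigma_g^2 / 2 * [pmix (1 - pmix)]^alpha_mix
logit P(nonsynonymous)  = mu + gamma * log(pmix)
```

and estimates the mixture weight `w` two ways: a profile likelihood over
`w` for the logistic non-synonymous model, and a generalized-method-of-
moments fit of `(w, alpha_mix, sigma_g^2)` to bin-wise per-allele
effect-size variance estimated from GWAS summary statistics across a
12 x 10 grid of bivariate African/European MAF bins. Both come with
likelihood-ratio or block-jackknife uncertainty, non-nested model
comparison (Vuong test, relative likelihood gains, scaled MSE against a
no-MAF-dependence null), random-effects meta-analysis across traits, and a
fully seeded generative simulator so the entire pipeline runs end-to-end
without external data.

The package is aimed at statistical geneticists studying MAF-dependent
architectures, and at anyone who needs a tested reference implementation of
the mixture-frequency estimators on synthetic data.

## Worked example

Estimate the mixture weight from simulated non-synonymous labels:

```r
library(alphamix)

panel <- simulate_maf_panel(50000, seed = 42)       # correlated pA/pE panel
lab   <- label_nonsynonymous(panel, w = 0.95, gamma = -0.5, mu = -3, seed = 43)
prof  <- maximize_profile(lab$nonsyn, lab$maf_afr, lab$maf_eur)
prof
#> <profile_curve> n = 50000 SNPs
#>   w_mle = 0.9481 (95% CI 0.9226, 0.9686), gamma = -0.5132, logLik = -26090.14
format_pvalue(lrt_pvalue(prof, 0))
#> [1] "<1e-15"
```

The profile MLE recovers the generative weight (0.95) within its
likelihood-ratio CI, and the European-only model (`w = 0`) is rejected.
`autoplot(prof)` draws the profile curve.

Fit the effect-variance model to bin-wise variances from five simulated
traits (here using true effects; `fit_stratified_ldsc()` +
`per_allele_variance()` + `bin_mean_variance()` produce the same tables
from summary statistics):

```r
panel  <- alphamix:::simulate_common_panel(8000, 0.01, 0.12)  # pE >= 0.05
scheme <- build_binning_scheme(panel, preset = "fit")          # 120 bins
binned <- assign_bins(panel, scheme, eur_common_only = TRUE)
cfg    <- generative_config(n_snps = 8000, n_causal = 2000, w_true = 0.95, seed = 1)
tabs   <- dplyr::bind_rows(lapply(1:5, function(t) {
  pt <- simulate_causal_effects(binned, cfg, seed = 100 + t)
  oracle_bin_variance(pt, trait = sprintf("trait%02d", t))
}))
fit <- fit_alphamix(tabs, seed = 1)
fit
#> <alphamix_fit> 5 trait(s), 119 bins/trait, bin_mean moment form
#>   w = 0.8814, alpha = -0.4102, scaled MSE = 0.5884
fit$comparisons
#>   model        w  alpha     loss scaled_mse
#> 1 alphamix 0.881 -0.410 0.000335      0.588
#> 2 null     0      0     0.000570      1
#> 3 w0       0     -0.413 0.000486      0.854
#> 4 w1       1     -0.250 0.000353      0.620
```

The joint fit places most weight on African MAF (`w = 0.88` at a
generative 0.95), with the scaled mean-squared error normalised so the
no-MAF-dependence null is exactly 1; the mixture model fits better than
the European-only (`w0`) and African-only (`w1`) restrictions. `tidy(fit)`
and `glance(fit)` return the estimates as tibbles;
`profile_alpha_over_w()` and its `autoplot()` show how the exponent
estimate and fit quality vary with `w`, and `run_simulation_study()` wraps
panel simulation, summary-statistic generation, chi-square regression and
the joint fit into one seeded experiment.

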