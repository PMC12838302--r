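---
title: "Mixture-frequency models of MAF-dependent genetic architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-frequency models of MAF-dependent genetic architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphamix)
```

## The models

Negative selection couples a variant's effect on a trait to its frequency:
variants with larger per-allele effects are held at lower minor allele
frequency (MAF). The standard single-population formulation ("alpha model")
writes the per-allele effect-size variance of a SNP as proportional to
$[p(1-p)]^\alpha$ for its MAF $p$ in the GWAS population, with $\alpha < 0$
meaning rarer variants have larger effects. Because most common variants are
older than the split between African and non-African populations, and the
out-of-Africa bottleneck distorted non-African allele frequencies, the MAF
observed in an unadmixed African population can carry a cleaner record of
selection than the European MAF of the same variant. `alphamix` implements
models in which the frequency entering the selection term is a *mixture*:

$$p_{\mathrm{mix}} = w\,p_A + (1 - w)\,p_E,$$

with $p_A$, $p_E$ the folded African and European MAFs and $w$ the mixture
weight. Two complementary analyses share this predictor.

**Per-allele effect-size variance.** For trait $t$,

$$E[\beta_t^2 \mid p_A, p_E] =
  \frac{\sigma_{g,t}^2}{2}\,
  \bigl[p_{\mathrm{mix}}(1 - p_{\mathrm{mix}})\bigr]^{\alpha_{\mathrm{mix}}},$$

where $\beta_t$ is the per-allele causal effect, $\sigma_{g,t}^2$ a
trait-specific variance parameter, and $\alpha_{\mathrm{mix}}$ the degree of
MAF dependence. $w = 0$ recovers the standard European-MAF alpha model;
$w = 1$ is a purely African-MAF model.

**Non-synonymous status.** The probability that a SNP is non-synonymous — a
proxy for being under strong selection that does not require GWAS data — is
modelled by logistic regression:

$$\mathrm{logit}\,P(Y = 1) = \mu + \gamma \log p_{\mathrm{mix}}.$$

For fixed $w$ this is an ordinary two-parameter logistic fit; $w$ itself is
estimated by profiling the likelihood, $L(w) = \max_{\mu,\gamma}
L(w, \mu, \gamma)$, and maximising over $w$ numerically
(`maximize_profile()`). Confidence intervals and tests for $w$ come from the
1-df likelihood-ratio statistic, $\{w : 2[L(\hat w) - L(w)] \le 3.841\}$.

## Estimating the effect-variance model

Per-SNP effect-variance estimates are far too noisy to fit the variance
model directly, so estimation works on *bivariate MAF bins*:

1. **Binning** (`build_binning_scheme()`, `assign_bins()`): SNPs are
   stratified by African MAF into 12 bins (10 common-MAF deciles, one
   low-frequency bin $[0.005, 0.05)$, one rare bin $< 0.005$) crossed with
   10 European common-MAF deciles — 120 bivariate bins. SNPs with European
   MAF below 0.05 are excluded from the trait fit, because heritability
   partitioning is only reliable for common SNPs in the GWAS population.
   Decile boundaries are empirical quantiles (type 7) of the reference
   MAFs; bins are left-closed/right-open with the last bin closed at 0.5.
   A coarser 7 x 5 `"display"` scheme serves heat tables.
2. **Bin-wise variance** (`fit_stratified_ldsc()`,
   `per_allele_variance()`, `bin_mean_variance()`): per-SNP $\chi^2$
   statistics are regressed on $N \times$ annotation LD scores with one
   indicator annotation per bivariate bin, giving per-annotation
   heritability coefficients $\tau_d$; per-SNP heritability
   $\hat h^2_i = \sum_d a_d(i)\hat\tau_d$ is converted to per-allele scale
   by dividing by the Hardy-Weinberg variance $2 p_{E,i}(1 - p_{E,i})$, and
   averaged within bins. Negative estimates are retained throughout — the
   moment fit handles them, and truncation would bias bin means upward.
3. **GMM fit** (`fit_alphamix()`): parameters minimise the
   SNP-count-weighted squared deviation between the model's predicted bin
   variance (evaluated at the mixture of bin-mean MAFs, which equals the
   bin mean of per-SNP mixtures by linearity) and the estimated bin means,
   summed over traits. For fixed $(w, \alpha_{\mathrm{mix}})$ each
   $\sigma_{g,t}^2$ has a closed-form minimiser
   $2\sum_k n_k \hat\beta^2_{t,k} g_k / \sum_k n_k g_k^2$ with
   $g_k = [\bar p_{\mathrm{mix},k}(1-\bar p_{\mathrm{mix},k})]^{\alpha}$,
   so the search is effectively two-dimensional.

Uncertainty for any pipeline output comes from a genomic block jackknife
(`block_jackknife()`): 200 blocks contiguous in positional order with
counts differing by at most one, identical boundaries reused across traits,
$SE^2 = \frac{B-1}{B}\sum_b(\theta_{(b)} - \bar\theta)^2$, normal CIs and
two-sided p-values (reported as `<1e-15` below that floor). Per-trait
estimates are combined by DerSimonian–Laird random-effects meta-analysis
with a fixed-effects and Cochran's Q companion (`meta_analyze()`), and an
analysis set of approximately independent traits can be assembled greedily
by descending $N h^2$ under a squared-genetic-correlation ceiling
(`select_independent_traits()`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maf_floor` | 0.002 | floor applied to $p_A$, $p_E$ before $\log p_{\mathrm{mix}}$ in the logistic model; 0.05 reproduces the common-only sensitivity analysis |
| `w` bounds | $[-0.5, 1.5]$ | search interval for the mixture weight (both models) |
| `alpha` bounds | $[-1.5, 1.5]$ | search interval for the exponent |
| `plateau_T` | 0.005 | generative threshold below which effect variance stops growing with decreasing $p_{\mathrm{mix}}$ |
| `n_common_bins` | 10 | common-MAF bins per ancestry (5 for display) |
| `n_blocks` | 200 | jackknife blocks |
| `pE_min` | 0.05 | common-European restriction for trait fits and normalisers |

Weights outside $[0,1]$ can push $p_{\mathrm{mix}}$ out of $(0, 0.5]$; every
power or log transform therefore clamps it into $[10^{-6}, 0.5]$ first.

## Numerical choices

- **Logistic solver:** two-parameter IRLS with closed 2x2 weighted normal
  equations, gradient tolerance $10^{-8}$, at most 100 iterations, a
  $10^{-10}$ ridge on the information matrix and step damping near
  separation. Complete separation and constant predictors are errors, not
  silently returned fits.
- **Profile maximiser:** coarse 31-point grid warm start, then Brent
  search (tolerance $10^{-6}$); CI endpoints by root-finding on the LRT
  statistic. A profile that never crosses the cutoff inside the bounds
  returns the bound as the endpoint with a warning rather than failing.
- **GMM optimiser:** rand/1/bin differential evolution (population 30, up
  to 200 generations, $F = 0.8$, $CR = 0.9$, fixed seed, early stop when
  the population's loss spread collapses) followed by an L-BFGS-B polish.
  Deterministic starts at $w \in \{-0.5, 0, 1, 1.5\}$ are always polished
  too, which guarantees the fitted loss never exceeds the nested
  fixed-weight models even on flat or multimodal objectives. Near-ties
  between distinct optima are resolved toward the most central $w$ and
  flagged as weakly identified.
- **Moment form:** the default evaluates the variance law at the mixture of
  bin-mean MAFs; an alternative per-SNP form averages the transformed
  per-SNP values within bins (optionally plateau-thresholded). The two
  differ only through Jensen-gap effects within bins; the bin-mean form is
  the default because 10 common bins per ancestry keep within-bin MAF
  spread small.
- **Degenerate inputs:** empty bins are excluded with a warning; a panel
  whose mixture frequencies collapse to one point cannot be rescaled to a
  target heritability and is rejected; rank-deficient LD-score designs
  error with the names of the collinear annotations.

## The generative simulator

`simulate_maf_panel()` draws an ancestral frequency from a $1/q$ density
truncated to $[5\times10^{-4}, 1-5\times10^{-4}]$ (the neutral
infinite-sites shape) and then population frequencies from Balding–Nichols
Beta distributions with drift $F_A = 0.01$ and $F_E = 0.12$. These drifts
are *emulation knobs, not demographic claims*: they give folded-MAF
correlation near 0.8, a European spectrum with an excess of drifted-to-rare
variants, and a small class of SNPs common in Europeans but rare in
Africans — the features the downstream analyses rely on. Labels follow the
logistic model (defaults $\mu = -3$, $\gamma = -0.5$: a steeper slope and
higher base rate than typical consequence annotations, chosen so that a
$10^5$-SNP desk panel carries useful information about $w$; real-variant
slopes are shallower but sit on panels hundreds of times larger). Causal
effects are sparse, drawn with variance
$\propto [q(1-q)]^{\alpha}$ at $q = \max(T, p_{\mathrm{mix}})$, and rescaled
by one constant so the genetic variance equals $h^2$ exactly — the
prefactor of the variance law is deliberately not a free parameter.
Summary statistics come either from the direct unlinked-SNP form
$z = \sqrt{N}\beta\sqrt{2p(1-p)} + e$, $e \sim N(0,1)$, or from explicit
binomial genotypes with marginal least-squares association (a small-scale
cross-check of the direct form).

What the simulator does *not* emulate: linkage disequilibrium between
SNPs, real functional annotation structure, case/control traits, or any
forward-in-time evolutionary dynamics. Passing tests therefore certify the
estimation machinery against its own generative assumptions, not the
behaviour of the full S-LDSC stack on real, LD-structured genomes (see
*Limitations*).

## Study sizes and the desk-scale design

The end-to-end study (`run_simulation_study()`) mirrors a biobank-scale
estimator-validation experiment at desk scale. The biobank regime it
emulates used millions of common SNPs and per-trait $N h^2 \approx
1.7\times10^5$; what governs the moment-fit's bias is the per-bin
noise-to-signal ratio of the bin-variance estimates, roughly
$\sqrt{2/n_k}\, M /(N h^2) \approx 0.22$ in that regime. The package's
defaults reproduce that ratio with $M = 20{,}000$ common SNPs,
$N = 20{,}000$, $h^2 = 0.5$, 25 traits and 5,000 causal SNPs per trait
(the causal fraction is higher than in the emulated study so that
architecture-sampling noise stays subordinate to estimation noise). The
oracle-regime analyses use 5,000 common SNPs with 400 causal per trait
across 20 replicates. Naively scaling $N h^2$ down in proportion to $M$
instead would multiply the per-bin noise-to-signal ratio by more than ten
and leave the weight essentially unidentified per replicate.

In this noisy regime the weight estimate is approximately unbiased near
$w = 0.95$, falls at or below the truth at a true weight of 1, and the
exponent is biased modestly downward. In the oracle regime (true effects,
causal-only bins, per-SNP mixture frequencies thresholded at the
generative plateau $T$) both parameters are recovered without material
bias; the acceptance suite checks both patterns. One caveat: with unlinked
SNPs and a fixed regression intercept the per-bin errors are independent,
and at a true weight of exactly 0 the estimate comes out essentially
unbiased rather than noticeably pulled upward. LD-structured data behave
differently there — a free LD-score-regression intercept and LD spread the
heritability regression's errors across MAF bins in a correlated,
European-MAF-shaped way that an African-weighted mixture can partially
absorb — so the conservative pull away from $w = 0$ seen in LD-aware
pipelines is *not* reproduced by the unlinked stage. This is the main
known fidelity gap of the simplified design, and the corresponding
acceptance check is expected to flag it.

## Design decisions

- The LD-score regression stage is deliberately minimal: unweighted OLS,
  indicator annotations only, no reference-panel LD estimation, no
  regression-SNP filtering. In unlinked simulations the usual
  heteroskedasticity weights are near-constant and the LD score of an
  indicator annotation is the indicator itself. Hooks accept per-SNP
  weights and externally computed bin-variance tables
  (`read_bin_table()`), so estimates from a full stratified-LD-score
  pipeline can be ingested unchanged.
- The regression intercept is free by default but must be fixed at 1 when
  the annotations exactly partition the regression SNPs (the two are then
  collinear, which the fitter reports as an error naming the columns); the
  pipeline runner fixes it at 1, which is exact for unconfounded
  direct-mode statistics.
- Inference-side thresholding of per-SNP mixture frequencies at the
  plateau `T` is available but off by default: the main inference model is
  intentionally different from the generative model, and the thresholded
  variant exists to demonstrate that the estimator becomes unbiased when
  the inference model matches.
- Natural logs are used for $\log p_{\mathrm{mix}}$ (the base only rescales
  $\gamma$); standardising the predictor to unit variance
  (`standardized_gamma()`) leaves the likelihood and $\hat w$ unchanged
  while making the slope's magnitude comparable across weights.
- Random-effects combination uses DerSimonian–Laird with the between-trait
  variance floored at zero, alongside the fixed-effects estimate and
  Cochran's Q.

## Limitations

- No LD: the simplified heritability-regression stage cannot reproduce
  bias components that arise from LD between SNPs or from interactions
  with a full annotation model; the realistic-regime acceptance checks
  characterise the unlinked approximation, not S-LDSC itself.
- Two ancestries only, continental resolution, no allele-age information.
- Infinitesimal effect model within the causal set; no point-mass mixture
  of effect sizes.
- The logistic-model analyses require consequence labels as input; calling
  variant consequences is upstream of this package.
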