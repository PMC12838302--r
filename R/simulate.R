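# Generative simulator: joint two-population MAF panels, non-synonymous
# labels, sparse MAF-dependent causal effects, and GWAS summary statistics.

#' Generative configuration for the simulation study
#'
#' Bundles and validates the parameters of the generative model: panel and
#' GWAS sizes, heritability, the generative mixture weight and MAF-dependence
#' exponent, the low-MAF plateau threshold `T` below which per-allele effect
#' variance stops growing, causal SNP count, and the two Balding-Nichols
#' drift parameters that shape the joint African/European frequency spectrum.
#'
#' Defaults are the package's desk-scale emulation of a biobank-scale
#' simulation study: 20,000 common SNPs, 25 traits, N = 20,000, h2 = 0.5,
#' 5,000 causal SNPs, plateau T = 0.005, and drift parameters giving
#' corr(pA, pE) around 0.8 with a bottleneck-distorted European spectrum.
#'
#' @param n_snps Number of SNPs in the analysis panel.
#' @param n_traits Number of traits simulated per replicate.
#' @param gwas_n GWAS sample size N.
#' @param h2 Trait heritability in (0, 1); phenotypic variance is 1.
#' @param w_true Generative mixture weight in `[0, 1]`.
#' @param alpha_true Generative MAF-dependence exponent.
#' @param plateau_T Plateau threshold `T` in (0, 0.5): per-allele effect
#'   variance is evaluated at `max(T, pmix)`.
#' @param n_causal Number of causal SNPs per trait (`<= n_snps`).
#' @param drift_afr,drift_eur Fst-like drift parameters in (0, 1) for the
#'   African and European frequency draws.
#' @param seed Integer master seed.
#' @return A validated list of class `"generative_config"`.
#' @export
generative_config <- function(n_snps = 20000, n_traits = 25, gwas_n = 20000,
                              h2 = 0.5, w_true = 0.95, alpha_true = -0.38,
                              plateau_T = 0.005, n_causal = 5000,
                              drift_afr = 0.01, drift_eur = 0.12,
                              seed = 1L) {
  assert_scalar_number(n_snps, "n_snps", lower = 1)
  assert_scalar_number(n_traits, "n_traits", lower = 1)
  assert_scalar_number(gwas_n, "gwas_n", lower = 2)
  assert_scalar_number(h2, "h2")
  if (h2 <= 0 || h2 >= 1) abort("`h2` must be in (0, 1).")
  assert_scalar_number(w_true, "w_true", lower = 0, upper = 1)
  assert_scalar_number(alpha_true, "alpha_true")
  assert_scalar_number(plateau_T, "plateau_T")
  if (plateau_T <= 0 || plateau_T >= 0.5) abort("`plateau_T` must be in (0, 0.5).")
  assert_scalar_number(n_causal, "n_causal", lower = 1)
  if (n_causal > n_snps) abort("`n_causal` must not exceed `n_snps`.")
  for (nm in c("drift_afr", "drift_eur")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v <= 0 || v >= 1) abort(sprintf("`%s` must be in (0, 1).", nm))
  }
  assert_scalar_number(seed, "seed")
  structure(list(n_snps = as.integer(n_snps), n_traits = as.integer(n_traits),
                 gwas_n = as.integer(gwas_n), h2 = h2, w_true = w_true,
                 alpha_true = alpha_true, plateau_T = plateau_T,
                 n_causal = as.integer(n_causal), drift_afr = drift_afr,
                 drift_eur = drift_eur, seed = as.integer(seed)),
            class = "generative_config")
}

#' @export
print.generative_config <- function(x, ...) {
  cat("<generative_config>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Simulate a joint African/European MAF panel
#'
#' Draws an ancestral derived-allele frequency `q0` from a density
#' proportional to `1/q` truncated to `[q_min, 1 - q_min]` (the neutral
#' infinite-sites shape), then draws population frequencies from a
#' Balding-Nichols Beta distribution with mean `q0` and variance
#' `q0 (1 - q0) F`, with `F = drift_afr` and `drift_eur` respectively.
#' The much larger European drift emulates the out-of-Africa bottleneck:
#' the European spectrum is distorted (an excess of variants drifted to
#' rarity or lost) while the African spectrum stays close to the ancestral
#' one. Frequencies are clipped to `[1e-6, 1 - 1e-6]` and folded per
#' ancestry, so minor alleles can differ between ancestries.
#'
#' @param n_snps Number of SNPs.
#' @param drift_afr,drift_eur Drift parameters in (0, 1).
#' @param q_min Lower truncation of the ancestral spectrum.
#' @param seed Optional integer seed.
#' @return A tibble (SNP panel) with columns `snp_id`, `pos_index`,
#'   `freq_afr`, `freq_eur`, `maf_afr`, `maf_eur`.
#' @export
#' @examples
#' panel <- simulate_maf_panel(1000, seed = 1)
#' cor(panel$maf_afr, panel$maf_eur)
simulate_maf_panel <- function(n_snps, drift_afr = 0.01, drift_eur = 0.12,
                               q_min = 5e-4, seed = NULL) {
  assert_scalar_number(n_snps, "n_snps", lower = 1)
  for (nm in c("drift_afr", "drift_eur")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v <= 0 || v >= 1) abort(sprintf("`%s` must be in (0, 1).", nm))
  }
  n_snps <- as.integer(n_snps)
  with_opt_seed(seed, {
    q_max <- 1 - q_min
    # inverse CDF of the truncated 1/q density
    q0 <- q_min * (q_max / q_min)^runif(n_snps)
    freq_afr <- rbn_freq(q0, drift_afr)
    freq_eur <- rbn_freq(q0, drift_eur)
    tibble(
      snp_id = sprintf("snp%07d", seq_len(n_snps)),
      pos_index = seq_len(n_snps),
      freq_afr = freq_afr,
      freq_eur = freq_eur,
      maf_afr = pmin(freq_afr, 1 - freq_afr),
      maf_eur = pmin(freq_eur, 1 - freq_eur)
    )
  })
}

# Balding-Nichols draw: Beta with mean q0 and variance q0 (1-q0) F,
# clipped away from the boundary so folded MAFs stay in (0, 0.5].
rbn_freq <- function(q0, f, clip = 1e-6) {
  shape_scale <- (1 - f) / f
  p <- rbeta(length(q0), q0 * shape_scale, (1 - q0) * shape_scale)
  pmin(pmax(p, clip), 1 - clip)
}

#' Simulate non-synonymous labels under the logistic mixture model
#'
#' Each SNP's label is Bernoulli with
#' `logit P(Y = 1) = mu + gamma * log(pmix)`, where `pmix` is computed from
#' floored MAFs (`pA`, `pE` below `maf_floor` are set to `maf_floor`).
#' A negative `gamma` makes rarer variants (in the mixture frequency) more
#' likely to be non-synonymous, the signature of negative selection.
#'
#' @param panel SNP panel tibble with `maf_afr`, `maf_eur`.
#' @param w Mixture weight in `[0, 1]` (generation requires a valid
#'   frequency).
#' @param gamma Slope on `log(pmix)`.
#' @param mu Intercept on the logit scale.
#' @param maf_floor MAF floor applied to both ancestries, default 0.002.
#' @param seed Optional integer seed.
#' @return The panel with a binary `nonsyn` column added.
#' @export
label_nonsynonymous <- function(panel, w, gamma, mu, maf_floor = 0.002,
                                seed = NULL) {
  assert_columns(panel, c("maf_afr", "maf_eur"), "`panel`")
  assert_scalar_number(w, "w", lower = 0, upper = 1)
  assert_scalar_number(gamma, "gamma")
  assert_scalar_number(mu, "mu")
  if (maf_floor <= 0) abort("`maf_floor` must be positive.")
  pmix <- compute_pmix(floor_maf(panel$maf_afr, maf_floor),
                       floor_maf(panel$maf_eur, maf_floor), w)
  prob <- plogis(mu + gamma * log(pmix))
  with_opt_seed(seed, {
    dplyr::mutate(panel, nonsyn = rbinom(dplyr::n(), 1L, prob))
  })
}

#' Simulate sparse MAF-dependent causal effects
#'
#' Chooses `n_causal` SNPs uniformly at random and draws their per-allele
#' effects from `Normal(0, c * [q (1 - q)]^alpha_true)` with
#' `q = max(plateau_T, pmix)` and `pmix = w_true * pA + (1 - w_true) * pE`.
#' All effects are then rescaled by a single constant so the genetic variance
#' `sum(2 * freq_eur * (1 - freq_eur) * beta^2)` equals `h2` exactly
#' (phenotypic variance normalised to 1); the prefactor of the variance law
#' is therefore irrelevant and is not a free parameter.
#'
#' @param panel SNP panel tibble.
#' @param config A [generative_config()].
#' @param seed Optional integer seed (defaults to fresh draws from the
#'   current RNG stream).
#' @return The panel with a `beta` column (non-zero for exactly
#'   `n_causal` SNPs).
#' @export
simulate_causal_effects <- function(panel, config, seed = NULL) {
  stopifnot(inherits(config, "generative_config"))
  assert_columns(panel, c("maf_afr", "maf_eur", "freq_eur"), "`panel`")
  if (config$n_causal > nrow(panel)) {
    abort("`n_causal` exceeds the number of SNPs in `panel`.")
  }
  pmix <- compute_pmix(panel$maf_afr, panel$maf_eur, config$w_true)
  if (diff(range(pmix)) == 0) {
    abort("All pmix values collapse to a single point; effect variance is degenerate.")
  }
  q <- pmax(config$plateau_T, pmix)
  with_opt_seed(seed, {
    idx <- sample.int(nrow(panel), config$n_causal)
    beta <- numeric(nrow(panel))
    beta[idx] <- rnorm(config$n_causal, 0, sqrt((q[idx] * (1 - q[idx]))^config$alpha_true))
    gvar <- sum(2 * panel$freq_eur * (1 - panel$freq_eur) * beta^2)
    beta <- beta * sqrt(config$h2 / gvar)
    dplyr::mutate(panel, beta = beta)
  })
}

#' Simulate GWAS summary statistics directly (unlinked SNPs)
#'
#' Genotype-free equivalent of an explicit GWAS for unlinked SNPs: per SNP,
#' `z = sqrt(N) * beta * sqrt(2 p (1 - p)) + e` with `e ~ Normal(0, 1)` and
#' `p = freq_eur` (the unfolded GWAS-population frequency). Null SNPs have
#' `E[chi2] = 1`; a causal SNP has `E[chi2] = 1 + N * 2 p (1 - p) * beta^2`.
#'
#' @param panel SNP panel with a `beta` column ([simulate_causal_effects()]).
#' @param gwas_n GWAS sample size N.
#' @param seed Optional integer seed.
#' @return A tibble of summary statistics: `snp_id`, `n`, `z`, `chi2`.
#' @export
simulate_sumstats_direct <- function(panel, gwas_n, seed = NULL) {
  assert_columns(panel, c("snp_id", "freq_eur", "beta"), "`panel`")
  assert_scalar_number(gwas_n, "gwas_n", lower = 1)
  p <- panel$freq_eur
  ncp <- sqrt(gwas_n) * panel$beta * sqrt(2 * p * (1 - p))
  with_opt_seed(seed, {
    z <- ncp + rnorm(nrow(panel))
    tibble(snp_id = panel$snp_id, n = as.integer(gwas_n), z = z, chi2 = z^2)
  })
}

#' Simulate GWAS summary statistics from explicit genotypes
#'
#' Validation-scale mode: genotypes are drawn `Binomial(2, freq_eur)`
#' independently per SNP, the phenotype is `Y = X beta + epsilon` with
#' residual variance `1 - h2` (the genetic variance set by the effect
#' rescaling), and per-SNP marginal least-squares association yields the
#' `z`-scores. Intended for small panels as an independent cross-check of
#' [simulate_sumstats_direct()].
#'
#' @param panel SNP panel with a `beta` column.
#' @param gwas_n GWAS sample size N.
#' @param seed Optional integer seed.
#' @param max_cells Refuse genotype matrices with more than this many
#'   entries (default 5e7).
#' @return A tibble of summary statistics: `snp_id`, `n`, `z`, `chi2`.
#' @export
simulate_genotypes_explicit <- function(panel, gwas_n, seed = NULL,
                                        max_cells = 5e7) {
  assert_columns(panel, c("snp_id", "freq_eur", "beta"), "`panel`")
  assert_scalar_number(gwas_n, "gwas_n", lower = 3)
  m <- nrow(panel)
  if (as.double(gwas_n) * m > max_cells) {
    abort(sprintf(
      "Genotype matrix would have %.3g cells (cap %.3g); use simulate_sumstats_direct().",
      as.double(gwas_n) * m, max_cells))
  }
  n <- as.integer(gwas_n)
  gvar <- sum(2 * panel$freq_eur * (1 - panel$freq_eur) * panel$beta^2)
  resid_sd <- sqrt(max(0, 1 - gvar))
  with_opt_seed(seed, {
    X <- matrix(rbinom(n * m, 2L, rep(panel$freq_eur, each = n)), nrow = n)
    y <- drop(X %*% panel$beta) + rnorm(n, 0, resid_sd)
    r <- suppressWarnings(as.vector(cor(X, y)))
    r[is.na(r)] <- 0  # monomorphic draw
    z <- sqrt(n - 2) * r / sqrt(pmax(1 - r^2, .Machine$double.eps))
    tibble(snp_id = panel$snp_id, n = n, z = z, chi2 = z^2)
  })
}
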