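# Shared fixtures, all generated in code.

# Small correlated two-population panel.
small_panel <- function(n = 2000, seed = 101, drift_afr = 0.01,
                        drift_eur = 0.12) {
  simulate_maf_panel(n, drift_afr = drift_afr, drift_eur = drift_eur,
                     seed = seed)
}

# A bin-assigned common-European panel plus its scheme, as used for fitting.
binned_fixture <- function(n = 4000, seed = 202, n_common_bins = 5) {
  panel <- withr::with_seed(seed, alphamix:::simulate_common_panel(n, 0.01, 0.12))
  scheme <- build_binning_scheme(panel, preset = NULL,
                                 n_common_bins = n_common_bins)
  list(panel = assign_bins(panel, scheme, eur_common_only = TRUE),
       scheme = scheme)
}

# Noiseless bin-variance tables generated exactly from the mixture
# effect-variance model at (w, alpha, sigma2 per trait).
noiseless_tables <- function(bins, w, alpha, sigma2) {
  purrr::map_dfr(seq_along(sigma2), function(t) {
    tibble::tibble(
      trait = sprintf("trait%02d", t),
      bin = bins$bin, n_k = bins$n_k,
      mean_pA = bins$mean_pA, mean_pE = bins$mean_pE,
      beta2_hat = predict_bin_variance(bins, w, alpha, sigma2[t]))
  })
}

# Random bin-variance table (possibly with negative entries).
random_table <- function(n_bins = 25, seed = 7, trait = "trait01") {
  withr::with_seed(seed, {
    pA <- runif(n_bins, 0.01, 0.5)
    pE <- runif(n_bins, 0.05, 0.5)
    tibble::tibble(trait = trait, bin = sprintf("b%02d", seq_len(n_bins)),
                   n_k = sample(50:500, n_bins, replace = TRUE),
                   mean_pA = pA, mean_pE = pE,
                   beta2_hat = rnorm(n_bins, 1e-5, 8e-6))
  })
}

# Bin summaries of a deterministic small grid (used where the exact bin
# geometry matters more than realism).
toy_bins <- function(n_bins = 12) {
  g <- expand.grid(pA = seq(0.05, 0.45, length.out = max(3, n_bins %/% 4)),
                   pE = seq(0.08, 0.48, length.out = 4))[seq_len(n_bins), ]
  tibble::tibble(bin = sprintf("b%02d", seq_len(n_bins)),
                 n_k = 100L + 10L * seq_len(n_bins),
                 mean_pA = g$pA, mean_pE = g$pE)
}
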