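# Simplified stratified LD-score regression and bin-wise variance stage.

test_that("regression on exact expected chi-square recovers tau exactly", {
  withr::local_seed(3)
  n_snp <- 3000
  annot <- matrix(0, n_snp, 3, dimnames = list(NULL, c("a", "b", "c")))
  idx <- sample(0:3, n_snp, replace = TRUE)  # 0 leaves some SNPs unannotated
  annot[cbind(which(idx > 0), idx[idx > 0])] <- 1
  tau <- c(a = 2e-6, b = 8e-6, c = 4e-6)
  n <- 5e4
  chi2 <- 1 + n * drop(annot %*% tau)  # exact expectations, no noise
  fit <- fit_stratified_ldsc(tibble::tibble(chi2 = chi2), annot, n)
  expect_equal(unname(fit$tau), unname(tau), tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  # same answer with the intercept fixed at 1
  fit0 <- fit_stratified_ldsc(tibble::tibble(chi2 = chi2), annot, n,
                              free_intercept = FALSE)
  expect_equal(unname(fit0$tau), unname(tau), tolerance = 1e-8)
})

test_that("null GWAS gives near-zero tau and unit intercept", {
  withr::local_seed(4)
  n_snp <- 20000
  annot <- matrix(0, n_snp, 2, dimnames = list(NULL, c("a", "b")))
  idx <- sample(0:2, n_snp, replace = TRUE)
  annot[cbind(which(idx > 0), idx[idx > 0])] <- 1
  chi2 <- rnorm(n_snp)^2
  fit <- fit_stratified_ldsc(tibble::tibble(chi2 = chi2), annot, n = 1e4)
  expect_equal(fit$intercept, 1, tolerance = 0.05)
  expect_equal(unname(fit$tau) * 1e4, c(0, 0), tolerance = 0.05)
})

test_that("collinear annotations are reported by name", {
  annot <- cbind(a = rep(1, 100), b = rep(1, 100))
  expect_error(
    fit_stratified_ldsc(tibble::tibble(chi2 = rep(1, 100)), annot, 1000),
    "collinear.*b")
})

test_that("per-allele conversion divides by heterozygosity", {
  annot <- cbind(a = c(1, 0), b = c(0, 1))
  tau <- c(a = 1.8e-6, b = 0)
  expect_equal(per_allele_variance(tau, annot, c(0.1, 0.5)),
               c(1.8e-6 / 0.18, 0))
  expect_equal(per_allele_variance(c(a = 0, b = 0), annot, c(0.1, 0.2)),
               c(0, 0))
  expect_error(per_allele_variance(tau, annot, c(0, 0.2)), "0, 0.5")
})

test_that("bin means average per-allele variances and keep negatives", {
  fx <- binned_fixture(2000)
  beta2 <- rep(3e-6, nrow(fx$panel))
  tab <- suppressWarnings(bin_mean_variance(fx$panel, beta2))
  expect_true(all(tab$beta2_hat == 3e-6))
  expect_equal(sum(tab$n_k), nrow(fx$panel))
  # two SNPs in a bin average, negatives retained
  two <- fx$panel[1:2, ]
  two$bin <- factor("onebin", levels = "onebin")
  tab2 <- bin_mean_variance(two, c(1e-6, 3e-6))
  expect_equal(tab2$beta2_hat, 2e-6)
  tab3 <- bin_mean_variance(two, c(-5e-6, 1e-6))
  expect_equal(tab3$beta2_hat, -2e-6)
})

test_that("oracle tables: causal restriction, scaling, determinism", {
  fx <- binned_fixture(3000)
  cfg <- generative_config(n_snps = 3000, n_causal = 1500, seed = 2)
  panel <- simulate_causal_effects(fx$panel, cfg, seed = 8)
  t_all <- oracle_bin_variance(panel)
  t_causal <- oracle_bin_variance(panel, causal_only = TRUE)
  expect_lt(sum(t_causal$n_k), sum(t_all$n_k))
  expect_identical(oracle_bin_variance(panel), t_all)
  # causal fraction f with causal-only variance v: all-SNP mean ~ f * v
  join <- dplyr::inner_join(t_all, t_causal, by = "bin",
                            suffix = c("_all", "_c"))
  f <- join$n_k_c / join$n_k_all
  big <- join$n_k_all > 100
  expect_equal(mean(join$beta2_hat_all[big] /
                    (f[big] * join$beta2_hat_c[big])), 1, tolerance = 0.05)
  # single causal SNP alone in a bin
  solo <- panel[1, ]
  solo$beta <- 0.01
  solo$bin <- factor("solo", levels = "solo")
  expect_equal(oracle_bin_variance(solo, causal_only = TRUE)$beta2_hat, 1e-4)
  # scaling beta by c scales every bin mean by c^2
  doubled <- oracle_bin_variance(dplyr::mutate(panel, beta = 2 * beta))
  expect_equal(doubled$beta2_hat, 4 * t_all$beta2_hat, tolerance = 1e-12)
})

test_that("oracle and LDSC modes agree on a noiseless design", {
  fx <- binned_fixture(3000)
  annot <- bin_annotations(fx$panel)
  tau <- setNames(seq_len(ncol(annot)) * 1e-6, colnames(annot))
  h2i <- drop(annot %*% tau)
  het <- 2 * fx$panel$maf_eur * (1 - fx$panel$maf_eur)
  panel <- dplyr::mutate(fx$panel, beta = sqrt(h2i / het))
  n <- 5e4
  chi2 <- 1 + n * h2i  # plug in exact chi-square expectations
  fit <- fit_stratified_ldsc(tibble::tibble(chi2 = chi2), annot, n,
                             free_intercept = FALSE)
  beta2 <- per_allele_variance(fit, annot, fx$panel$maf_eur)
  ldsc_tab <- suppressWarnings(bin_mean_variance(fx$panel, beta2))
  oracle_tab <- oracle_bin_variance(panel)
  expect_equal(ldsc_tab$beta2_hat, oracle_tab$beta2_hat, tolerance = 1e-8)
})

test_that("cross-trait normalisation and random-effects combination", {
  tab1 <- random_table(20, seed = 11, trait = "t1")
  expect_error(normalize_and_meta(tab1), "two traits")
  # identical traits: combined value is the common (normalised) value,
  # between-trait variance 0; the normalised global mean is exactly 1
  tabs <- dplyr::bind_rows(tab1, dplyr::mutate(tab1, trait = "t2"))
  meta <- normalize_and_meta(tabs)
  expect_true(all(meta$tau2 == 0))
  norm1 <- sum(tab1$n_k * tab1$beta2_hat) / sum(tab1$n_k)
  expect_equal(meta$estimate[match(tab1$bin, meta$bin)],
               tab1$beta2_hat / norm1)
  expect_equal(sum(tab1$n_k * meta$estimate[match(tab1$bin, meta$bin)]) /
                 sum(tab1$n_k), 1, tolerance = 1e-12)
  # a trait with a non-positive normaliser is dropped with a warning
  bad <- dplyr::mutate(tab1, trait = "t3", beta2_hat = -abs(beta2_hat))
  expect_warning(normalize_and_meta(dplyr::bind_rows(tabs, bad)),
                 "non-positive")
})

test_that("meta-analysis matches hand-computed fixed and DL estimators", {
  # symmetric average
  fe <- meta_analyze(c(1, 3), c(1, 1))
  expect_equal(fe$estimate[fe$method == "fixed"], 2)
  # no heterogeneity when estimates coincide
  same <- meta_analyze(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(same$q[1], 0)
  expect_equal(same$estimate, c(2, 2))
  # hand-worked DerSimonian-Laird on a 3-trait table
  y <- c(0.2, 0.6, 1.1); s <- c(0.1, 0.2, 0.3)
  wts <- 1 / s^2
  ybar <- sum(wts * y) / sum(wts)
  q <- sum(wts * (y - ybar)^2)
  tau2 <- max(0, (q - 2) / (sum(wts) - sum(wts^2) / sum(wts)))
  wre <- 1 / (s^2 + tau2)
  expect_re <- sum(wre * y) / sum(wre)
  got <- meta_analyze(y, s)
  expect_equal(got$estimate[got$method == "random"], expect_re,
               tolerance = 1e-10)
  expect_equal(got$tau2[1], tau2, tolerance = 1e-10)
  # non-finite SEs excluded with a warning
  expect_warning(meta_analyze(c(1, 2, 3), c(1, NA, 1)), "Excluding")
})

test_that("greedy trait selection follows the stated filters and order", {
  traits <- tibble::tibble(trait = c("a", "b", "c", "d", "e"),
                           h2_z = c(10, 12, 8, 3, 9),
                           nh2 = c(9e4, 7e4, 5e4, 8e4, 3e4))
  # d fails the z filter, e passes; all-correlated: only the top-nh2 trait
  rg_hi <- matrix(1, 5, 5, dimnames = list(traits$trait, traits$trait))
  expect_equal(select_independent_traits(traits, rg_hi), "a")
  # all-independent: every passing trait, in descending N*h2 order
  rg_lo <- diag(5); dimnames(rg_lo) <- list(traits$trait, traits$trait)
  expect_equal(select_independent_traits(traits, rg_lo),
               c("a", "b", "c", "e"))
  # brute-force greedy trace on a structured instance
  rg <- rg_lo
  rg["a", "b"] <- rg["b", "a"] <- 0.5  # b conflicts with a
  rg["c", "e"] <- rg["e", "c"] <- 0.25 # e conflicts with c
  expect_equal(select_independent_traits(traits, rg), c("a", "c"))
  expect_error(select_independent_traits(traits, rg * 2), "unit diagonal")
})
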