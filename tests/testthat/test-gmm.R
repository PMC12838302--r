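# GMM estimation of (w, alpha, sigma_g^2) from bin-variance tables.

test_that("predicted bin variance evaluates the closed form", {
  bins <- tibble::tibble(mean_pA = 0.5, mean_pE = 0.5)
  expect_equal(predict_bin_variance(bins, w = 0.3, alpha = -0.38, sigma2 = 2),
               0.25^(-0.38))
  # no MAF dependence: sigma2 / 2 everywhere
  bins2 <- toy_bins(8)
  expect_equal(predict_bin_variance(bins2, 0.7, 0, 3e-5),
               rep(1.5e-5, 8))
  # mixture symmetry: swap ancestries and w -> 1 - w
  swapped <- dplyr::rename(bins2, mean_pA = mean_pE, mean_pE = mean_pA)
  expect_equal(predict_bin_variance(bins2, 0.3, -0.5, 1e-4),
               predict_bin_variance(swapped, 0.7, -0.5, 1e-4))
})

test_that("analytic sigma matches closed forms and brute-force grids", {
  one <- tibble::tibble(trait = "t", bin = "b1", n_k = 10L,
                        mean_pA = 0.1, mean_pE = 0.2, beta2_hat = 4e-5)
  g1 <- (clamp_pmix(compute_pmix(0.1, 0.2, 0.6)) *
           (1 - clamp_pmix(compute_pmix(0.1, 0.2, 0.6))))^(-0.4)
  expect_equal(analytic_sigma(one, 0.6, -0.4), 2 * 4e-5 / g1)
  # alpha = 0 reduces to the count-weighted mean rule
  tab <- random_table(15, seed = 5)
  expect_equal(analytic_sigma(tab, 0.5, 0),
               2 * sum(tab$n_k * tab$beta2_hat) / sum(tab$n_k))
  # brute-force grid oracle on random tables
  for (s in 1:20) {
    tabr <- random_table(12, seed = 300 + s)
    w <- runif(1, -0.3, 1.3); a <- runif(1, -1.2, 1.2)
    sig <- analytic_sigma(tabr, w, a)
    span <- max(abs(sig), 1e-4) * 3
    grid <- seq(-span, span, length.out = 1e5)
    loss_of <- function(s2) gmm_loss(tabr, w, a, s2)
    p <- clamp_pmix(compute_pmix(tabr$mean_pA, tabr$mean_pE, w))
    g <- (p * (1 - p))^a
    losses <- vapply(grid, function(s2)
      sum(tabr$n_k * (s2 / 2 * g - tabr$beta2_hat)^2), numeric(1))
    best <- grid[which.min(losses)]
    expect_equal(sig, best, tolerance = max(1e-6, 2 * span / 1e5 / abs(sig)))
    # optimality against the perturbed-sigma loss
    expect_lte(loss_of(sig), loss_of(sig * 1.01) + 1e-18)
    expect_lte(loss_of(sig), loss_of(sig * 0.99) + 1e-18)
  }
})

test_that("the GMM loss is zero at truth and linear in bin counts", {
  bins <- toy_bins(10)
  tabs <- noiseless_tables(bins, w = 0.8, alpha = -0.5, sigma2 = c(2e-5, 5e-5))
  expect_equal(gmm_loss(tabs, 0.8, -0.5, c(trait01 = 2e-5, trait02 = 5e-5)), 0)
  noisy <- dplyr::mutate(tabs, beta2_hat = beta2_hat * 1.2)
  l1 <- gmm_loss(noisy, 0.8, -0.5, c(trait01 = 2e-5, trait02 = 5e-5))
  doubled <- dplyr::mutate(noisy, n_k = 2L * n_k)
  expect_equal(gmm_loss(doubled, 0.8, -0.5, c(trait01 = 2e-5, trait02 = 5e-5)),
               2 * l1)
  # mismatched bin sets across traits are rejected in bin-mean form
  broken <- dplyr::filter(tabs, !(trait == "trait02" & bin == "b01"))
  expect_error(gmm_loss(broken, 0.8, -0.5, c(2e-5, 5e-5)), "Bin sets differ")
})

test_that("noiseless tables are exactly identifiable", {
  fx <- binned_fixture(6000, seed = 404, n_common_bins = 5)
  bins <- bin_summaries(fx$panel)
  for (truth in list(c(0.3, -0.8), c(0.75, -0.38), c(1.0, 0.4))) {
    tabs <- noiseless_tables(bins, truth[1], truth[2], c(3e-5, 6e-5))
    fit <- fit_alphamix(tabs, nested = FALSE, seed = 1)
    expect_equal(fit$w, truth[1], tolerance = 1e-3)
    expect_equal(fit$alpha, truth[2], tolerance = 1e-3)
    expect_equal(fit$sigma2$sigma_g2, c(3e-5, 6e-5), tolerance = 1e-3)
  }
})

test_that("fitted scaled MSE is nested below the fixed-parameter models", {
  tabs <- dplyr::bind_rows(random_table(20, seed = 21, trait = "t1"),
                           random_table(20, seed = 22, trait = "t2"))
  fit <- fit_alphamix(tabs, seed = 3)
  comp <- fit$comparisons
  expect_equal(comp$scaled_mse[comp$model == "null"], 1, tolerance = 1e-12)
  expect_lte(fit$scaled_mse, comp$scaled_mse[comp$model == "w0"] + 1e-12)
  expect_lte(fit$scaled_mse, comp$scaled_mse[comp$model == "w1"] + 1e-12)
  expect_lte(fit$scaled_mse, 1 + 1e-12)
  expect_gte(fit$loss, 0)
})

test_that("scale equivariance and ancestry-swap symmetry of the fit", {
  fx <- binned_fixture(5000, seed = 505, n_common_bins = 5)
  bins <- bin_summaries(fx$panel)
  tabs <- noiseless_tables(bins, 0.7, -0.45, 4e-5)
  fit <- fit_alphamix(tabs, nested = FALSE, seed = 2)
  scaled <- dplyr::mutate(tabs, beta2_hat = 2 * beta2_hat)
  fit2 <- fit_alphamix(scaled, nested = FALSE, seed = 2)
  expect_equal(fit2$w, fit$w, tolerance = 1e-4)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-4)
  expect_equal(fit2$sigma2$sigma_g2, 2 * fit$sigma2$sigma_g2,
               tolerance = 1e-3)
  swapped <- dplyr::rename(tabs, mean_pA = mean_pE, mean_pE = mean_pA)
  fit3 <- fit_alphamix(swapped, nested = FALSE, seed = 2)
  expect_equal(fit3$w, 1 - fit$w, tolerance = 1e-3)
  expect_equal(fit3$alpha, fit$alpha, tolerance = 1e-3)
})

test_that("single-trait joint fit equals the per-trait fit, and identical
           tables give the joint answer for every trait", {
  tab <- random_table(18, seed = 31, trait = "t1")
  joint <- fit_alphamix(tab, nested = FALSE, seed = 4)
  per <- fit_alphamix_per_trait(tab, nested = FALSE, seed = 4)
  expect_equal(per$w, joint$w, tolerance = 1e-6)
  expect_equal(per$alpha, joint$alpha, tolerance = 1e-6)
  tabs <- dplyr::bind_rows(tab, dplyr::mutate(tab, trait = "t2"))
  joint2 <- fit_alphamix(tabs, nested = FALSE, seed = 4)
  per2 <- fit_alphamix_per_trait(tabs, nested = FALSE, seed = 4)
  expect_equal(per2$w, rep(joint2$w, 2), tolerance = 1e-4)
  expect_equal(per2$alpha, rep(joint2$alpha, 2), tolerance = 1e-4)
})

test_that("fixing w = 0 reduces to the single-ancestry exponent model", {
  tab <- random_table(20, seed = 41)
  fixed <- fit_alphamix(tab, fix_w = 0, nested = FALSE, seed = 5)
  prof <- profile_alpha_over_w(tab, w_grid = c(0, 0.5, 1))
  expect_equal(fixed$alpha, prof$alpha[prof$w == 0], tolerance = 1e-6)
  expect_equal(fixed$loss, prof$loss[prof$w == 0], tolerance = 1e-10)
})

test_that("the exponent-over-w profile is minimised at the global fit", {
  fx <- binned_fixture(5000, seed = 606, n_common_bins = 5)
  bins <- bin_summaries(fx$panel)
  tabs <- noiseless_tables(bins, 0.6, -0.4, 5e-5)
  fit <- fit_alphamix(tabs, nested = FALSE, seed = 6)
  prof <- profile_alpha_over_w(tabs, w_grid = sort(c(seq(-0.5, 1.5, 0.25),
                                                     fit$w)))
  expect_equal(prof$w[which.min(prof$loss)], fit$w)
  expect_true(all(prof$loss >= fit$loss - 1e-15))
})

test_that("tidy and glance methods summarise fits", {
  tab <- random_table(15, seed = 51)
  fit <- fit_alphamix(tab, nested = FALSE, seed = 7)
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("w", "alpha", "sigma_g2"))
  gl <- glance(fit)
  expect_equal(gl$w, fit$w)
  expect_equal(gl$n_traits, 1L)
})

test_that("block-jackknifed pipelines expose SEs and null tests", {
  # constant inputs: zero SE, p = 1 against the estimate itself
  const <- tibble::tibble(x = rep(2, 100), pos_index = 1:100)
  jk <- block_jackknife(const, function(d) c(m = mean(d$x)), n_blocks = 10,
                        null_values = c(m = 2))
  expect_equal(jk$se, 0)
  expect_equal(jk$p_value, 1)
  # jackknifing a small moment-fit pipeline end to end
  fx <- binned_fixture(2000, seed = 707, n_common_bins = 5)
  cfg <- generative_config(n_snps = 2000, n_causal = 800, seed = 8)
  panel <- simulate_causal_effects(fx$panel, cfg, seed = 9)
  stat <- function(d) {
    tab <- oracle_bin_variance(d)
    f <- fit_alphamix(tab, nested = FALSE, seed = 10,
                      control = de_control(pop_size = 15, n_gens = 20))
    c(w = f$w, alpha = f$alpha)
  }
  jk2 <- block_jackknife(panel, stat, n_blocks = 8,
                         null_values = c(w = 0, alpha = 0))
  expect_true(all(jk2$se > 0))
  expect_true(all(jk2$ci_lo < jk2$estimate & jk2$estimate < jk2$ci_hi))
})
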