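# Profile-likelihood logistic model for non-synonymous status.

nonsyn_fixture <- function(n = 20000, w = 0.9, gamma = -0.5, mu = -3,
                           seed = 71) {
  panel <- small_panel(n, seed = seed)
  label_nonsynonymous(panel, w, gamma, mu, seed = seed + 1)
}

test_that("IRLS logistic fit agrees with direct likelihood maximisation", {
  d <- nonsyn_fixture(500)
  x <- log(compute_pmix(floor_maf(d$maf_afr), floor_maf(d$maf_eur), 0.9))
  fit <- fit_logistic(d$nonsyn, x)
  # independent oracle: direct optimisation of the Bernoulli log-likelihood
  nll <- function(par) {
    eta <- par[1] + par[2] * x
    -sum(d$nonsyn * eta - log1p(exp(eta)))
  }
  oracle <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(fit$mu, oracle$par[1], tolerance = 1e-4)
  expect_equal(fit$gamma, oracle$par[2], tolerance = 1e-4)
  expect_equal(fit$loglik, -oracle$value, tolerance = 1e-6)
  expect_lte(fit$loglik, 0)
  expect_true(fit$converged)
})

test_that("degenerate logistic inputs are rejected", {
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic(y, rep(1, 20)), "Constant predictor")
  expect_error(fit_logistic(rep(1, 20), rnorm(20)), "Both label classes")
  # complete separation
  x <- c(rep(-1, 10), rep(1, 10))
  expect_error(fit_logistic(c(rep(0, 10), rep(1, 10)), x), "separation")
})

test_that("null-slope generation yields a null fit", {
  d <- nonsyn_fixture(30000, gamma = 0, mu = -1.5, seed = 81)
  x <- log(floor_maf(d$maf_afr))
  fit <- fit_logistic(d$nonsyn, x)
  null <- fit_null_logistic(d$nonsyn)
  expect_equal(fit$gamma, 0, tolerance = 0.05)
  expect_equal(fit$mu, qlogis(mean(d$nonsyn)), tolerance = 0.2)
  expect_equal(mcfadden_r2(null, null), 0)
  expect_lt(mcfadden_r2(fit, null), 1e-3)
})

test_that("profile endpoints equal single-ancestry fits exactly", {
  d <- nonsyn_fixture(10000)
  for (w in c(0, 1)) {
    prof <- profile_loglik(d$nonsyn, d$maf_afr, d$maf_eur, w)
    x <- log(if (w == 1) floor_maf(d$maf_afr) else floor_maf(d$maf_eur))
    direct <- fit_logistic(d$nonsyn, x)
    expect_equal(prof$loglik, direct$loglik, tolerance = 1e-10)
    expect_equal(prof$gamma, direct$gamma, tolerance = 1e-8)
  }
  # pA == pE makes w unidentifiable: the profile is flat
  same <- dplyr::mutate(d, maf_eur = maf_afr)
  ll <- vapply(c(0, 0.3, 0.7, 1), function(w)
    profile_loglik(same$nonsyn, same$maf_afr, same$maf_eur, w)$loglik,
    numeric(1))
  expect_lt(diff(range(ll)), 1e-8)
})

test_that("profile maximisation dominates endpoints and matches a dense grid", {
  d <- nonsyn_fixture(20000)
  suppressWarnings(prof <- maximize_profile(d$nonsyn, d$maf_afr, d$maf_eur))
  ll0 <- profile_loglik(d$nonsyn, d$maf_afr, d$maf_eur, 0)$loglik
  ll1 <- profile_loglik(d$nonsyn, d$maf_afr, d$maf_eur, 1)$loglik
  expect_gte(prof$loglik_mle, max(ll0, ll1))
  # dense-grid oracle for the maximiser
  grid <- seq(-0.5, 1.5, length.out = 2001)
  ll <- vapply(grid, function(w)
    profile_loglik(d$nonsyn, d$maf_afr, d$maf_eur, w)$loglik, numeric(1))
  expect_lt(abs(prof$w_mle - grid[which.max(ll)]), 1e-3)
  # LRT machinery: p = 1 at the MLE, CI endpoints on the chi-square cutoff
  expect_equal(lrt_pvalue(prof, prof$w_mle), 1, tolerance = 1e-6)
  expect_true(all(prof$ci95[1] <= prof$w_mle & prof$w_mle <= prof$ci95[2]))
  for (end in prof$ci95) {
    if (end > -0.5 && end < 1.5) {
      ll_end <- profile_loglik(d$nonsyn, d$maf_afr, d$maf_eur, end)$loglik
      expect_equal(2 * (prof$loglik_mle - ll_end), qchisq(0.95, 1),
                   tolerance = 1e-3)
    }
  }
})

test_that("Vuong statistic has the stated conventions and sign", {
  d <- nonsyn_fixture(20000)
  xa <- log(floor_maf(d$maf_afr))
  xe <- log(floor_maf(d$maf_eur))
  fa <- fit_logistic(d$nonsyn, xa)
  fe <- fit_logistic(d$nonsyn, xe)
  same <- vuong_test(fa, fa)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # labels were generated mostly from African MAF (w = 0.9): A better -> positive
  v <- vuong_test(fa, fe)
  expect_gt(v$statistic, 0)
  expect_lt(v$p_value, 0.05)
  # shuffled predictor is a strictly worse model
  xs <- withr::with_seed(1, sample(xa))
  v2 <- vuong_test(fa, fit_logistic(d$nonsyn, xs))
  expect_gt(v2$statistic, 0)
})

test_that("relative log-likelihood gain ratios behave as ratios", {
  d <- nonsyn_fixture(20000)
  null <- fit_null_logistic(d$nonsyn)
  fa <- fit_logistic(d$nonsyn, log(floor_maf(d$maf_afr)))
  expect_equal(relative_ll_gain(fa, null, fa), 1)
  expect_equal(relative_ll_gain(null, null, fa), 0)
  # profiled mixture model dominates the fixed-weight reference
  suppressWarnings(prof <- maximize_profile(d$nonsyn, d$maf_afr, d$maf_eur))
  fit_mle <- profile_loglik(d$nonsyn, d$maf_afr, d$maf_eur, prof$w_mle)
  expect_gte(relative_ll_gain(fit_mle, null, fa), 1)
  expect_error(relative_ll_gain(fa, fa, null), "non-positive")
})

test_that("standardising the predictor rescales gamma but not the likelihood", {
  d <- nonsyn_fixture(20000)
  w_grid <- seq(0, 1, by = 0.25)
  std <- standardized_gamma(d$nonsyn, d$maf_afr, d$maf_eur, w_grid)
  expect_equal(std$gamma_std, std$gamma * std$sd_log_pmix)
  for (i in seq_along(w_grid)) {
    prof <- profile_loglik(d$nonsyn, d$maf_afr, d$maf_eur, w_grid[i])
    expect_equal(std$loglik[i], prof$loglik, tolerance = 1e-8)
  }
})

test_that("PNS tabulation gives binomial summaries and the selection gradient", {
  panel <- small_panel(60000, seed = 91)
  scheme <- build_binning_scheme(panel, preset = "display")
  zero <- pns_by_bins(dplyr::mutate(panel, nonsyn = 0L), scheme)
  expect_true(all(zero$pns == 0))
  d <- label_nonsynonymous(panel, w = 1, gamma = -0.8, mu = -1.5, seed = 92)
  tab <- pns_by_bins(d, scheme)
  expect_equal(tab$se, sqrt(tab$pns * (1 - tab$pns) / tab$n))
  # under w = 1 and negative gamma, PNS decreases with African MAF within
  # each European stratum (check well-populated strata)
  big <- dplyr::filter(tab, n > 1000)
  trend <- big |>
    dplyr::group_by(bin_eur) |>
    dplyr::filter(dplyr::n() >= 4) |>
    dplyr::summarise(drop = cor(as.integer(bin_afr), pns), .groups = "drop")
  expect_true(all(trend$drop < 0))
})

test_that("jackknife comparison is null on identical inputs and matches
           the closed-form SE of a mean", {
  d <- nonsyn_fixture(5000)
  da <- tibble::tibble(label = d$nonsyn,
                       log_maf = log(floor_maf(d$maf_afr)),
                       pos_index = d$pos_index)
  same <- jackknife_compare(da, da, n_blocks = 20)
  expect_equal(same$estimate, c(0, 0))
  expect_equal(same$p_value, c(1, 1))
  # block jackknife of a sample mean vs s / sqrt(n)
  x <- withr::with_seed(6, rnorm(2000))
  jk <- block_jackknife(tibble::tibble(x = x, pos_index = seq_along(x)),
                        function(d) c(mean = mean(d$x)), n_blocks = 50)
  expect_equal(jk$se, sd(x) / sqrt(length(x)), tolerance = 0.15)
  expect_error(block_jackknife(tibble::tibble(x = 1:5, pos_index = 1:5),
                               function(d) mean(d$x), n_blocks = 10),
               "exceeds")
})
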