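# Logistic mixture-frequency model for non-synonymous status:
# logit P(Y = 1) = mu + gamma * log(pmix), profiled over the mixture
# weight w, with likelihood-ratio intervals and non-nested comparisons.

#' Logistic regression of a binary label on log mixture frequency
#'
#' Maximum-likelihood fit of `logit P(Y=1) = mu + gamma * x` by iteratively
#' reweighted least squares specialised to the two-parameter model (closed
#' 2x2 weighted normal equations per iteration; at most 100 iterations,
#' gradient tolerance 1e-8, ridge jitter 1e-10 on the information matrix
#' near separation). The profile over the mixture weight evaluates this fit
#' hundreds of times per data set, so the solver is written for that inner
#' loop. Non-convergence is flagged on the returned object; complete
#' separation (vanishing residual deviance with both classes present) and
#' constant predictors are errors.
#'
#' @param labels Binary 0/1 vector.
#' @param log_pmix Numeric predictor (log mixture frequency).
#' @return Object of class `"logistic_fit"`: fields `mu`, `gamma`, `loglik`,
#'   `n`, `converged`, and the per-observation log-likelihood vector
#'   `per_obs_loglik` (used by [vuong_test()]).
#' @export
fit_logistic <- function(labels, log_pmix) {
  if (length(labels) != length(log_pmix)) {
    abort("`labels` and `log_pmix` must have the same length.")
  }
  if (any(!labels %in% c(0, 1))) abort("`labels` must be binary 0/1.")
  if (any(!is.finite(log_pmix))) abort("`log_pmix` must be finite.")
  if (length(unique(labels)) < 2L) abort("Both label classes must be present.")
  if (sd(log_pmix) == 0) {
    abort("Constant predictor: the slope gamma is unidentifiable.")
  }
  x <- log_pmix
  y <- labels
  n <- length(y)
  mu <- qlogis(mean(y))
  gamma <- 0
  converged <- FALSE
  for (it in seq_len(100L)) {
    p <- plogis(mu + gamma * x)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    r <- y - p
    g1 <- sum(r)
    g2 <- sum(r * x)
    if (max(abs(g1), abs(g2)) < 1e-8 * n) {
      converged <- TRUE
      break
    }
    wt <- p * (1 - p)
    i11 <- sum(wt)
    i12 <- sum(wt * x)
    i22 <- sum(wt * x * x)
    det <- i11 * i22 - i12^2 + 1e-10  # ridge jitter near separation
    d1 <- (i22 * g1 - i12 * g2) / det
    d2 <- (i11 * g2 - i12 * g1) / det
    step <- max(abs(d1), abs(d2))
    if (step > 10) {  # damp early overshoot; separation still diverges slowly
      d1 <- d1 * 10 / step
      d2 <- d2 * 10 / step
    }
    mu <- mu + d1
    gamma <- gamma + d2
  }
  p <- plogis(mu + gamma * x)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll_obs <- y * log(p) + (1 - y) * log1p(-p)
  if (-2 * sum(ll_obs) < 1e-6 * n) {  # per-observation deviance ~ 0
    abort("Complete separation: the logistic likelihood is unbounded.")
  }
  structure(list(mu = mu, gamma = gamma,
                 loglik = sum(ll_obs),
                 n = n,
                 converged = converged,
                 per_obs_loglik = ll_obs),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, mu = %.4f, gamma = %.4f, loglik = %.2f%s\n",
              x$n, x$mu, x$gamma, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("mu", "gamma"), estimate = c(x$mu, x$gamma))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n, converged = x$converged)
}

#' Profile log-likelihood of the label model at a fixed mixture weight
#'
#' Floors `pA` and `pE` at `maf_floor`, forms `pmix = w pA + (1 - w) pE`
#' (clamped into `[1e-6, 0.5]` for weights outside `[0, 1]`), and fits the
#' logistic model, maximising over the nuisance parameters `(mu, gamma)`.
#' At `w = 1` (resp. `w = 0`) this is exactly the African-only
#' (resp. European-only) logistic regression.
#'
#' @param labels Binary 0/1 vector.
#' @param pA,pE Folded MAFs per ancestry.
#' @param w Fixed mixture weight.
#' @param maf_floor MAF floor, default 0.002.
#' @return A `"logistic_fit"` (see [fit_logistic()]).
#' @export
profile_loglik <- function(labels, pA, pE, w, maf_floor = 0.002) {
  pmix <- compute_pmix(floor_maf(pA, maf_floor), floor_maf(pE, maf_floor), w)
  fit_logistic(labels, log(clamp_pmix(pmix)))
}

#' Maximise the profile likelihood over the mixture weight
#'
#' Profiles the logistic log-likelihood `L(w) = max_{mu,gamma} L(w, mu, gamma)`
#' over a bounded interval (default `[-0.5, 1.5]`) with a coarse grid warm
#' start followed by Brent optimisation (tolerance 1e-6), and inverts the
#' 1-df likelihood-ratio test for a 95% confidence interval
#' (`{w : 2[L(w_mle) - L(w)] <= 3.841}`). If the profile never crosses the
#' LRT cutoff inside the bounds, the corresponding CI endpoint is the bound
#' and a warning about a flat profile is issued.
#'
#' @inheritParams profile_loglik
#' @param bounds Search interval for `w`.
#' @param grid_n Coarse warm-start grid size (also the stored curve grid).
#' @param w_grid Optional explicit grid for the stored curve.
#' @return Object of class `"profile_curve"`: the curve tibble
#'   (`w`, `loglik`, `gamma`, `mu`), `w_mle`, `loglik_mle`, `gamma_mle`,
#'   `mu_mle`, `ci95`, `n`, and the data needed to evaluate LRT p-values at
#'   arbitrary null weights via [lrt_pvalue()].
#' @export
maximize_profile <- function(labels, pA, pE, maf_floor = 0.002,
                             bounds = c(-0.5, 1.5), grid_n = 31,
                             w_grid = NULL) {
  w_grid <- w_grid %||% seq(bounds[1], bounds[2], length.out = grid_n)
  fits <- lapply(w_grid, function(w) profile_loglik(labels, pA, pE, w, maf_floor))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  i <- which.max(ll)
  lo <- w_grid[max(1L, i - 1L)]
  hi <- w_grid[min(length(w_grid), i + 1L)]
  obj <- function(w) profile_loglik(labels, pA, pE, w, maf_floor)$loglik
  opt <- optimize(obj, lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)
  w_mle <- opt$maximum
  ll_mle <- opt$objective
  if (ll[i] > ll_mle) { w_mle <- w_grid[i]; ll_mle <- ll[i] }
  fit_mle <- profile_loglik(labels, pA, pE, w_mle, maf_floor)

  cutoff <- qchisq(0.95, 1)
  f_ci <- function(w) 2 * (ll_mle - obj(w)) - cutoff
  ci <- c(NA_real_, NA_real_)
  for (side in 1:2) {
    bound <- bounds[side]
    if (f_ci(bound) > 0) {
      ci[side] <- uniroot(f_ci, sort(c(w_mle, bound)), tol = 1e-6)$root
    } else {
      ci[side] <- bound
      warn(sprintf(
        "Profile is flat towards w = %s; CI endpoint set to the search bound.",
        format(bound)))
    }
  }

  structure(list(
    curve = tibble(w = w_grid, loglik = ll,
                   gamma = vapply(fits, function(f) f$gamma, numeric(1)),
                   mu = vapply(fits, function(f) f$mu, numeric(1))),
    w_mle = w_mle, loglik_mle = ll_mle,
    gamma_mle = fit_mle$gamma, mu_mle = fit_mle$mu,
    ci95 = ci, n = length(labels), maf_floor = maf_floor, bounds = bounds,
    data = list(labels = labels, pA = pA, pE = pE)),
    class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve> n = %d SNPs\n", x$n))
  cat(sprintf("  w_mle = %.4f (95%% CI %.4f, %.4f), gamma = %.4f, logLik = %.2f\n",
              x$w_mle, x$ci95[1], x$ci95[2], x$gamma_mle, x$loglik_mle))
  invisible(x)
}

#' @export
tidy.profile_curve <- function(x, ...) {
  tibble(term = c("w", "gamma", "mu"),
         estimate = c(x$w_mle, x$gamma_mle, x$mu_mle),
         ci_lo = c(x$ci95[1], NA, NA), ci_hi = c(x$ci95[2], NA, NA))
}

#' @export
glance.profile_curve <- function(x, ...) {
  tibble(w_mle = x$w_mle, logLik = x$loglik_mle, nobs = x$n,
         ci_lo = x$ci95[1], ci_hi = x$ci95[2])
}

#' Likelihood-ratio p-value for a null mixture weight
#'
#' Tests `w = w0` against the profile maximum with a 1-df likelihood ratio
#' statistic `2[L(w_mle) - L(w0)]`. Use [format_pvalue()] for the `<1e-15`
#' reporting convention.
#'
#' @param profile A [maximize_profile()] result.
#' @param w0 Null mixture weight.
#' @return Numeric p-value.
#' @export
lrt_pvalue <- function(profile, w0) {
  stopifnot(inherits(profile, "profile_curve"))
  d <- profile$data
  ll0 <- profile_loglik(d$labels, d$pA, d$pE, w0, profile$maf_floor)$loglik
  stat <- max(0, 2 * (profile$loglik_mle - ll0))
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Proportion of non-synonymous SNPs by bivariate MAF bin
#'
#' Tabulates PNS (non-synonymous count over all SNPs in the bin, coding and
#' non-coding alike) per bivariate bin, with binomial standard errors
#' `sqrt(PNS (1 - PNS) / n)`. Empty bins are omitted (PNS undefined).
#'
#' @param panel SNP panel with a `nonsyn` column.
#' @param scheme A [build_binning_scheme()] result.
#' @return Tibble of class `"pns_table"`: `bin`, `bin_afr`, `bin_eur`, `n`,
#'   `n_nonsyn`, `pns`, `se`.
#' @export
pns_by_bins <- function(panel, scheme) {
  assert_columns(panel, "nonsyn", "`panel`")
  out <- assign_bins(panel, scheme) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .data$bin_afr, .data$bin_eur) |>
    dplyr::summarise(n = dplyr::n(), n_nonsyn = sum(.data$nonsyn),
                     .groups = "drop") |>
    dplyr::mutate(pns = .data$n_nonsyn / .data$n,
                  se = sqrt(.data$pns * (1 - .data$pns) / .data$n))
  class(out) <- c("pns_table", class(out))
  out
}

#' Vuong test for non-nested models with equal degrees of freedom
#'
#' Compares two models fit to the same observations via the per-observation
#' log-likelihood differences `d_i`: the statistic is
#' `sqrt(n) * mean(d) / sd(d)`, referred to a standard normal (two-sided).
#' A positive statistic favours model A. Identical models give statistic 0
#' and p = 1 by convention; a zero-variance difference between genuinely
#' different models is an error.
#'
#' @param fit_a,fit_b `"logistic_fit"` objects (or any objects with a
#'   `per_obs_loglik` field) fit to the same observations.
#' @return Tibble with `statistic` and `p_value`.
#' @export
vuong_test <- function(fit_a, fit_b) {
  la <- fit_a$per_obs_loglik
  lb <- fit_b$per_obs_loglik
  if (length(la) != length(lb)) {
    abort("Models must be fit to the same observations.")
  }
  d <- la - lb
  if (all(d == 0)) return(tibble(statistic = 0, p_value = 1))
  s <- sd(d)
  if (s == 0) abort("Zero variance of log-likelihood differences for unequal models.")
  stat <- sqrt(length(d)) * mean(d) / s
  tibble(statistic = stat, p_value = 2 * pnorm(-abs(stat)))
}

#' McFadden pseudo-r-squared
#'
#' `1 - logLik(model) / logLik(null)`, where the null is the intercept-only
#' (`gamma = 0`) fit on the same observations; 0 for the null model itself.
#'
#' @param fit,fit_null `"logistic_fit"` objects on the same observations.
#' @return Numeric scalar.
#' @export
mcfadden_r2 <- function(fit, fit_null) {
  1 - fit$loglik / fit_null$loglik
}

#' Relative log-likelihood gain over a null model
#'
#' `[L(model) - L(null)] / [L(reference) - L(null)]` for three fits on
#' identical observations, the headline "x-fold larger increase in
#' log-likelihood" comparison. The null is the no-MAF-dependence
#' (`gamma = 0`) model; a non-positive reference gain is an error.
#'
#' @param fit_model,fit_null,fit_reference `"logistic_fit"` objects.
#' @return Numeric ratio.
#' @export
relative_ll_gain <- function(fit_model, fit_null, fit_reference) {
  ns <- c(fit_model$n, fit_null$n, fit_reference$n)
  if (length(unique(ns)) != 1L) {
    abort("All three fits must be on identical observations.")
  }
  denom <- fit_reference$loglik - fit_null$loglik
  if (denom <= 0) abort("Reference model has non-positive log-likelihood gain.")
  (fit_model$loglik - fit_null$loglik) / denom
}

#' Slope per mixture weight with a standardised predictor
#'
#' Refits the logistic model over a grid of mixture weights with
#' `log(pmix)` divided by its sample standard deviation. Standardisation is
#' an affine reparameterisation, so the log-likelihood (and hence the MLE of
#' `w`) is unchanged and `gamma_std = gamma * sd(log pmix)`; unlike the raw
#' slope, `|gamma_std|` peaks near the likelihood maximiser.
#'
#' @inheritParams profile_loglik
#' @param w_grid Grid of mixture weights.
#' @return Tibble with `w`, `gamma`, `sd_log_pmix`, `gamma_std`, `loglik`.
#' @export
standardized_gamma <- function(labels, pA, pE, w_grid, maf_floor = 0.002) {
  purrr::map_dfr(w_grid, function(w) {
    x <- log(clamp_pmix(compute_pmix(floor_maf(pA, maf_floor),
                                     floor_maf(pE, maf_floor), w)))
    fit <- fit_logistic(labels, x)
    tibble(w = w, gamma = fit$gamma, sd_log_pmix = sd(x),
           gamma_std = fit$gamma * sd(x), loglik = fit$loglik)
  })
}

#' Jackknife comparison of logistic fits on different SNP sets
#'
#' Compares the slope `gamma` and McFadden pseudo-r-squared of two
#' single-predictor logistic fits that may use different SNP sets, via a
#' genomic block jackknife with shared block boundaries: blocks are defined
#' once on the pooled positional index (contiguous, sizes differing by at
#' most one) and each delete-one-block replicate refits both models without
#' their SNPs in that block. A zero jackknife SE with a zero difference is
#' reported as p = 1.
#'
#' @param data_a,data_b Tibbles with columns `label`, `log_maf`,
#'   `pos_index`.
#' @param n_blocks Number of blocks (default 200).
#' @return Tibble with rows `d_gamma` and `d_r2`: `estimate`, `se`,
#'   `p_value`.
#' @export
jackknife_compare <- function(data_a, data_b, n_blocks = 200) {
  for (d in list(data_a, data_b)) {
    assert_columns(d, c("label", "log_maf", "pos_index"), "jackknife data")
  }
  pooled <- sort(c(data_a$pos_index, data_b$pos_index))
  if (n_blocks > length(pooled)) {
    abort("n_blocks exceeds the number of available positions.")
  }
  # shared boundaries: equal pooled counts per block
  cuts <- quantile(pooled, probs = seq_len(n_blocks - 1L) / n_blocks, type = 1)
  block_of <- function(pos) findInterval(pos, cuts) + 1L
  stat_pair <- function(a, b) {
    fa <- fit_logistic(a$label, a$log_maf)
    fb <- fit_logistic(b$label, b$log_maf)
    r2a <- mcfadden_r2(fa, fit_null_logistic(a$label))
    r2b <- mcfadden_r2(fb, fit_null_logistic(b$label))
    c(d_gamma = fa$gamma - fb$gamma, d_r2 = r2a - r2b)
  }
  full <- stat_pair(data_a, data_b)
  ba <- block_of(data_a$pos_index)
  bb <- block_of(data_b$pos_index)
  theta <- t(vapply(seq_len(n_blocks), function(b) {
    stat_pair(data_a[ba != b, , drop = FALSE], data_b[bb != b, , drop = FALSE])
  }, numeric(2)))
  se <- jackknife_se(theta)
  tibble(term = names(full), estimate = unname(full), se = unname(se),
         p_value = jackknife_pvalue(unname(full), unname(se), c(0, 0)))
}

#' Intercept-only logistic fit
#'
#' Closed-form intercept-only (`gamma = 0`) fit, the no-MAF-dependence null
#' used in likelihood-gain ratios and McFadden pseudo-r-squared.
#'
#' @param labels Binary 0/1 vector.
#' @return A `"logistic_fit"`.
#' @export
fit_null_logistic <- function(labels) {
  pbar <- mean(labels)
  ll_obs <- labels * log(pbar) + (1 - labels) * log1p(-pbar)
  structure(list(mu = qlogis(pbar), gamma = 0, loglik = sum(ll_obs),
                 n = length(labels), converged = TRUE,
                 per_obs_loglik = ll_obs),
            class = "logistic_fit")
}
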