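# Generalized-method-of-moments estimation of the mixture-frequency
# effect-variance model: per-bin moment conditions
#   E[ sigma_t^2/2 * (pmix_k (1 - pmix_k))^alpha - beta2_hat_{t,k} ] = 0,
# minimised as a SNP-count-weighted sum of squares over (w, alpha), with
# each trait's variance parameter eliminated analytically.

#' Predicted bin-wise per-allele effect-size variance
#'
#' Evaluates `sigma2/2 * [p (1 - p)]^alpha` with
#' `p = clamp(w * mean_pA + (1 - w) * mean_pE)` per bin (clamped into
#' `[1e-6, 0.5]`, which only matters for mixture weights outside `[0, 1]`).
#'
#' @param bins Tibble with `mean_pA`, `mean_pE` (a bin-variance table or
#'   [bin_summaries()] output).
#' @param w Mixture weight.
#' @param alpha MAF-dependence exponent.
#' @param sigma2 Variance parameter `sigma_g^2`.
#' @return Numeric vector of predicted per-bin variances.
#' @export
predict_bin_variance <- function(bins, w, alpha, sigma2) {
  assert_columns(bins, c("mean_pA", "mean_pE"), "`bins`")
  p <- clamp_pmix(compute_pmix(bins$mean_pA, bins$mean_pE, w))
  sigma2 / 2 * (p * (1 - p))^alpha
}

# ---- internal data preparation -------------------------------------------

# Normalised internal representation of the moment data. Bin-mean form uses
# the transform of the bin-mean pmix; per-SNP form averages the transformed
# per-SNP values within each bin (optionally plateau-thresholded), which is
# what the oracle-regime analyses need.
prepare_gmm_data <- function(tables, snps = NULL, pmix_threshold = NULL,
                             require_aligned = is.null(snps)) {
  assert_columns(tables, c("trait", "bin", "n_k", "mean_pA", "mean_pE",
                           "beta2_hat"), "`tables`")
  tables <- dplyr::arrange(tables, .data$trait, .data$bin)
  traits <- unique(tables$trait)
  if (require_aligned && length(traits) > 1L) {
    sets <- split(as.character(tables$bin), tables$trait)
    if (length(unique(lapply(sets, sort))) != 1L) {
      abort("Bin sets differ across traits; tables must share a common binning scheme.")
    }
  }
  d <- list(
    n_traits = length(traits), traits = traits,
    t_idx = match(tables$trait, traits),
    nk = tables$n_k, b = tables$beta2_hat,
    mpA = tables$mean_pA, mpE = tables$mean_pE,
    tables = tables, threshold = pmix_threshold, per_snp = !is.null(snps)
  )
  if (d$per_snp) {
    assert_columns(snps, c("trait", "bin", "pA", "pE"), "`snps`")
    key_t <- paste(tables$trait, tables$bin)
    key_s <- paste(snps$trait, snps$bin)
    row_map <- match(key_s, key_t)
    if (anyNA(row_map)) abort("`snps` contains trait/bin pairs absent from `tables`.")
    counts <- tabulate(row_map, nbins = nrow(tables))
    if (any(counts == 0L)) abort("Every table row needs at least one SNP in `snps`.")
    d$row_map <- row_map
    d$row_n <- counts
    d$pA <- snps$pA
    d$pE <- snps$pE
  }
  # null model (alpha = 0): g = 1, sigma/2 is the count-weighted mean
  null_half <- rowsum_vec(d$nk * d$b, d$t_idx, d$n_traits) /
    rowsum_vec(d$nk, d$t_idx, d$n_traits)
  d$null_loss <- sum(d$nk * (null_half[d$t_idx] - d$b)^2)
  d
}

rowsum_vec <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  agg <- rowsum(x, group, reorder = TRUE)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# Per-bin geometry factor g_k(w, alpha) for every table row.
gmm_g <- function(d, w, alpha) {
  if (d$per_snp) {
    q <- compute_pmix(d$pA, d$pE, w)
    if (!is.null(d$threshold)) q <- pmax(q, d$threshold)
    q <- clamp_pmix(q)
    rowsum_vec((q * (1 - q))^alpha, d$row_map, length(d$row_n)) / d$row_n
  } else {
    p <- clamp_pmix(compute_pmix(d$mpA, d$mpE, w))
    (p * (1 - p))^alpha
  }
}

# Concentrated loss: sigma_t^2 solved analytically for each trait.
gmm_eval <- function(d, w, alpha) {
  g <- gmm_g(d, w, alpha)
  num <- rowsum_vec(d$nk * d$b * g, d$t_idx, d$n_traits)
  den <- rowsum_vec(d$nk * g * g, d$t_idx, d$n_traits)
  if (any(den == 0)) abort("All bin geometry factors vanished; cannot solve for sigma.")
  half <- num / den
  list(loss = sum(d$nk * (half[d$t_idx] * g - d$b)^2),
       sigma2 = 2 * half, g = g, pred = half[d$t_idx] * g)
}

#' Analytic variance parameter given (w, alpha)
#'
#' Closed-form minimiser of the single-trait quadratic-in-sigma loss:
#' `sigma_g^2 = 2 * sum_k n_k beta2_k g_k / sum_k n_k g_k^2` with
#' `g_k = [pmix_k (1 - pmix_k)]^alpha`. May be negative when bin means are
#' predominantly negative.
#'
#' @param table One-trait bin-variance table.
#' @param w,alpha Model parameters.
#' @param snps Optional per-SNP rows (per-SNP moment form, see
#'   [fit_alphamix()]).
#' @param pmix_threshold Optional plateau threshold applied to per-SNP pmix.
#' @return Numeric `sigma_g^2`.
#' @export
analytic_sigma <- function(table, w, alpha, snps = NULL,
                           pmix_threshold = NULL) {
  if (dplyr::n_distinct(table$trait) != 1L) {
    abort("`analytic_sigma()` expects a single-trait table.")
  }
  if (all(table$n_k <= 0)) abort("At least one bin must have n_k > 0.")
  d <- prepare_gmm_data(table, snps, pmix_threshold)
  gmm_eval(d, w, alpha)$sigma2
}

#' Weighted squared-moment GMM loss
#'
#' `sum_t sum_k n_k (sigma_t^2/2 * g_k - beta2_hat_{t,k})^2`, the objective
#' of the moment fit, weighted by the number of SNPs in each bin. In the
#' bin-mean moment form all traits must share the same bin set.
#'
#' @param tables Bin-variance table (rows: trait x bin).
#' @param w,alpha Model parameters.
#' @param sigma2 Named numeric vector of `sigma_g^2` per trait (single
#'   unnamed value allowed for one trait).
#' @inheritParams analytic_sigma
#' @return Numeric loss (>= 0).
#' @export
gmm_loss <- function(tables, w, alpha, sigma2, snps = NULL,
                     pmix_threshold = NULL) {
  d <- prepare_gmm_data(tables, snps, pmix_threshold)
  if (is.null(names(sigma2))) {
    if (length(sigma2) != d$n_traits) {
      abort("`sigma2` must supply one value per trait.")
    }
    names(sigma2) <- d$traits
  }
  if (!all(d$traits %in% names(sigma2))) {
    abort("`sigma2` is missing values for some traits.")
  }
  g <- gmm_g(d, w, alpha)
  half <- unname(sigma2[match(d$traits, names(sigma2))]) / 2
  sum(d$nk * (half[d$t_idx] * g - d$b)^2)
}

# ---- differential evolution ----------------------------------------------

#' Optimiser settings for the GMM fit
#'
#' Pinned configuration of the global optimiser: a rand/1/bin differential
#' evolution population search over `(w, alpha)` followed by an L-BFGS-B
#' polish. The defaults (population 30, 200 generations, F = 0.8, CR = 0.9)
#' are deterministic given the fit's seed; early stopping triggers when the
#' population's loss spread collapses.
#'
#' @param pop_size Population size.
#' @param n_gens Maximum generations.
#' @param f Differential weight.
#' @param cr Crossover probability.
#' @param polish Run a bounded local polish from the best member.
#' @param tol Relative loss-spread early-stopping tolerance.
#' @return A list of class `"de_control"`.
#' @export
de_control <- function(pop_size = 30, n_gens = 200, f = 0.8, cr = 0.9,
                       polish = TRUE, tol = 1e-12) {
  structure(list(pop_size = as.integer(pop_size), n_gens = as.integer(n_gens),
                 f = f, cr = cr, polish = polish, tol = tol),
            class = "de_control")
}

de_optimize <- function(fn, lower, upper, control) {
  k <- length(lower)
  np <- control$pop_size
  pop <- matrix(runif(np * k, lower, upper), nrow = np, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  for (gen in seq_len(control$n_gens)) {
    for (i in seq_len(np)) {
      idx <- sample.int(np, 3L)
      trial <- pop[idx[1L], ] + control$f * (pop[idx[2L], ] - pop[idx[3L], ])
      cross <- runif(k) < control$cr
      cross[sample.int(k, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      cost_trial <- fn(trial)
      if (cost_trial <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- cost_trial
      }
    }
    if (diff(range(cost)) < control$tol * (1 + abs(min(cost)))) break
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}

# 1-D concentrated optimisation over the remaining free parameter.
optimize_1d <- function(fn, lower, upper, n_grid = 41) {
  grid <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(grid, fn, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- optimize(fn, lower = lo, upper = hi, tol = 1e-8)
  if (vals[i] < opt$objective) list(par = grid[i], value = vals[i])
  else list(par = opt$minimum, value = opt$objective)
}

# ---- fitting --------------------------------------------------------------

#' Fit the mixture-frequency effect-variance model
#'
#' Estimates `(w, alpha)` jointly across traits (single shared `w` and
#' `alpha`; one `sigma_g^2` per trait, eliminated analytically at every loss
#' evaluation) by global minimisation of the SNP-count-weighted squared
#' moment loss over bounded rectangles (defaults `w` in `[-0.5, 1.5]`,
#' `alpha` in `[-1.5, 1.5]`), using differential evolution plus a local
#' polish. Fits with the weight or exponent held fixed provide the nested
#' comparison models (no MAF dependence `alpha = 0`; European-only `w = 0`;
#' African-only `w = 1`) whose scaled losses are reported alongside; the
#' loss is scaled so the no-MAF-dependence null has weighted scaled MSE 1.
#'
#' The per-SNP moment form (`snps` supplied) replaces the transform of the
#' bin-mean mixture frequency with the bin mean of per-SNP transformed
#' values, optionally thresholded at the plateau `pmix_threshold` — the
#' oracle-regime inference model.
#'
#' @param tables Bin-variance table (rows: trait x bin): columns `trait`,
#'   `bin`, `n_k`, `mean_pA`, `mean_pE`, `beta2_hat`.
#' @param snps Optional per-SNP tibble (`trait`, `bin`, `pA`, `pE`) enabling
#'   the per-SNP moment form.
#' @param pmix_threshold Optional plateau threshold for per-SNP pmix
#'   (per-SNP form only; off by default, matching the main inference model).
#' @param fix_w,fix_alpha Optionally hold a parameter fixed.
#' @param w_bounds,alpha_bounds Optimiser bounds.
#' @param control A [de_control()].
#' @param nested Also fit the nested comparison models (default `TRUE`).
#' @param seed Integer seed for the population search (default 1).
#' @return Object of class `"alphamix_fit"`; see [tidy.alphamix_fit()] and
#'   [glance.alphamix_fit()].
#' @export
fit_alphamix <- function(tables, snps = NULL, pmix_threshold = NULL,
                         fix_w = NULL, fix_alpha = NULL,
                         w_bounds = c(-0.5, 1.5), alpha_bounds = c(-1.5, 1.5),
                         control = de_control(), nested = TRUE, seed = 1L) {
  d <- prepare_gmm_data(tables, snps, pmix_threshold)
  loss_fn <- function(w, alpha) gmm_eval(d, w, alpha)$loss

  solve_free <- function(fw, fa) {
    if (!is.null(fw) && !is.null(fa)) {
      list(par = c(fw, fa), value = loss_fn(fw, fa))
    } else if (!is.null(fw)) {
      o <- optimize_1d(function(a) loss_fn(fw, a), alpha_bounds[1], alpha_bounds[2])
      list(par = c(fw, o$par), value = o$value)
    } else if (!is.null(fa)) {
      o <- optimize_1d(function(w) loss_fn(w, fa), w_bounds[1], w_bounds[2])
      list(par = c(o$par, fa), value = o$value)
    } else {
      fn <- function(p) loss_fn(p[1], p[2])
      lower <- c(w_bounds[1], alpha_bounds[1])
      upper <- c(w_bounds[2], alpha_bounds[2])
      cand <- list(de_optimize(fn, lower, upper, control))
      # extra deterministic starts: the endpoint models guard the nesting
      # property L(fit) <= L(w=0), L(w=1) even on flat or multimodal losses
      for (w0 in c(w_bounds[1], 0, 1, w_bounds[2])) {
        o <- optimize_1d(function(a) loss_fn(w0, a),
                         alpha_bounds[1], alpha_bounds[2], n_grid = 21)
        cand <- c(cand, list(list(par = c(w0, o$par), value = o$value)))
      }
      if (isTRUE(control$polish)) {
        cand <- lapply(cand, function(cc) {
          p <- tryCatch(
            optim(cc$par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                  control = list(factr = 1e4)),
            error = function(e) NULL)
          if (!is.null(p) && p$value <= cc$value) list(par = p$par, value = p$value)
          else cc
        })
      }
      vals <- vapply(cand, function(cc) cc$value, numeric(1))
      best_val <- min(vals)
      near <- which(vals <= best_val * (1 + 1e-9) + 1e-300)
      if (length(near) > 1L) {
        ws <- vapply(cand[near], function(cc) cc$par[1], numeric(1))
        distinct <- abs(ws - ws[which.min(vals[near])]) > 1e-4
        # tie-break: among near-optimal distinct weights keep the most
        # central one and flag the fit as weakly identified
        pick <- near[which.min(abs(ws - 0.5))]
        res <- cand[[pick]]
        res$ambiguous <- any(distinct)
        res
      } else {
        cand[[which.min(vals)]]
      }
    }
  }

  res <- with_opt_seed(seed, solve_free(fix_w, fix_alpha))
  w_hat <- res$par[1]
  alpha_hat <- res$par[2]
  ev <- gmm_eval(d, w_hat, alpha_hat)

  comparisons <- NULL
  if (nested) {
    comp <- function(label, fw, fa) {
      r <- with_opt_seed(seed, solve_free(fw, fa))
      tibble(model = label, w = r$par[1], alpha = r$par[2], loss = r$value,
             scaled_mse = r$value / d$null_loss)
    }
    comparisons <- dplyr::bind_rows(
      tibble(model = "alphamix", w = w_hat, alpha = alpha_hat,
             loss = ev$loss, scaled_mse = ev$loss / d$null_loss),
      comp("null", fix_w %||% 0, 0),
      comp("w0", 0, fix_alpha),
      comp("w1", 1, fix_alpha))
  }

  at_bound <- function(x, b) min(abs(x - b)) < 1e-6
  structure(list(
    w = w_hat, alpha = alpha_hat,
    sigma2 = tibble(trait = d$traits, sigma_g2 = ev$sigma2),
    loss = ev$loss, null_loss = d$null_loss,
    scaled_mse = ev$loss / d$null_loss,
    residuals = dplyr::mutate(d$tables, predicted = ev$pred,
                              residual = ev$pred - d$b),
    comparisons = comparisons,
    bounds_hit = (is.null(fix_w) && at_bound(w_hat, w_bounds)) ||
      (is.null(fix_alpha) && at_bound(alpha_hat, alpha_bounds)),
    ambiguous = isTRUE(res$ambiguous),
    moment_form = if (d$per_snp) "per_snp" else "bin_mean",
    pmix_threshold = pmix_threshold,
    fixed = list(w = fix_w, alpha = fix_alpha),
    n_traits = d$n_traits, n_bins = nrow(d$tables) / d$n_traits,
    seed = seed),
    class = "alphamix_fit")
}

#' Fit the model separately for each trait
#'
#' Runs [fit_alphamix()] per trait and collects the per-trait estimates,
#' which feed [meta_analyze()].
#'
#' @inheritParams fit_alphamix
#' @param ... Passed to [fit_alphamix()].
#' @return Tibble with one row per trait: `trait`, `w`, `alpha`,
#'   `sigma_g2`, `loss`, `scaled_mse`, and the full fit in list-column
#'   `fit`.
#' @export
fit_alphamix_per_trait <- function(tables, snps = NULL, ...) {
  traits <- unique(tables$trait)
  purrr::map_dfr(traits, function(tr) {
    tab <- dplyr::filter(tables, .data$trait == tr)
    sn <- if (!is.null(snps)) dplyr::filter(snps, .data$trait == tr)
    fit <- fit_alphamix(tab, snps = sn, ...)
    tibble(trait = tr, w = fit$w, alpha = fit$alpha,
           sigma_g2 = fit$sigma2$sigma_g2[1], loss = fit$loss,
           scaled_mse = fit$scaled_mse, fit = list(fit))
  })
}

#' Profile the exponent over a grid of mixture weights
#'
#' For each fixed `w`, minimises the concentrated loss over `alpha`
#' (variance parameters analytic), giving the exponent-versus-weight curve
#' and the weighted scaled MSE curve (null `alpha = 0` model scaled to 1).
#'
#' @inheritParams fit_alphamix
#' @param w_grid Grid of mixture weights.
#' @return Tibble of class `"alphamix_profile"`: `w`, `alpha`, `loss`,
#'   `scaled_mse`.
#' @export
profile_alpha_over_w <- function(tables, w_grid = seq(-0.5, 1.5, by = 0.05),
                                 snps = NULL, pmix_threshold = NULL,
                                 alpha_bounds = c(-1.5, 1.5)) {
  d <- prepare_gmm_data(tables, snps, pmix_threshold)
  out <- purrr::map_dfr(w_grid, function(w) {
    o <- optimize_1d(function(a) gmm_eval(d, w, a)$loss,
                     alpha_bounds[1], alpha_bounds[2])
    tibble(w = w, alpha = o$par, loss = o$value,
           scaled_mse = o$value / d$null_loss)
  })
  class(out) <- c("alphamix_profile", class(out))
  out
}

#' @export
print.alphamix_fit <- function(x, ...) {
  cat(sprintf("<alphamix_fit> %d trait(s), %s bins/trait, %s moment form\n",
              x$n_traits, format(x$n_bins), x$moment_form))
  cat(sprintf("  w = %.4f, alpha = %.4f, scaled MSE = %.4f%s%s\n",
              x$w, x$alpha, x$scaled_mse,
              if (x$bounds_hit) " [at bound]" else "",
              if (x$ambiguous) " [weakly identified]" else ""))
  invisible(x)
}

#' Tidy method for mixture-model fits
#'
#' @param x An `"alphamix_fit"`.
#' @param ... Unused.
#' @return Tibble of parameter estimates (`w`, `alpha`, one `sigma_g2` row
#'   per trait).
#' @export
tidy.alphamix_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = c("w", "alpha"), trait = NA_character_,
           estimate = c(x$w, x$alpha)),
    tibble(term = "sigma_g2", trait = as.character(x$sigma2$trait),
           estimate = x$sigma2$sigma_g2))
}

#' Glance method for mixture-model fits
#'
#' @param x An `"alphamix_fit"`.
#' @param ... Unused.
#' @return One-row tibble with the fit summary.
#' @export
glance.alphamix_fit <- function(x, ...) {
  tibble(w = x$w, alpha = x$alpha, loss = x$loss, scaled_mse = x$scaled_mse,
         n_traits = x$n_traits, moment_form = x$moment_form,
         bounds_hit = x$bounds_hit)
}
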