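# Cross-trait combination of parameter estimates and the greedy
# independent-trait selection used to assemble an analysis set.

#' Random- and fixed-effects meta-analysis of per-trait estimates
#'
#' Combines per-trait estimates with a DerSimonian-Laird random-effects
#' model (between-trait variance floored at 0) and an inverse-variance
#' fixed-effects model, via \pkg{metafor}, and reports Cochran's Q
#' heterogeneity test. Traits with non-finite or non-positive standard
#' errors are excluded with a warning.
#'
#' @param estimates Numeric vector of per-trait estimates (e.g. `w` or
#'   `alpha` from [fit_alphamix_per_trait()]).
#' @param se Numeric vector of per-trait standard errors.
#' @return Tibble with rows `random` and `fixed`: `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `tau2` (between-trait variance; `NA` for fixed),
#'   `q`, `q_pvalue`, `n_traits`.
#' @export
meta_analyze <- function(estimates, se) {
  if (length(estimates) != length(se)) {
    abort("`estimates` and `se` must have the same length.")
  }
  ok <- is.finite(estimates) & is.finite(se) & se > 0
  if (any(!ok)) {
    warn(sprintf("Excluding %d trait(s) with non-finite or non-positive SE.",
                 sum(!ok)))
  }
  estimates <- estimates[ok]
  se <- se[ok]
  if (length(estimates) < 2L) abort("At least two usable traits are required.")
  re <- metafor::rma(yi = estimates, sei = se, method = "DL")
  fe <- metafor::rma(yi = estimates, sei = se, method = "FE")
  tibble(
    method = c("random", "fixed"),
    estimate = c(as.numeric(re$b), as.numeric(fe$b)),
    se = c(re$se, fe$se),
    ci_lo = c(re$ci.lb, fe$ci.lb),
    ci_hi = c(re$ci.ub, fe$ci.ub),
    tau2 = c(re$tau2, NA_real_),
    q = c(re$QE, fe$QE),
    q_pvalue = c(re$QEp, fe$QEp),
    n_traits = length(estimates)
  )
}

#' Greedy selection of approximately independent traits
#'
#' Filters traits to those with heritability z-score above `z_min` and
#' `N * h2` above `nh2_min`, then greedily selects in descending `N * h2`
#' order, rejecting any candidate whose squared genetic correlation with an
#' already-selected trait reaches `rg2_max`.
#'
#' @param traits Tibble with columns `trait`, `h2_z`, `nh2`.
#' @param rg2 Symmetric matrix of squared genetic correlations with unit
#'   diagonal, dimnames matching `traits$trait`.
#' @param z_min Heritability z-score filter (default 6).
#' @param nh2_min `N * h2` filter (default 20000).
#' @param rg2_max Squared-genetic-correlation ceiling between selected
#'   traits (default 0.1).
#' @return Character vector of selected trait names (possibly empty), in
#'   selection order.
#' @export
select_independent_traits <- function(traits, rg2, z_min = 6,
                                      nh2_min = 20000, rg2_max = 0.1) {
  assert_columns(traits, c("trait", "h2_z", "nh2"), "`traits`")
  rg2 <- as.matrix(rg2)
  if (!isSymmetric(unname(rg2)) || any(abs(diag(rg2) - 1) > 1e-8)) {
    abort("`rg2` must be symmetric with unit diagonal.")
  }
  if (is.null(rownames(rg2))) {
    rownames(rg2) <- colnames(rg2) <- traits$trait
  }
  pass <- traits |>
    dplyr::filter(.data$h2_z > z_min, .data$nh2 > nh2_min) |>
    dplyr::arrange(dplyr::desc(.data$nh2))
  selected <- character(0)
  for (tr in pass$trait) {
    if (length(selected) == 0L ||
        all(rg2[tr, selected] < rg2_max)) {
      selected <- c(selected, tr)
    }
  }
  selected
}
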