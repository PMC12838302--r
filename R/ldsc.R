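# Simplified stratified LD-score regression stage: chi-square regression on
# annotation LD scores, per-allele conversion, and bin-wise mean per-allele
# effect-size variance (the sample moments consumed by the GMM fitter).

#' Stratified LD-score regression of chi-square statistics
#'
#' Regresses per-SNP `chi2` on `N * l_{i,d}` across annotations `d`
#' (ordinary least squares; in unlinked mode the LD score of an indicator
#' annotation is the indicator itself, where standard heteroskedasticity
#' weights are near-constant). The per-annotation coefficient `tau_d` is the
#' increase in per-SNP heritability per unit of annotation `d`. The
#' intercept is free by default (fix it at 1 with
#' `free_intercept = FALSE`, appropriate for unconfounded simulated
#' statistics — note a free intercept is collinear with annotations that
#' exactly partition the regression SNPs). A rank-deficient design is an
#' error naming the collinear annotations. Optional block-jackknife
#' covariance retains per-block coefficient estimates.
#'
#' @param sumstats Tibble with a `chi2` (or `z`) column, one row per
#'   regression SNP, aligned with `ld_scores` rows.
#' @param ld_scores Numeric matrix, SNPs by annotations (unlinked mode: the
#'   annotation indicator matrix from [bin_annotations()]).
#' @param n GWAS sample size.
#' @param free_intercept Estimate the intercept (default `TRUE`) or fix it
#'   at 1.
#' @param n_blocks Optional number of jackknife blocks; requires `pos_index`.
#' @param pos_index Positional index per SNP (for jackknife blocks).
#' @return Object of class `"ldsc_fit"`: `tau` (named per-annotation
#'   coefficients), `intercept`, `se` (jackknife, when requested), the
#'   per-block coefficient matrix `jackknife`, and `n_snps`.
#' @export
fit_stratified_ldsc <- function(sumstats, ld_scores, n, free_intercept = TRUE,
                                n_blocks = NULL, pos_index = NULL) {
  assert_scalar_number(n, "n", lower = 1)
  if (!"chi2" %in% names(sumstats)) {
    assert_columns(sumstats, "z", "`sumstats`")
    sumstats$chi2 <- sumstats$z^2
  }
  ld_scores <- as.matrix(ld_scores)
  if (nrow(ld_scores) != nrow(sumstats)) {
    abort("`ld_scores` rows must align with `sumstats` rows.")
  }
  if (is.null(colnames(ld_scores))) {
    colnames(ld_scores) <- paste0("annot", seq_len(ncol(ld_scores)))
  }
  x <- n * ld_scores
  y <- sumstats$chi2
  if (free_intercept) {
    x <- cbind(`(Intercept)` = 1, x)
  } else {
    y <- y - 1
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    abort(sprintf("Rank-deficient design; collinear column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qr_x, y)
  intercept <- if (free_intercept) unname(coefs["(Intercept)"]) else 1
  tau <- coefs[colnames(x) != "(Intercept)"]

  jack <- NULL
  se <- NULL
  if (!is.null(n_blocks)) {
    if (is.null(pos_index)) pos_index <- seq_len(nrow(sumstats))
    blocks <- jackknife_blocks(pos_index, n_blocks)
    xtx <- crossprod(x)
    xty <- crossprod(x, y)
    jack <- matrix(NA_real_, n_blocks, ncol(x), dimnames = list(NULL, colnames(x)))
    for (b in seq_len(n_blocks)) {
      sel <- blocks == b
      xb <- x[sel, , drop = FALSE]
      jack[b, ] <- solve(xtx - crossprod(xb), xty - crossprod(xb, y[sel]))
    }
    se_all <- jackknife_se(jack)
    se <- se_all[colnames(x) != "(Intercept)"]
  }
  structure(list(tau = tau, intercept = intercept, se = se, jackknife = jack,
                 n_snps = nrow(sumstats), gwas_n = n,
                 free_intercept = free_intercept),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("<ldsc_fit> %d SNPs, %d annotations, intercept %s %.4f\n",
              x$n_snps, length(x$tau),
              if (x$free_intercept) "=" else "fixed at", x$intercept))
  invisible(x)
}

#' @export
tidy.ldsc_fit <- function(x, ...) {
  out <- tibble(term = names(x$tau), estimate = unname(x$tau))
  if (!is.null(x$se)) out$se <- unname(x$se)
  out
}

#' Per-SNP per-allele effect-size variance
#'
#' Converts annotation coefficients to per-SNP heritability
#' `h2_i = sum_d a_d(i) tau_d` and divides by the Hardy-Weinberg sample
#' variance of the genotype, `beta2_i = h2_i / (2 pE_i (1 - pE_i))`.
#' Negative values are permitted and propagated (downstream bin means and
#' the GMM loss handle them).
#'
#' @param tau Named coefficient vector (or an `"ldsc_fit"`).
#' @param annotations SNP-by-annotation indicator matrix.
#' @param pE European folded MAF per SNP, in `(0, 0.5]`.
#' @return Numeric vector of per-SNP per-allele effect-size variances.
#' @export
per_allele_variance <- function(tau, annotations, pE) {
  if (inherits(tau, "ldsc_fit")) tau <- tau$tau
  annotations <- as.matrix(annotations)
  if (!is.null(colnames(annotations)) && !is.null(names(tau))) {
    if (!setequal(colnames(annotations), names(tau))) {
      abort("Annotation columns do not match tau names.")
    }
    tau <- tau[colnames(annotations)]
  }
  if (any(pE <= 0 | pE > 0.5)) abort("`pE` must be in (0, 0.5].")
  drop(annotations %*% tau) / (2 * pE * (1 - pE))
}

#' Bin-wise mean per-allele effect-size variance
#'
#' Unweighted mean of per-SNP per-allele effect-size variance within each
#' bivariate bin, with the per-bin counts and mean MAFs the GMM fitter
#' needs. Negative bin means are retained, never truncated. Empty bins are
#' excluded with a warning.
#'
#' @param panel Bin-assigned panel ([assign_bins()]).
#' @param beta2 Per-SNP per-allele variance, aligned with `panel` rows.
#' @param trait Trait identifier recorded in the table.
#' @param warn_empty Warn about empty bins (default `TRUE`).
#' @return A bin-variance table: tibble with `trait`, `bin`, `n_k`,
#'   `mean_pA`, `mean_pE`, `beta2_hat`.
#' @export
bin_mean_variance <- function(panel, beta2, trait = "trait1",
                              warn_empty = TRUE) {
  assert_columns(panel, c("bin", "maf_afr", "maf_eur"), "`panel`")
  if (length(beta2) != nrow(panel)) {
    abort("`beta2` must align with `panel` rows.")
  }
  n_empty <- sum(!levels(panel$bin) %in% as.character(panel$bin))
  if (warn_empty && n_empty > 0) {
    warn(sprintf("%d empty bin(s) excluded from the bin-variance table.", n_empty))
  }
  panel |>
    dplyr::mutate(.beta2 = beta2) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_k = dplyr::n(),
                     mean_pA = mean(.data$maf_afr),
                     mean_pE = mean(.data$maf_eur),
                     beta2_hat = mean(.data$.beta2),
                     .groups = "drop") |>
    dplyr::mutate(trait = trait, .before = 1L)
}

#' Oracle bin-wise variance from true causal effects
#'
#' Bin means of the true squared per-allele effects, the noiseless
#' counterpart of the LD-score-regression estimates. With
#' `causal_only = TRUE` the means are restricted to causal SNPs (bins with
#' no causal SNP are excluded), the regime in which the GMM fit is
#' unbiased when combined with inference-side plateau thresholding. With
#' `keep_snps = TRUE`, per-SNP `(trait, bin, pA, pE)` rows are attached as
#' attribute `"snps"` for the per-SNP moment form of the fitter.
#'
#' @param panel Bin-assigned panel with a `beta` column.
#' @param causal_only Restrict to causal (non-zero effect) SNPs.
#' @param keep_snps Attach per-SNP frequency rows.
#' @param trait Trait identifier.
#' @return A bin-variance table (see [bin_mean_variance()]).
#' @export
oracle_bin_variance <- function(panel, causal_only = FALSE, keep_snps = FALSE,
                                trait = "trait1") {
  assert_columns(panel, c("bin", "beta", "maf_afr", "maf_eur"), "`panel`")
  sub <- dplyr::filter(panel, !is.na(.data$bin))
  if (causal_only) sub <- dplyr::filter(sub, .data$beta != 0)
  if (nrow(sub) == 0L) abort("No SNPs left for the oracle bin-variance table.")
  out <- sub |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_k = dplyr::n(),
                     mean_pA = mean(.data$maf_afr),
                     mean_pE = mean(.data$maf_eur),
                     beta2_hat = mean(.data$beta^2),
                     .groups = "drop") |>
    dplyr::mutate(trait = trait, .before = 1L)
  if (keep_snps) {
    attr(out, "snps") <- tibble(trait = trait,
                                bin = sub$bin,
                                pA = sub$maf_afr, pE = sub$maf_eur)
  }
  out
}

#' Normalise per-trait bin variances and combine across traits
#'
#' Divides each trait's bin means by that trait's overall mean per-allele
#' variance across common-European SNPs (`mean_pE >= pE_min`), then combines
#' the normalised values per bin across traits by random-effects
#' meta-analysis (DerSimonian-Laird, via \pkg{metafor}). Traits with a
#' non-positive normaliser are excluded with a warning. When per-trait
#' standard errors are unavailable, traits are weighted equally (`se = 1`,
#' so the combined estimate is the cross-trait mean and the heterogeneity
#' estimate is relative).
#'
#' @param tables Combined bin-variance table for `>= 2` traits (rows:
#'   trait x bin), optionally with an `se` column.
#' @param pE_min European MAF cutoff defining the normaliser SNP set.
#' @return Tibble per bin: `bin`, `n_traits`, `estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `tau2`.
#' @export
normalize_and_meta <- function(tables, pE_min = 0.05) {
  assert_columns(tables, c("trait", "bin", "n_k", "mean_pE", "beta2_hat"),
                 "`tables`")
  if (dplyr::n_distinct(tables$trait) < 2L) {
    abort("At least two traits are required.")
  }
  norms <- tables |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(norm = sum(.data$n_k * .data$beta2_hat * (.data$mean_pE >= pE_min)) /
                       sum(.data$n_k * (.data$mean_pE >= pE_min)),
                     .groups = "drop")
  bad <- norms$trait[norms$norm <= 0 | !is.finite(norms$norm)]
  if (length(bad) > 0) {
    warn(sprintf("Excluding trait(s) with non-positive normaliser: %s.",
                 paste(bad, collapse = ", ")))
    tables <- dplyr::filter(tables, !.data$trait %in% bad)
    norms <- dplyr::filter(norms, !.data$trait %in% bad)
  }
  scaled <- tables |>
    dplyr::left_join(norms, by = "trait") |>
    dplyr::mutate(value = .data$beta2_hat / .data$norm,
                  value_se = if ("se" %in% names(tables)) .data$se / .data$norm else 1)
  scaled |>
    dplyr::group_by(.data$bin) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 1L) {
        return(tibble(n_traits = 1L, estimate = d$value, se = d$value_se,
                      ci_lo = NA_real_, ci_hi = NA_real_, tau2 = NA_real_))
      }
      fit <- metafor::rma(yi = d$value, sei = d$value_se, method = "DL")
      tibble(n_traits = nrow(d), estimate = as.numeric(fit$b),
             se = fit$se, ci_lo = fit$ci.lb, ci_hi = fit$ci.ub,
             tau2 = fit$tau2)
    }) |>
    dplyr::ungroup()
}
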