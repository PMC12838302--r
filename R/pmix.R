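#' Mixture minor allele frequency
#'
#' Computes the mixture frequency `pmix = w * pA + (1 - w) * pE`, the single
#' scalar that the mixture-frequency models use in place of a single-ancestry
#' MAF. `pmix` is linear in `w`, so the mixture of bin-mean frequencies equals
#' the bin mean of per-SNP mixtures.
#'
#' For `w` outside `[0, 1]` (the fitting bounds extend to `[-0.5, 1.5]`) the
#' result can leave `(0, 0.5]`; callers that need a valid frequency must clamp,
#' see [clamp_pmix()].
#'
#' @param pA,pE Folded minor allele frequencies in the two ancestries,
#'   each in `(0, 0.5]`.
#' @param w Mixture weight on `pA`.
#' @return Numeric vector `w * pA + (1 - w) * pE`.
#' @export
#' @examples
#' compute_pmix(0.1, 0.3, 0.5)  # 0.2
compute_pmix <- function(pA, pE, w) {
  w * pA + (1 - w) * pE
}

#' Clamp a mixture frequency into the valid folded range
#'
#' Mixture weights outside `[0, 1]` can push `pmix` out of `(0, 0.5]`; before
#' any `log` or power transform the value is clamped to `[lower, 0.5]`.
#'
#' @param p Numeric vector of (possibly out-of-range) mixture frequencies.
#' @param lower Lower clamp, default `1e-6`.
#' @param upper Upper clamp, default `0.5`.
#' @return Clamped numeric vector.
#' @export
clamp_pmix <- function(p, lower = 1e-6, upper = 0.5) {
  pmin(pmax(p, lower), upper)
}

#' Floor a minor allele frequency
#'
#' Replaces frequencies below `floor` by `floor`; applied to `pA` and `pE`
#' before computing `log(pmix)` in the non-synonymous logistic model
#' (default floor 0.002; a floor of 0.05 reproduces the common-SNP-only
#' sensitivity analysis).
#'
#' @param p Numeric vector of folded MAFs.
#' @param floor Floor value in `(0, 0.5)`.
#' @return `pmax(p, floor)`.
#' @export
#' @examples
#' floor_maf(c(0.0005, 0.01), 0.002)
floor_maf <- function(p, floor = 0.002) {
  assert_scalar_number(floor, "floor")
  if (floor <= 0 || floor >= 0.5) abort("`floor` must be in (0, 0.5).")
  pmax(p, floor)
}
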