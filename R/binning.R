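# Univariate and bivariate MAF binning.
#
# The fit scheme mirrors the annotation grid used for estimation: 12 African
# bins (10 common deciles + low-frequency + rare) crossed with 10 European
# common-MAF deciles, i.e. 120 bivariate bins. A coarser display scheme
# (7 x 5) is available for visualisation.

#' Univariate MAF bin edges
#'
#' Builds the boundaries of a univariate MAF binning: SNPs are first
#' stratified into common (MAF >= 0.05), low-frequency (0.005 <= MAF < 0.05)
#' and rare (MAF < 0.005) categories; the common range is then split at
#' empirical quantiles (type 7, linear interpolation) of the reference MAFs
#' restricted to >= 0.05. Bins are left-closed/right-open with the last bin
#' right-closed at 0.5.
#'
#' @param reference_mafs Numeric vector of folded MAFs in `(0, 0.5]` used to
#'   place the common-bin quantile boundaries.
#' @param n_common_bins Number of common-MAF bins (5 or 10).
#' @param include_noncommon If `TRUE`, prepend the rare `(0, 0.005)` and
#'   low-frequency `[0.005, 0.05)` bins.
#' @return Numeric vector of strictly increasing bin edges ending at 0.5.
#' @export
#' @examples
#' maf_bin_edges(runif(1e4, 0.05, 0.5), 5, include_noncommon = FALSE)
maf_bin_edges <- function(reference_mafs, n_common_bins = 10,
                          include_noncommon = TRUE) {
  if (length(reference_mafs) == 0L) abort("`reference_mafs` must be non-empty.")
  if (!n_common_bins %in% c(5L, 10L)) {
    abort("`n_common_bins` must be 5 or 10.")
  }
  common <- reference_mafs[reference_mafs >= 0.05]
  if (length(unique(common)) < n_common_bins) {
    abort(sprintf(
      "Reference has only %d distinct common (>= 0.05) MAF values; %d bins requested.",
      length(unique(common)), n_common_bins))
  }
  probs <- seq_len(n_common_bins - 1L) / n_common_bins
  inner <- unname(quantile(common, probs, type = 7))
  edges <- c(0.05, inner, 0.5)
  if (any(diff(edges) <= 0)) abort("Degenerate common-bin edges (tied quantiles).")
  if (include_noncommon) edges <- c(0, 0.005, edges)
  edges
}

bin_labels_from_edges <- function(edges, prefix) {
  n <- length(edges) - 1L
  lab <- character(n)
  for (i in seq_len(n)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    lab[i] <- if (hi <= 0.005) sprintf("%s_rare", prefix)
      else if (hi <= 0.05) sprintf("%s_low", prefix)
      else sprintf("%s_c%02d", prefix, sum(edges[seq_len(i)] >= 0.05))
  }
  lab
}

#' Build a bivariate MAF binning scheme
#'
#' Crosses a univariate African scheme with a univariate European scheme.
#' The `"fit"` preset uses 10 common deciles per ancestry plus African
#' low-frequency and rare bins (12 x 10 = 120 bivariate bins, the estimation
#' grid); the `"display"` preset uses 5 common quintiles plus African
#' low-frequency/rare bins (7 x 5 = 35 bins) for heat tables.
#'
#' @param panel SNP panel tibble with `maf_afr`, `maf_eur`; its MAFs are the
#'   reference for the quantile boundaries.
#' @param preset `"fit"` or `"display"`, or `NULL` to use the explicit
#'   arguments below.
#' @param n_common_bins Common bins per ancestry when `preset` is `NULL`.
#' @param afr_noncommon,eur_noncommon Include rare/low-frequency bins for
#'   the respective ancestry.
#' @return An object of class `"binning_scheme"` with fields `afr_edges`,
#'   `eur_edges`, `afr_labels`, `eur_labels` and bivariate `labels`
#'   (African label crossed with European label).
#' @export
build_binning_scheme <- function(panel, preset = c("fit", "display"),
                                 n_common_bins = NULL, afr_noncommon = TRUE,
                                 eur_noncommon = FALSE) {
  assert_columns(panel, c("maf_afr", "maf_eur"), "`panel`")
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    n_common_bins <- n_common_bins %||% switch(preset, fit = 10L, display = 5L)
  } else if (is.null(n_common_bins)) {
    abort("Provide `n_common_bins` when `preset` is NULL.")
  }
  afr_edges <- maf_bin_edges(panel$maf_afr, n_common_bins, afr_noncommon)
  eur_edges <- maf_bin_edges(panel$maf_eur, n_common_bins, eur_noncommon)
  new_binning_scheme(afr_edges, eur_edges)
}

new_binning_scheme <- function(afr_edges, eur_edges) {
  afr_labels <- bin_labels_from_edges(afr_edges, "afr")
  eur_labels <- bin_labels_from_edges(eur_edges, "eur")
  grid <- expand.grid(afr = afr_labels, eur = eur_labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(list(afr_edges = afr_edges, eur_edges = eur_edges,
                 afr_labels = afr_labels, eur_labels = eur_labels,
                 labels = paste(grid$afr, grid$eur, sep = ":")),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %d African x %d European = %d bivariate bins\n",
              length(x$afr_labels), length(x$eur_labels), length(x$labels)))
  cat("  afr edges:", paste(signif(x$afr_edges, 3), collapse = " "), "\n")
  cat("  eur edges:", paste(signif(x$eur_edges, 3), collapse = " "), "\n")
  invisible(x)
}

# Left-closed/right-open interval index with the last bin right-closed.
bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, left.open = FALSE)
  idx[x == edges[length(edges)]] <- length(edges) - 1L
  idx[idx < 1L | idx > length(edges) - 1L] <- NA_integer_
  idx
}

#' Assign SNPs to bivariate MAF bins
#'
#' Maps each SNP to exactly one bivariate bin of `scheme`, or marks it
#' excluded when its MAF falls outside the scheme (e.g. European MAF below
#' 0.05 under a common-only European scheme). With `eur_common_only = TRUE`,
#' SNPs with `maf_eur < 0.05` are excluded from the trait-fit bins regardless
#' of the scheme, mirroring the restriction of heritability estimation to
#' common European SNPs.
#'
#' @param panel SNP panel tibble.
#' @param scheme A [build_binning_scheme()] result.
#' @param eur_common_only Exclude SNPs with European MAF below 0.05.
#' @return The panel with columns `bin_afr`, `bin_eur` and `bin` (factor with
#'   the scheme's bivariate labels as levels; `NA` when excluded).
#' @export
assign_bins <- function(panel, scheme, eur_common_only = FALSE) {
  stopifnot(inherits(scheme, "binning_scheme"))
  assert_columns(panel, c("maf_afr", "maf_eur"), "`panel`")
  ia <- bin_index(panel$maf_afr, scheme$afr_edges)
  ie <- bin_index(panel$maf_eur, scheme$eur_edges)
  if (eur_common_only) ie[panel$maf_eur < 0.05] <- NA_integer_
  bin_afr <- scheme$afr_labels[ia]
  bin_eur <- scheme$eur_labels[ie]
  bin <- ifelse(is.na(bin_afr) | is.na(bin_eur), NA_character_,
                paste(bin_afr, bin_eur, sep = ":"))
  dplyr::mutate(panel,
                bin_afr = factor(bin_afr, levels = scheme$afr_labels),
                bin_eur = factor(bin_eur, levels = scheme$eur_labels),
                bin = factor(bin, levels = scheme$labels))
}

#' Per-bin SNP counts and mean MAFs
#'
#' Summarises a bin-assigned panel into per-bivariate-bin counts and mean
#' folded MAFs. Because `pmix` is linear in `w`, the bin-mean mixture
#' frequency is `w * mean_pA + (1 - w) * mean_pE` exactly.
#'
#' @param panel A panel with a `bin` column from [assign_bins()].
#' @return Tibble with `bin`, `bin_afr`, `bin_eur`, `n_k`, `mean_pA`,
#'   `mean_pE` (excluded SNPs dropped; empty bins omitted).
#' @export
bin_summaries <- function(panel) {
  assert_columns(panel, c("bin", "maf_afr", "maf_eur"), "`panel`")
  panel |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .data$bin_afr, .data$bin_eur) |>
    dplyr::summarise(n_k = dplyr::n(),
                     mean_pA = mean(.data$maf_afr),
                     mean_pE = mean(.data$maf_eur),
                     .groups = "drop")
}

#' Export bin assignments as an annotation indicator matrix
#'
#' One indicator column per bivariate bin (LDSC-annot style); excluded SNPs
#' get an all-zero row. Empty bins are dropped so the matrix has full column
#' rank over the binned SNPs.
#'
#' @param panel A bin-assigned panel.
#' @param drop_empty Drop bins with no SNPs (default `TRUE`).
#' @return Numeric 0/1 matrix, SNPs by bins, with bin labels as column names.
#' @export
bin_annotations <- function(panel, drop_empty = TRUE) {
  assert_columns(panel, "bin", "`panel`")
  levs <- levels(panel$bin)
  if (drop_empty) levs <- levs[levs %in% as.character(panel$bin)]
  m <- matrix(0, nrow(panel), length(levs), dimnames = list(NULL, levs))
  idx <- match(as.character(panel$bin), levs)
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Serialise / restore a binning scheme
#'
#' Writes the edges as structured text (JSON) so jackknife replicates and
#' per-trait analyses reuse identical boundaries.
#'
#' @param scheme A `binning_scheme`.
#' @param path File path.
#' @return `write_binning_scheme()` returns `path` invisibly;
#'   `read_binning_scheme()` returns the scheme.
#' @export
write_binning_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "binning_scheme"))
  jsonlite::write_json(list(afr_edges = scheme$afr_edges,
                            eur_edges = scheme$eur_edges),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_binning_scheme
#' @export
read_binning_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_binning_scheme(as.numeric(x$afr_edges), as.numeric(x$eur_edges))
}
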