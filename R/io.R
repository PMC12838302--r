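# Text I/O: SNP panels, LDSC-dialect summary statistics, bin-variance
# tables, and study configurations. All numeric columns round-trip at full
# double precision.

fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

write_tsv_full <- function(df, path) {
  out <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double), fmt_full))
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read and write SNP panels
#'
#' Tab-separated with header; columns `snp_id`, `pos_index`, `freq_afr`,
#' `freq_eur`, `maf_afr`, `maf_eur` plus optional `nonsyn` and `beta`.
#' Reading validates that folded MAFs lie in `(0, 0.5]` and reports the
#' offending line numbers; an empty file with a header is an empty panel,
#' not an error. Numeric values round-trip losslessly.
#'
#' @param panel SNP panel tibble.
#' @param path File path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   the panel tibble.
#' @export
write_panel <- function(panel, path) {
  assert_columns(panel, c("snp_id", "pos_index", "freq_afr", "freq_eur",
                          "maf_afr", "maf_eur"), "`panel`")
  keep <- intersect(c("snp_id", "pos_index", "freq_afr", "freq_eur",
                      "maf_afr", "maf_eur", "nonsyn", "beta"), names(panel))
  write_tsv_full(panel[keep], path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             snp_id = readr::col_character(),
                             pos_index = readr::col_integer(),
                             .default = readr::col_double()))
  assert_columns(panel, c("snp_id", "pos_index", "freq_afr", "freq_eur",
                          "maf_afr", "maf_eur"), sprintf("Panel file '%s'", path))
  for (col in c("maf_afr", "maf_eur")) {
    bad <- which(!is.finite(panel[[col]]) | panel[[col]] <= 0 | panel[[col]] > 0.5)
    if (length(bad) > 0) {
      abort(sprintf("%s outside (0, 0.5] in '%s' at line(s): %s.",
                    col, path, paste(head(bad + 1L, 5), collapse = ", ")))
    }
  }
  panel
}

#' Read and write summary statistics in the LDSC dialect
#'
#' Tab-separated with one header line and columns `SNP`, `A1`, `A2`, `N`,
#' `Z`. The simulator does not track alleles, so placeholder alleles are
#' written; `read_sumstats()` returns the package's internal layout
#' (`snp_id`, `n`, `z`, `chi2`).
#'
#' @param sumstats Summary-statistics tibble (`snp_id`, `n`, `z`).
#' @param path File path.
#' @return `write_sumstats()` returns `path` invisibly; `read_sumstats()`
#'   the tibble.
#' @export
write_sumstats <- function(sumstats, path) {
  assert_columns(sumstats, c("snp_id", "n", "z"), "`sumstats`")
  out <- tibble(SNP = sumstats$snp_id, A1 = "A", A2 = "C",
                N = sumstats$n, Z = sumstats$z)
  write_tsv_full(out, path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           SNP = readr::col_character(),
                           A1 = readr::col_character(),
                           A2 = readr::col_character(),
                           N = readr::col_double(),
                           Z = readr::col_double()))
  assert_columns(raw, c("SNP", "N", "Z"), sprintf("Sumstats file '%s'", path))
  tibble(snp_id = raw$SNP, n = raw$N, z = raw$Z, chi2 = raw$Z^2)
}

#' Read and write bin-variance tables
#'
#' The exchange format between the bin-wise variance stage and the GMM
#' fitter: tab-separated columns `trait`, `bin`, `n_k`, `mean_pA`,
#' `mean_pE`, `beta2_hat` (plus optional `se`). Externally computed
#' bin-variance tables in this layout can be ingested directly.
#'
#' @param tables Bin-variance table tibble.
#' @param path File path.
#' @return `write_bin_table()` returns `path` invisibly; `read_bin_table()`
#'   the tibble.
#' @export
write_bin_table <- function(tables, path) {
  assert_columns(tables, c("trait", "bin", "n_k", "mean_pA", "mean_pE",
                           "beta2_hat"), "`tables`")
  out <- dplyr::mutate(tables, bin = as.character(.data$bin))
  write_tsv_full(out, path)
}

#' @rdname write_bin_table
#' @export
read_bin_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trait = readr::col_character(),
                           bin = readr::col_character(),
                           n_k = readr::col_integer(),
                           .default = readr::col_double()))
  assert_columns(out, c("trait", "bin", "n_k", "mean_pA", "mean_pE",
                        "beta2_hat"), sprintf("Bin table '%s'", path))
  out
}

#' Serialise / restore a generative configuration
#'
#' JSON round-trip of a [generative_config()]; `read_generative_config()`
#' re-validates, so an invalid stored configuration (e.g.
#' `n_causal > n_snps`) is rejected on read.
#'
#' @param config A `generative_config`.
#' @param path File path.
#' @return `write_generative_config()` returns `path` invisibly;
#'   `read_generative_config()` the validated config.
#' @export
write_generative_config <- function(config, path) {
  stopifnot(inherits(config, "generative_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generative_config
#' @export
read_generative_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(generative_config, x)
}
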