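# Internal helpers shared across modules.

# Derive a reproducible stream of sub-seeds from one master seed without
# disturbing the caller's RNG state. Values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Run `code` under `seed` when a seed is supplied, otherwise use the current
# RNG stream (so explicitly seeded pipelines stay byte-reproducible).
with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Format a p-value with the reporting floor
#'
#' P-values below `floor` are reported as a bound (`"<1e-15"` by default)
#' rather than as a number, the convention used throughout the package's
#' printed output.
#'
#' @param p Numeric vector of p-values.
#' @param floor Smallest p-value printed exactly.
#' @param digits Significant digits for values above the floor.
#' @return Character vector.
#' @export
#' @examples
#' format_pvalue(c(0.03, 1e-20))
format_pvalue <- function(p, floor = 1e-15, digits = 3) {
  out <- ifelse(p < floor,
                paste0("<", format(floor, scientific = TRUE)),
                format(signif(p, digits), scientific = (p < 1e-4)))
  out[is.na(p)] <- NA_character_
  out
}
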