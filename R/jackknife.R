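# Genomic block jackknife: contiguous blocks in positional order, delete-one
# re-estimation, and the usual (B-1)/B variance formula.

#' Contiguous jackknife block assignment
#'
#' Splits observations into `n_blocks` blocks that are contiguous in
#' `pos_index` with counts differing by at most one.
#'
#' @param pos_index Numeric positional index (genomic order proxy).
#' @param n_blocks Number of blocks (default 200).
#' @return Integer vector of block ids, aligned with `pos_index`.
#' @export
jackknife_blocks <- function(pos_index, n_blocks = 200) {
  n <- length(pos_index)
  if (n_blocks > n) {
    abort(sprintf("n_blocks (%d) exceeds the number of observations (%d).",
                  n_blocks, n))
  }
  sizes <- rep(n %/% n_blocks, n_blocks)
  extra <- n %% n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  blocks <- integer(n)
  blocks[order(pos_index)] <- rep.int(seq_len(n_blocks), sizes)
  blocks
}

#' Block-jackknife a statistic of a positional data set
#'
#' Re-computes `statistic` on the data with each block deleted in turn and
#' returns delete-one estimates, jackknife standard errors
#' (`SE^2 = (B-1)/B * sum_b (theta_b - mean)^2`), normal 95% confidence
#' intervals, and optionally two-sided normal p-values against stated null
#' values. A zero jackknife SE with an estimate equal to the null is reported
#' as p = 1 rather than 0/0.
#'
#' @param data A data frame containing `pos_col`.
#' @param statistic Function `data -> named numeric vector` (the full
#'   pipeline being jackknifed).
#' @param n_blocks Number of contiguous blocks (default 200).
#' @param pos_col Name of the positional column (default `"pos_index"`).
#' @param null_values Optional named list/vector of null values per term;
#'   terms absent from it get no p-value.
#' @return A tibble with `term`, `estimate`, `se`, `ci_lo`, `ci_hi` and
#'   (when nulls are supplied) `null`, `p_value`; the delete-one estimates
#'   are attached as attribute `"jackknife"`.
#' @export
block_jackknife <- function(data, statistic, n_blocks = 200,
                            pos_col = "pos_index", null_values = NULL) {
  assert_columns(data, pos_col, "`data`")
  blocks <- jackknife_blocks(data[[pos_col]], n_blocks)
  full <- statistic(data)
  if (is.null(names(full))) names(full) <- paste0("theta", seq_along(full))
  theta <- matrix(NA_real_, n_blocks, length(full),
                  dimnames = list(NULL, names(full)))
  for (b in seq_len(n_blocks)) {
    theta[b, ] <- statistic(data[blocks != b, , drop = FALSE])
  }
  se <- jackknife_se(theta)
  out <- tibble(term = names(full), estimate = unname(full), se = unname(se),
                ci_lo = unname(full - 1.96 * se),
                ci_hi = unname(full + 1.96 * se))
  if (!is.null(null_values)) {
    nv <- unlist(null_values)
    out$null <- unname(nv[out$term])
    out$p_value <- jackknife_pvalue(out$estimate, out$se, out$null)
  }
  attr(out, "jackknife") <- theta
  out
}

jackknife_se <- function(theta) {
  b <- nrow(theta)
  center <- colMeans(theta)
  sqrt((b - 1) / b * colSums((theta - rep(center, each = b))^2))
}

jackknife_pvalue <- function(estimate, se, null) {
  p <- rep(NA_real_, length(estimate))
  ok <- !is.na(null)
  zero <- ok & se == 0
  p[zero] <- ifelse(estimate[zero] == null[zero], 1, 0)
  pos <- ok & se > 0
  p[pos] <- 2 * pnorm(-abs(estimate[pos] - null[pos]) / se[pos])
  p
}
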