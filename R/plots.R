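# ggplot2 presentation of the package's result types.

#' Heat table of the proportion of non-synonymous SNPs
#'
#' Bivariate-bin heat table (African MAF bins as rows, European as columns)
#' with the per-bin PNS printed in each cell; cell values are exactly the
#' underlying table entries.
#'
#' @param object A [pns_by_bins()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pns_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_eur, y = .data$bin_afr,
                                       fill = .data$pns)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", 100 * .data$pns)),
                       size = 2.8) +
    ggplot2::scale_fill_viridis_c(name = "PNS") +
    ggplot2::labs(x = "European MAF bin", y = "African MAF bin",
                  title = "Proportion of non-synonymous SNPs by bivariate MAF bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Profile likelihood curve for the mixture weight
#'
#' Negative profile log-likelihood against `w`, with the MLE marked; the
#' marker is placed at the fit's reported maximiser.
#'
#' @param object A [maximize_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$w, y = -.data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$w_mle, colour = "red") +
    ggplot2::annotate("point", x = object$w_mle, y = -object$loglik_mle,
                      colour = "red") +
    ggplot2::labs(x = "mixture weight w", y = "negative profile log-likelihood",
                  subtitle = sprintf("w_mle = %.3f (95%% CI %.3f, %.3f)",
                                     object$w_mle, object$ci95[1],
                                     object$ci95[2])) +
    ggplot2::theme_minimal()
}

#' Exponent and scaled-MSE profiles over the mixture weight
#'
#' Either the weighted scaled MSE curve (null model at 1) or the best-fit
#' exponent as a function of `w`, with the curve minimum marked.
#'
#' @param object A [profile_alpha_over_w()] result.
#' @param what `"scaled_mse"` or `"alpha"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.alphamix_profile <- function(object, what = c("scaled_mse", "alpha"),
                                      ...) {
  what <- match.arg(what)
  best <- object[which.min(object$loss), ]
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$w, y = .data[[what]])) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = best$w, colour = "red") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "mixture weight w",
                  y = if (what == "scaled_mse") "weighted scaled MSE"
                      else "best-fit exponent")
  if (what == "scaled_mse") {
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = "dashed")
  }
  p
}

#' Simulation-study estimates with confidence intervals
#'
#' Mean estimated mixture weight and exponent per generative weight, with
#' 95% CIs of the mean across replicates and the true values marked in red.
#'
#' @param object A [run_simulation_study()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.alphamix_study <- function(object, ...) {
  s <- object$summary
  long <- dplyr::bind_rows(
    tibble(true_w = s$true_w, param = "w", mean = s$mean_w,
           lo = s$ci_lo_w, hi = s$ci_hi_w, truth = s$true_w),
    tibble(true_w = s$true_w, param = "alpha", mean = s$mean_alpha,
           lo = s$ci_lo_alpha, hi = s$ci_hi_alpha,
           truth = object$alpha_true))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$true_w), y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$truth), colour = "red",
                        shape = 95, size = 8) +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "true mixture weight", y = "mean estimate") +
    ggplot2::theme_minimal()
}
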