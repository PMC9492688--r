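# ggplot2 helpers for the main result types.

#' Plot a strand cross-correlation curve
#'
#' @param xcor Tibble from [strand_cross_correlation()].
#' @return A ggplot; a dimeric-transposase library shows a peak at 9 bp.
#' @export
plot_cross_correlation <- function(xcor) {
  ggplot2::ggplot(xcor, ggplot2::aes(x = .data$shift, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "strand shift (bp)", y = "Pearson correlation") +
    ggplot2::theme_minimal()
}

#' Scatter comparison of two bias tables
#'
#' Median-centers both tables and plots matched k-mers against each other,
#' annotating the Pearson correlation.
#'
#' @param x,y Bias tables over the same k.
#' @param xlab,ylab Axis labels.
#' @return A ggplot.
#' @export
plot_bias_comparison <- function(x, y, xlab = "bias score (x)",
                                 ylab = "bias score (y)") {
  xc <- center_scores(x); yc <- center_scores(y)
  d <- dplyr::inner_join(
    tibble::tibble(kmer = xc$kmer, sx = xc$score),
    tibble::tibble(kmer = yc$kmer, sy = yc$score),
    by = "kmer"
  )
  r <- .pearson(d$sx, d$sy)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sx, y = .data$sy)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::geom_abline(linetype = 2, color = "grey50") +
    ggplot2::labs(x = xlab, y = ylab,
                  subtitle = sprintf("R = %.3f (n = %d k-mers)", r, nrow(d))) +
    ggplot2::theme_minimal()
}

#' Plot an aggregate footprint profile
#'
#' @param agg Tibble from [aggregate_profile()].
#' @return A ggplot with both strands; spike anchors sit at the
#'   left/right `offset = 0` positions.
#' @export
plot_aggregate_profile <- function(agg) {
  d <- tidyr::pivot_longer(agg, c("plus", "minus"),
                           names_to = "strand", values_to = "signal")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$signal,
                                  color = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = range(which(agg$segment == "center")) + c(-1, 1),
                        linetype = 3, color = "grey40") +
    ggplot2::labs(x = "footprint frame (flank | spike | scaled center | spike | flank)",
                  y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot for a simplex bias fit
#'
#' Observed naive scores against model-fitted scores for the training
#' k-mers.
#'
#' @param object A `selma_fit`.
#' @param naive The naive bias table the fit was trained on.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selma_fit <- function(object, naive, ...) {
  keep <- is.finite(naive$score)
  d <- tibble::tibble(observed = naive$score[keep],
                      fitted = predict(object, naive$kmer[keep]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(color = "red") +
    ggplot2::labs(x = "model bias score", y = "naive bias score") +
    ggplot2::theme_minimal()
}

#' Plot the ANOVA contribution profile
#'
#' @param profile Tibble from [anova_contribution_profile()].
#' @param alpha,beta Overlay the Beta weight with these shapes (default
#'   2, 3); use `NULL` to suppress.
#' @return A ggplot of median qualifying F per PBS percentile.
#' @export
plot_anova_profile <- function(profile, alpha = 2, beta = 3) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$x, y = .data$median_f)) +
    ggplot2::geom_col(width = 0.009, fill = "grey60") +
    ggplot2::labs(x = "PBS percentile", y = "median F (qualifying peaks)") +
    ggplot2::theme_minimal()
  if (!is.null(alpha)) {
    mx <- max(profile$median_f, na.rm = TRUE)
    wx <- tibble::tibble(x = seq(0, 0.99, 0.01))
    wx$w <- beta_weight(wx$x, alpha, beta) * mx / beta_weight((alpha - 1) / (alpha + beta - 2), alpha, beta)
    p <- p + ggplot2::geom_line(data = wx, ggplot2::aes(y = .data$w), color = "red")
  }
  p
}
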