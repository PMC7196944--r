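#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' Conventional NMR orientation: the ppm axis decreases to the right.
#'
#' @param object A spectrum.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  m <- spectrum_meta(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity",
                  title = m$sample_id, subtitle = m$method) +
    ggplot2::theme_minimal()
}

#' Plot PCA scores coloured by group
#'
#' @param object An [pca()] result with sample metadata.
#' @param components Which two components to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmr_pca <- function(object, components = c(1, 2), ...) {
  sc <- object$scores
  xy <- paste0("PC", components)
  lab <- sprintf("%s (%.1f%%)", xy, 100 * object$explained_variance_ratio[components])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[xy[1]]], y = .data[[xy[2]]]))
  if ("group" %in% names(sc))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  else p <- p + ggplot2::geom_point(size = 2)
  p + ggplot2::labs(x = lab[1], y = lab[2]) + ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Per-pair differences against means, with the bias line and 1.96-sd limits
#' of agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = object$limits, linetype = 2) +
    ggplot2::labs(x = "mean of methods", y = "difference (NMR - reference)") +
    ggplot2::theme_minimal()
}

#' VIP score plot
#'
#' VIP scores by chemical shift with the importance threshold.
#'
#' @param object A [vip_scores()] signature.
#' @param threshold Threshold line (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vip_signature <- function(object, threshold = 1, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$vip,
                                       colour = .data$important)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$ppm, yend = 0)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "VIP") +
    ggplot2::theme_minimal()
}
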