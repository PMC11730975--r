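#' Plot a stimulus image
#'
#' @param img A [vd_image()].
#' @param degrees Label axes in degrees of visual angle (default) rather
#'   than pixels.
#' @return A ggplot.
#' @export
plot_stimulus <- function(img, degrees = TRUE) {
  px <- img$pixels
  sc <- if (degrees) 1 / img$ppd else 1
  df <- tidyr::expand_grid(y = seq_len(nrow(px)), x = seq_len(ncol(px)))
  df$luminance <- as.numeric(px)
  ggplot2::ggplot(df, ggplot2::aes(.data$x * sc, .data$y * sc,
                                   fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = if (degrees) "degrees" else "px",
                  y = if (degrees) "degrees" else "px",
                  title = img$category) +
    ggplot2::theme_minimal()
}

#' Scree plot of a PCA result
#'
#' @param object A `vd_pca`.
#' @param ... Unused.
#' @return A ggplot (eigenvalues against component, Kaiser line at 1).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.vd_pca <- function(object, ...) {
  df <- glance(object)
  df$k <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$retained), size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = df$k,
                                labels = df$component) +
    ggplot2::labs(x = NULL, y = "eigenvalue",
                  title = "Scree plot (Kaiser criterion at 1)") +
    ggplot2::theme_minimal()
}

#' Power-spectrum plot of a Welch PSD
#'
#' @param object A `vd_psd` from [welch_psd()].
#' @param channels Optional channel labels to keep.
#' @param fmax Upper frequency limit for the plot (Hz).
#' @param ... Unused.
#' @return A ggplot of log power against frequency per channel.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.vd_psd <- function(object, channels = NULL, fmax = 40, ...) {
  labs <- if (is.null(object$labels))
    sprintf("ch%02d", seq_len(nrow(object$psd))) else object$labels
  df <- tibble::tibble(
    channel = rep(labs, times = length(object$freq)),
    freq = rep(object$freq, each = nrow(object$psd)),
    power = as.numeric(object$psd))
  if (!is.null(channels)) df <- df[df$channel %in% channels, ]
  df <- df[df$freq > 0 & df$freq <= fmax, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$power,
                                   color = .data$channel)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD~(mu*V^2/Hz))) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a mixed-model fit
#'
#' @param object A `vd_fit`.
#' @param ... Unused.
#' @return A ggplot of estimates with confidence intervals (intercept
#'   omitted).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.vd_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
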