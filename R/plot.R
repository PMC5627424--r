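#' Display a thermogram
#'
#' Raster display of the temperature field with an optional mask contour
#' overlay, on the image convention (row 1 at the top).
#'
#' @param tg a [thermogram()].
#' @param mask optional logical matrix drawn as an overlay.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_thermogram <- function(tg, mask = NULL, title = NULL) {
  stopifnot(is_thermogram(tg))
  df <- as.data.frame(tg)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$temp_c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "°C") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(mask) && any(mask)) {
    check_mask(mask, dim(tg$temps))
    md <- data.frame(which(mask, arr.ind = TRUE))
    p <- p + ggplot2::geom_tile(data = md,
      ggplot2::aes(x = .data$col, y = .data$row), fill = NA,
      colour = "cyan", linewidth = 0.2, inherit.aes = FALSE)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.otsu_detection <- function(object, ...) {
  md <- data.frame(which(object$region_mask, arr.ind = TRUE))
  ggplot2::ggplot(md, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(fill = "red", alpha = 0.8) +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Otsu mean difference: %s (mu_d = %.1f degC)",
                                  object$decision, object$mu_d),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.p2p_detection <- function(object, ...) {
  d <- object$diff_map
  df <- data.frame(row = rep.int(seq_len(nrow(d)), ncol(d)),
                   col = rep(seq_len(ncol(d)), each = nrow(d)),
                   diff_c = as.vector(abs(d)))
  df <- df[!is.na(df$diff_c), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$diff_c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "|ΔT| °C") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Point-to-point difference: %s", object$decision),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (any(object$hyper_mask)) {
    md <- data.frame(which(object$hyper_mask, arr.ind = TRUE))
    p <- p + ggplot2::geom_tile(data = md,
      ggplot2::aes(x = .data$col, y = .data$row), fill = NA, colour = "red",
      linewidth = 0.3, inherit.aes = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
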