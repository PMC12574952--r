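#' Plot an association track
#'
#' r over time with a gray bar at FDR-significant points and, when Bayes
#' factors are present, a log10(BF) colour strip underneath.
#'
#' @param track an \code{association_track}.
#' @return A ggplot object.
#' @export
plot_association_track <- function(track) {
  df <- as.data.frame(track)
  ymin <- min(df$r, na.rm = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time_ms, y = r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$fdr_sig, , drop = FALSE],
                        ggplot2::aes(y = ymin - 0.05), shape = 15,
                        colour = "grey40", size = 0.8) +
    ggplot2::labs(x = "Time (ms)", y = "r",
                  title = sprintf("%s correlation (n = %d)", track$kind,
                                  track$n)) +
    ggplot2::theme_minimal()
  if (!all(is.na(df$bf)))
    p <- p + ggplot2::geom_tile(
      ggplot2::aes(y = ymin - 0.12, fill = log10(bf)), height = 0.04) +
      ggplot2::scale_fill_viridis_c(name = "log10 BF")
  p
}

#' Plot a dominance decomposition track
#'
#' Stacked per-predictor total-dominance shares over time.
#'
#' @param track a \code{dominance_track}.
#' @return A ggplot object.
#' @export
plot_dominance_track <- function(track) {
  df <- as.data.frame(track)
  long <- data.frame(
    time_ms = rep(df$time_ms, 2L),
    share = c(df$td_var, df$td_amp),
    predictor = rep(c("variability", "amplitude"), each = nrow(df)))
  ggplot2::ggplot(long, ggplot2::aes(x = time_ms, y = share,
                                     fill = predictor)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Time (ms)", y = expression(R^2~share)) +
    ggplot2::theme_minimal()
}

#' Plot a power map
#'
#' Heat map of detection probability over (size x time) with the 80%
#' contour.
#'
#' @param map a \code{power_map}.
#' @param threshold contour level (default 0.8).
#' @return A ggplot object.
#' @export
plot_power_map <- function(map, threshold = 0.8) {
  df <- as.data.frame(map)
  ggplot2::ggplot(df, ggplot2::aes(x = time_ms, y = size,
                                   fill = prob)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = prob), breaks = threshold,
                          colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "P(significant)", limits = c(0, 1)) +
    ggplot2::labs(x = "Time (ms)", y = map$axis) +
    ggplot2::theme_minimal()
}
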