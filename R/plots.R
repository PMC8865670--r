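#' Plot PARAFAC component loadings
#'
#' Faceted view of the loading vectors of every component across the five
#' modes (source layer, target layer, time, frequency, connection).
#'
#' @param object a `parafac_model`.
#' @param modes subset of modes to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.parafac_model <- function(object,
                                   modes = c("source_layer", "target_layer",
                                             "time", "freq"), ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$mode %in% modes) |>
    dplyr::mutate(component = factor(.data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$loading,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mode, scales = "free") +
    ggplot2::labs(x = NULL, y = "loading") +
    ggplot2::theme_minimal()
}

#' Time-frequency image of a connectivity tensor
#'
#' Averages the five-way tensor over layers and connections and shows the
#' resulting time-frequency map of directed interaction strength.
#'
#' @param object a `conn_tensor`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.conn_tensor <- function(object, ...) {
  tf <- apply(object$values, c(3, 4), mean)
  df <- tidyr::expand_grid(time = object$time, freq = object$freqs)
  df$value <- as.numeric(tf)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "iPDC") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Temporal percent-change curves per component
#'
#' @param temporal tibble from [temporal_stats()] rows bound over
#'   components (column `component` present).
#' @return A ggplot object.
#' @export
plot_temporal_dynamics <- function(temporal) {
  ggplot2::ggplot(temporal, ggplot2::aes(x = .data$time, y = .data$pct_change)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pct_change - .data$sd,
                                      ymax = .data$pct_change + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude change (%)") +
    ggplot2::theme_minimal()
}
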