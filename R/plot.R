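# Plotting: raster views of theziograms and marker summaries.

#' Plot a theziogram as a raster map
#'
#' @param object A `theziogram`.
#' @param ... Unused.
#' @return A ggplot object; masked pixels are blank.
#' @export
autoplot.theziogram <- function(object, ...) {
  df <- as_tibble(object)
  df$value[!df$mask] <- NA_real_
  plane <- if (is.infinite(df$phase_plane[1])) "integral"
           else sprintf("phi[k] == %.3g", df$phase_plane[1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s theziogram (%s)", object$parameter, plane),
                  x = "b", y = "a", fill = object$parameter) +
    ggplot2::theme_minimal()
}

#' Marker trends across phase planes
#'
#' Displays the four statistical moments of one parameter against the phase
#' plane, one line per sample, colored by group — the visual form of the
#' layer-by-layer scanning scenario.
#'
#' @param markers Marker tibble from [marker_table()].
#' @param parameter Which parameter to show (default `"LB"`).
#' @return A ggplot object.
#' @export
plot_marker_trends <- function(markers, parameter = "LB") {
  df <- markers[markers$parameter == parameter & is.finite(markers$phase_plane), ]
  if (!nrow(df)) .stop_jtez("no sectioned markers for this parameter", "jtez_invalid_argument")
  long <- tidyr_pivot(df)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$phase_plane, y = .data$value,
                               group = .data$sample_id, colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~.data$moment, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "phase plane (rad, decreasing)", y = NULL,
                  title = sprintf("Moment markers of %s across phase planes", parameter)) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  parts <- lapply(c("z1", "z2", "z3", "z4"), function(m) {
    tibble::tibble(sample_id = df$sample_id, group = df$group,
                   phase_plane = df$phase_plane, moment = m, value = df[[m]])
  })
  dplyr::bind_rows(parts)
}
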