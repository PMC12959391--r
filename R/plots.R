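# ggplot2 views of the main result types.

#' Plot methods
#'
#' `autoplot()` methods: angle and sensor streams as faceted traces,
#' spectra as amplitude stems, calibration reports as the polar per-joint
#' accuracy bar plot, classification reports as a confusion heat map.
#'
#' @param object The object to plot.
#' @param columns Optional subset of trace columns to show.
#' @param max_columns Trace panels to show when `columns` is NULL.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-stretchsuit
NULL

stream_autoplot <- function(object, columns, max_columns, value_name) {
  cols <- columns %||% utils::head(setdiff(names(object),
                                           c("time_s", "label", "split")),
                                   max_columns)
  long <- tidyr::pivot_longer(object[, c("time_s", cols)], -"time_s",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = value_name)
}

#' @rdname autoplot-stretchsuit
#' @method autoplot angle_stream
#' @export
autoplot.angle_stream <- function(object, columns = NULL, max_columns = 6, ...) {
  stream_autoplot(object, columns, max_columns, "angle (deg)")
}

#' @rdname autoplot-stretchsuit
#' @method autoplot sensor_stream
#' @export
autoplot.sensor_stream <- function(object, columns = NULL, max_columns = 6, ...) {
  stream_autoplot(object, columns, max_columns, "capacitance (pF)")
}

#' @rdname autoplot-stretchsuit
#' @method autoplot spectrum_profile
#' @export
autoplot.spectrum_profile <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$frequency_hz, y = .data$amplitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency_hz, yend = 0),
                          linewidth = 0.4) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "amplitude")
}

#' @rdname autoplot-stretchsuit
#' @method autoplot calib_report
#' @export
autoplot.calib_report <- function(object, ...) {
  ggplot2::ggplot(object$per_dof,
                  ggplot2::aes(x = .data$dof, y = .data$mae_deg,
                               fill = .data$joint)) +
    ggplot2::geom_col() +
    ggplot2::coord_polar() +
    ggplot2::labs(y = "MAE (deg)", x = NULL,
                  title = "Spatial distribution of calibration error") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
}

#' @rdname autoplot-stretchsuit
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("accuracy %.3f", object$accuracy)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot-stretchsuit
#' @method autoplot suit_design
#' @export
autoplot.suit_design <- function(object, ...) {
  paths <- purrr::map_dfr(seq_len(nrow(object$sensors)), function(i) {
    p <- object$sensors$path_pos[[i]]
    tibble::tibble(channel = object$sensors$channel[i],
                   joint = object$sensors$joint[i],
                   x = p[, 1], y = p[, 2], z = p[, 3])
  })
  ggplot2::ggplot(paths, ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$channel,
                                      colour = .data$joint)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = "Sensor paths (frontal projection)")
}
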