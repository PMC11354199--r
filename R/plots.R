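#' Plot the pixel-averaged power spectrum
#'
#' @param object a [pixel_power_spectra()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot spectrum_stack
#' @export
autoplot.spectrum_stack <- function(object, ...) {
  df <- tibble(freq_hz = object$freqs, power = rowMeans(object$psd))
  df <- df[df$freq_hz > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Mean one-sided PSD",
                  title = "Pixel-averaged power spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a dominant-frequency heat map
#'
#' Color gradient indicates faster vs. slower per-pixel beat
#' frequency; undefined pixels are blank.
#'
#' @param object a [dominant_frequency_map()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cbf_map
#' @export
autoplot.cbf_map <- function(object, ...) {
  m <- object$map
  df <- tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(seq_len(nrow(m)), ncol(m)),
    freq_hz = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$freq_hz)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "CBF (Hz)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-pixel dominant frequency") +
    ggplot2::theme_minimal()
}

#' Plot a CBF histogram
#'
#' @param object a `cbf_distribution` from [cbf_histogram()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cbf_distribution
#' @export
autoplot.cbf_distribution <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center_hz,
                                   y = .data$percentage)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9) +
    ggplot2::labs(x = "CBF (Hz)", y = "% of analyzed pixels",
                  title = "CBF distribution") +
    ggplot2::theme_minimal()
}

#' Plot a beat trace with detected landmarks
#'
#' @param object a [beat_trace()].
#' @param landmarks optional [detect_beat_landmarks()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot beat_trace
#' @export
autoplot.beat_trace <- function(object, landmarks = NULL, ...) {
  df <- tibble(time_s = (seq_along(object$values) - 1) / object$fps,
               intensity = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "ROI mean intensity",
                  title = "Beat trace") +
    ggplot2::theme_minimal()
  if (!is.null(landmarks)) {
    lf <- tibble(time_s = (landmarks$frame - 1) / object$fps,
                 intensity = landmarks$value)
    p <- p + ggplot2::geom_point(data = lf, color = "red", size = 1.5)
  }
  p
}

#' Plot a comparison report
#'
#' Group medians with IQR whiskers, one panel row per method.
#'
#' @param object a `cbf_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cbf_report
#' @export
autoplot.cbf_report <- function(object, ...) {
  s <- object$summary
  long <- dplyr::bind_rows(
    tibble(method = s$method, group = "PCD", median = s$median_pcd,
           iqr = s$iqr_pcd),
    tibble(method = s$method, group = "HC", median = s$median_hc,
           iqr = s$iqr_hc)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$median,
                                     color = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$median - .data$iqr / 2,
                                        ymax = .data$median + .data$iqr / 2),
                           width = 0.15) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(y = "Median CBF (Hz)", x = NULL,
                  title = "Cohort comparison") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
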