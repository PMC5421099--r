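## Waveform plots

#' Plot a PPG waveform
#'
#' @param object a `ppg_signal`.
#' @param ... unused.
#' @returns a ggplot of amplitude over time.
#' @exportS3Method ggplot2::autoplot
autoplot.ppg_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Time [s]", y = "PPG [a.u.]") +
    ggplot2::theme_minimal()
}

#' Plot an APG waveform, optionally with detected fiducials
#'
#' @param object an `apg_signal`.
#' @param fiducials optional table from [detect_fiducials()]; the a-e
#'   waves of each beat are marked.
#' @param ... unused.
#' @returns a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.apg_signal <- function(object, fiducials = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(colour = "navy") +
    ggplot2::labs(x = "Time [s]", y = "APG [a.u./s²]") +
    ggplot2::theme_minimal()
  if (!is.null(fiducials) && nrow(fiducials)) {
    pts <- tidyr::pivot_longer(
      fiducials,
      cols = tidyr::starts_with("t_"),
      names_to = "wave", names_prefix = "t_", values_to = "latency")
    hts <- tidyr::pivot_longer(
      fiducials,
      cols = tidyr::starts_with("h_"),
      names_to = "wave", names_prefix = "h_", values_to = "height")
    pts$height <- hts$height
    pts <- pts[!is.na(pts$latency), ]
    pts$time <- pts$onset_time + pts$latency
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$time,
                                              y = .data$height,
                                              colour = .data$wave),
                                 size = 2)
  }
  p
}
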