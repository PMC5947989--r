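#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a frame of a coarse movie
#'
#' @param object A `coarse_loom`.
#' @param frame Frame index.
#' @param ... Unused.
#' @return A ggplot raster of pixel luminances at their (possibly
#'   jittered) screen positions.
#' @exportS3Method ggplot2::autoplot
autoplot.coarse_loom <- function(object, frame = ncol(object$luminance), ...) {
  lay <- object$layout[order(object$layout$pixel), ]
  df <- tibble::tibble(az = lay$az, el = lay$el,
                       luminance = object$luminance[, frame])
  ggplot2::ggplot(df, ggplot2::aes(.data$az, .data$el,
                                   fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  fill = "gray level",
                  title = sprintf("frame %d (t = %.3f s)", frame,
                                  object$frame_times[frame]))
}

#' Plot simulated voltage traces
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot of voltage versus time per recorded site.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_result <- function(object, ...) {
  ggplot2::ggplot(object$voltage,
                  ggplot2::aes(.data$time_ms, .data$v_mV,
                               color = factor(.data$comp))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  color = "compartment")
}

#' Plot a coherence-preference fit
#'
#' @param object A [coherence_preference()] result.
#' @param ... Unused.
#' @return A ggplot of responses versus coherence with the fitted line.
#' @exportS3Method ggplot2::autoplot
autoplot.coherence_preference <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$coherence,
                                            .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::labs(x = "stimulus coherence (%)", y = "spike count",
                  subtitle = sprintf("slope %.3g spikes/%% (r = %.2f)",
                                     object$slope, object$pearson_r))
}

#' Plot a coherence sweep across blockade conditions
#'
#' @param object A [run_coherence_sweep()] result.
#' @param ... Unused.
#' @return A ggplot of spike count versus coherence per condition.
#' @exportS3Method ggplot2::autoplot
autoplot.coherence_sweep <- function(object, ...) {
  ggplot2::ggplot(object$responses,
                  ggplot2::aes(.data$coherence, .data$spike_count,
                               color = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "stimulus coherence (%)", y = "spike count")
}

#' Plot a smoothed firing-rate profile
#'
#' @param spike_times Spike times (ms).
#' @param window Time window `c(from, to)` in ms.
#' @param kernel_sd_ms Gaussian kernel standard deviation.
#' @return A ggplot of the instantaneous firing rate.
#' @export
plot_firing_rate <- function(spike_times, window = NULL, kernel_sd_ms = 20) {
  fr <- firing_rate(spike_times, t_range = window,
                    kernel_sd_ms = kernel_sd_ms)
  ggplot2::ggplot(fr, ggplot2::aes(.data$time_ms, .data$rate_spk_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "firing rate (spk/s)")
}
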