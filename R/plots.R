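#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity trace
#'
#' @param object An `intensity_trace` from [spectrogram_power()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$power_db)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "in-band power (dB re 1.0)",
                  title = "Framewise speech intensity") +
    ggplot2::theme_minimal()
}

#' Plot a pitch track
#'
#' Voiced frames as points (f0), unvoiced frames marked along the axis.
#'
#' @param object A `pitch_track` from [track_pitch()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pitch_track <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$f0)) +
    ggplot2::geom_point(data = object[object$voiced, ],
                        ggplot2::aes(colour = .data$strength)) +
    ggplot2::geom_rug(data = object[!object$voiced, ], sides = "b",
                      alpha = 0.4) +
    ggplot2::ylim(cfg$floor, cfg$ceiling) +
    ggplot2::labs(x = "time (s)", y = "f0 (Hz)",
                  title = "Pitch track (rug: unvoiced frames)") +
    ggplot2::theme_minimal()
}

#' Plot a formant track
#'
#' @param object A `formant_track` from [lpc_formant_track()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.formant_track <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time", grep("^f", names(object), value = TRUE))],
    -"time", names_to = "formant", values_to = "frequency"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$frequency,
                                     colour = .data$formant)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  title = "LPC formant track") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap resampling distribution
#'
#' Histogram of the resampled mean differences with the widest-alpha
#' confidence interval and the observed difference marked.
#'
#' @param object A `bootstrap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  df <- tibble::tibble(diff = object$resamples)
  ci <- object$ci[1, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$diff)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(ci$lower, ci$upper),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$observed_diff,
                        colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey30") +
    ggplot2::labs(x = "difference in means",
                  y = "resamples",
                  title = sprintf("Bootstrap distribution (%s)",
                                  significance_stars(object))) +
    ggplot2::theme_minimal()
}

#' Per-word intensity-change scatter
#'
#' Each point is one word, coloured by its clinical intensity-change band.
#'
#' @param intensity_comparison The `intensity_comparison` tibble from
#'   [run_speech_pipeline()].
#' @return A ggplot.
#' @export
plot_intensity_change <- function(intensity_comparison) {
  ggplot2::ggplot(intensity_comparison,
                  ggplot2::aes(.data$mean_off_db, .data$delta_db,
                               colour = .data$category)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(-5, 0, 5), linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(
      large_decrease = "goldenrod", decrease = "khaki3",
      increase = "skyblue", large_increase = "darkblue"
    ), drop = FALSE) +
    ggplot2::labs(x = "OFF intensity (dB)", y = "ON - OFF (dB)",
                  title = "Per-word intensity change") +
    ggplot2::theme_minimal()
}
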