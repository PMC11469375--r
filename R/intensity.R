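#' Speech-intensity analysis configuration
#'
#' @param window Analysis window length in seconds (Hann). Default 0.025.
#' @param hop Frame hop in seconds. Default 0.005.
#' @param band_low,band_high Frequency band summed for total power, Hz.
#'   Defaults 50 and 10000; `band_high` is clipped to Nyquist at use time.
#' @param median_filter_len Odd window length of the 1-D median filter applied
#'   to the framewise trace. Default 3.
#' @param floor_db Power floor in dB (re 1.0) applied inside the log. Default -120.
#' @return A list of class `intensity_config`.
#' @export
intensity_config <- function(window = 0.025, hop = 0.005, band_low = 50,
                             band_high = 10000, median_filter_len = 3,
                             floor_db = -120) {
  stopifnot(hop > 0, hop <= window, band_low < band_high,
            median_filter_len %% 2 == 1)
  structure(list(window = window, hop = hop, band_low = band_low,
                 band_high = band_high, median_filter_len = median_filter_len,
                 floor_db = floor_db),
            class = "intensity_config")
}

#' Framewise in-band spectral power of a recording
#'
#' Decomposes the signal into a short-time spectrogram (Hann window, FFT
#' length the next power of two at or above the window length) and returns
#' per-frame total power in dB over `[band_low, band_high]`.
#'
#' @param rec An [audio_recording()].
#' @param config An [intensity_config()].
#' @return A tibble of class `intensity_trace` with columns `time` (frame
#'   start, seconds) and `power_db`.
#' @export
spectrogram_power <- function(rec, config = intensity_config()) {
  stopifnot(inherits(rec, "audio_recording"))
  if (length(rec$samples) == 0) stop("empty recording", call. = FALSE)
  band_high <- config$band_high
  if (band_high > rec$rate / 2) band_high <- rec$rate / 2

  win_n <- round(config$window * rec$rate)
  hop_n <- max(1L, round(config$hop * rec$rate))
  nfft <- 2^ceiling(log2(win_n))
  w <- hann_window(win_n)
  eps <- 10^(config$floor_db / 10)

  starts <- seq(1L, length(rec$samples), by = hop_n)
  freqs <- (seq_len(nfft) - 1L) / nfft * rec$rate
  in_band <- freqs >= config$band_low & freqs <= band_high &
    freqs <= rec$rate / 2

  power_db <- vapply(starts, function(s) {
    frame <- rec$samples[s:min(s + win_n - 1L, length(rec$samples))]
    if (length(frame) < win_n) frame <- c(frame, numeric(win_n - length(frame)))
    spec <- stats::fft(c(frame * w, numeric(nfft - win_n)))
    10 * log10(sum(Mod(spec[in_band])^2) + eps)
  }, numeric(1))

  structure(
    tibble::tibble(time = (starts - 1L) / rec$rate, power_db = power_db),
    class = c("intensity_trace", class(tibble::tibble()))
  )
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Per-trial speech intensity
#'
#' Median of the median-filtered framewise power trace: the single dB value
#' summarising one word's loudness.
#'
#' @param trace An `intensity_trace` from [spectrogram_power()].
#' @param config An [intensity_config()] (supplies the median-filter length).
#' @return A single dB value.
#' @export
trial_intensity <- function(trace, config = intensity_config()) {
  stopifnot(nrow(trace) >= 1)
  k <- min(config$median_filter_len,
           if (nrow(trace) %% 2 == 1) nrow(trace) else nrow(trace) - 1L)
  smoothed <- if (nrow(trace) < 3) trace$power_db else
    stats::runmed(trace$power_db, k, endrule = "median")
  stats::median(smoothed)
}

#' Classify an intensity change into clinical bands
#'
#' Bands follow the convention: change above +5 dB is a clinically relevant
#' large increase, 0 to +5 dB an increase, 0 to -5 dB a decrease, and at or
#' below -5 dB a large decrease.
#'
#' @param delta_db Numeric vector of intensity changes (ON minus OFF), dB.
#' @return Factor with levels `large_decrease`, `decrease`, `increase`,
#'   `large_increase`.
#' @examples
#' classify_intensity_change(c(-6, -1, 0, 3, 6))
#' @export
classify_intensity_change <- function(delta_db) {
  if (any(!is.finite(delta_db))) {
    stop("`delta_db` must be finite", call. = FALSE)
  }
  lev <- c("large_decrease", "decrease", "increase", "large_increase")
  out <- ifelse(delta_db > 5, "large_increase",
         ifelse(delta_db >= 0, "increase",
         ifelse(delta_db > -5, "decrease", "large_decrease")))
  factor(out, levels = lev)
}
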