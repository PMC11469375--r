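#' Cepstral analysis configuration
#'
#' Frame and smoothing parameters for the power cepstrogram and the smoothed
#' cepstral peak prominence (CPPS). The quefrency search band is the period
#' range of the pitch search (1/400 to 1/75 s); the trend band over which the
#' regression line is fitted starts at 1 ms so the low-quefrency spectral
#' envelope does not dominate the fit.
#'
#' @param frame_len Analysis frame length, s. Default 0.048.
#' @param hop Frame hop, s. Default 0.002.
#' @param time_avg Moving-average span across time, s. Default 0.02.
#' @param quef_avg Moving-average span across quefrency, s. Default 0.0005.
#' @param search_band Quefrency band searched for the cepstral peak, s.
#'   Default `c(1/400, 1/75)`.
#' @param trend_band Quefrency band for the least-squares trend line, s.
#'   Default `c(0.001, 1/75)`.
#' @return A list of class `cepstral_config`.
#' @export
cepstral_config <- function(frame_len = 0.048, hop = 0.002, time_avg = 0.02,
                            quef_avg = 0.0005,
                            search_band = c(1 / 400, 1 / 75),
                            trend_band = c(0.001, 1 / 75)) {
  stopifnot(hop > 0, frame_len > 0,
            search_band[1] < search_band[2],
            trend_band[1] < trend_band[2],
            search_band[1] >= trend_band[1] - 1e-12,
            search_band[2] <= trend_band[2] + 1e-12,
            trend_band[2] < frame_len / 2)
  structure(list(frame_len = frame_len, hop = hop, time_avg = time_avg,
                 quef_avg = quef_avg, search_band = search_band,
                 trend_band = trend_band),
            class = "cepstral_config")
}

#' Power cepstrogram of a recording
#'
#' Per frame: Hann window, log power spectrum in dB, then the cepstrum as the
#' dB magnitude of the inverse transform of that log spectrum. The resulting
#' time-quefrency grid is smoothed by moving averages across time
#' (`time_avg`) and quefrency (`quef_avg`). A periodic signal shows a ridge
#' at the quefrency of its period.
#'
#' @param rec An [audio_recording()].
#' @param config A [cepstral_config()].
#' @return An object of class `cepstrogram`: list with `times` (s),
#'   `quefrencies` (s), and `magnitude_db` (quefrency x time matrix).
#' @export
power_cepstrogram <- function(rec, config = cepstral_config()) {
  stopifnot(inherits(rec, "audio_recording"))
  fs <- rec$rate
  win_n <- round(config$frame_len * fs)
  if (length(rec$samples) < win_n) {
    stop("recording shorter than one cepstral frame", call. = FALSE)
  }
  hop_n <- max(1L, round(config$hop * fs))
  nfft <- 2^ceiling(log2(win_n))
  w <- hann_window(win_n)
  starts <- seq(1L, length(rec$samples) - win_n + 1L, by = hop_n)

  n_q <- nfft %/% 2 + 1L
  mag <- matrix(0, nrow = n_q, ncol = length(starts))
  for (k in seq_along(starts)) {
    frame <- rec$samples[starts[k]:(starts[k] + win_n - 1L)] * w
    spec <- stats::fft(c(frame, numeric(nfft - win_n)))
    logpow <- 10 * log10(Mod(spec)^2 + 1e-300)
    cep <- Mod(stats::fft(logpow, inverse = TRUE)) / nfft
    mag[, k] <- 20 * log10(cep[1:n_q] + 1e-300)
  }

  # moving-average smoothing across time then quefrency
  n_t_avg <- max(1L, round(config$time_avg / config$hop))
  n_q_avg <- max(1L, round(config$quef_avg * fs))
  mag <- t(apply(mag, 1, moving_average, n = n_t_avg))
  mag <- apply(mag, 2, moving_average, n = n_q_avg)

  structure(
    list(
      times = (starts - 1L + win_n / 2) / fs,
      quefrencies = (seq_len(n_q) - 1L) / fs,
      magnitude_db = mag
    ),
    class = "cepstrogram"
  )
}

moving_average <- function(x, n) {
  if (n <= 1) return(x)
  stats::filter(x, rep(1 / n, n), sides = 2) |>
    as.numeric() |>
    (\(y) ifelse(is.na(y), x, y))()
}

#' Smoothed cepstral peak prominence (CPPS)
#'
#' Per frame of the smoothed cepstrogram, a straight line is fitted by
#' ordinary least squares to the cepstral magnitude over the trend band; the
#' frame's prominence is the peak magnitude inside the search band minus the
#' trend value at the peak quefrency. CPPS is the mean prominence over
#' frames. Higher CPPS indicates a clearer harmonic structure (less
#' dysphonic voice).
#'
#' @param cepstrogram A `cepstrogram` from [power_cepstrogram()].
#' @param config The [cepstral_config()] used to build it.
#' @return A list of class `cpps_result`: `cpps_db` (dB) and `n_frames`.
#' @export
cpps <- function(cepstrogram, config = cepstral_config()) {
  stopifnot(inherits(cepstrogram, "cepstrogram"))
  q <- cepstrogram$quefrencies
  in_trend <- q >= config$trend_band[1] & q <= config$trend_band[2]
  in_search <- q >= config$search_band[1] & q <= config$search_band[2]
  if (!any(in_search)) stop("search band empty at this resolution", call. = FALSE)

  qt <- q[in_trend]
  n_frames <- length(cepstrogram$times)
  prom <- vapply(seq_len(n_frames), function(k) {
    col <- cepstrogram$magnitude_db[, k]
    fit <- stats::lm.fit(cbind(1, qt), col[in_trend])
    peak_i <- which(in_search)[which.max(col[in_search])]
    trend_at_peak <- fit$coefficients[1] + fit$coefficients[2] * q[peak_i]
    col[peak_i] - trend_at_peak
  }, numeric(1))

  structure(list(cpps_db = mean(prom), n_frames = n_frames),
            class = "cpps_result")
}

#' @export
print.cpps_result <- function(x, ...) {
  cat(sprintf("<cpps_result> CPPS = %.2f dB over %d frames\n",
              x$cpps_db, x$n_frames))
  invisible(x)
}

#' Convenience wrapper: CPPS of a recording
#'
#' @param rec An [audio_recording()].
#' @param config A [cepstral_config()].
#' @return The `cpps_db` scalar.
#' @export
cpps_of <- function(rec, config = cepstral_config()) {
  cpps(power_cepstrogram(rec, config), config)$cpps_db
}
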