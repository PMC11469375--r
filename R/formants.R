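#' Formant-analysis configuration
#'
#' The linear-predictive-coding (LPC) formant pipeline: pre-emphasis
#' `1 - 0.63 z^-1`, 15 ms Hamming frames with 80% overlap, LPC model order
#' `round(rate/1000) + 2`, root gates at 90 Hz minimum frequency and 400 Hz
#' maximum bandwidth, first four surviving roots by ascending frequency;
#' per-vowel summaries use a window-3 running median, cubic-spline
#' resampling to 100 points and truncation to points 15-85 (the stable 70%
#' around the vowel centre).
#'
#' @param preemph_coeff Pre-emphasis coefficient. Default 0.63.
#' @param frame_len Frame length, s (Hamming). Default 0.015.
#' @param overlap Fractional frame overlap. Default 0.80.
#' @param min_freq Minimum admissible formant frequency, Hz. Default 90.
#' @param max_bandwidth Maximum admissible bandwidth, Hz. Default 400.
#' @param n_formants Number of formants retained per frame. Default 4.
#' @param warp_points Points of the per-vowel resampled trace. Default 100.
#' @param keep_range 1-based inclusive index range kept after resampling.
#'   Default `c(15, 85)` (71 points).
#' @return A list of class `formant_config`.
#' @export
formant_config <- function(preemph_coeff = 0.63, frame_len = 0.015,
                           overlap = 0.80, min_freq = 90,
                           max_bandwidth = 400, n_formants = 4,
                           warp_points = 100, keep_range = c(15, 85)) {
  stopifnot(preemph_coeff >= 0, preemph_coeff < 1, overlap > 0, overlap < 1,
            keep_range[1] >= 1, keep_range[2] <= warp_points,
            keep_range[1] < keep_range[2])
  structure(list(preemph_coeff = preemph_coeff, frame_len = frame_len,
                 overlap = overlap, min_freq = min_freq,
                 max_bandwidth = max_bandwidth, n_formants = n_formants,
                 warp_points = warp_points, keep_range = keep_range),
            class = "formant_config")
}

#' Pre-emphasis filter
#'
#' Applies `y[n] = x[n] - coeff * x[n-1]` (with `y[1] = x[1]`), boosting high
#' frequencies so the LPC fit is not dominated by the glottal spectral tilt.
#'
#' @param rec An [audio_recording()].
#' @param coeff Pre-emphasis coefficient in `[0, 1)`. Default 0.63.
#' @return A pre-emphasized `audio_recording`.
#' @examples
#' r <- audio_recording(c(1, 0, 0, 0), 8000)
#' preemphasize(r, 0.63)$samples # impulse response 1, -0.63, 0, 0
#' @export
preemphasize <- function(rec, coeff = 0.63) {
  stopifnot(inherits(rec, "audio_recording"), coeff >= 0, coeff < 1)
  x <- rec$samples
  y <- x - coeff * c(0, x[-length(x)])
  y[1] <- x[1]
  audio_recording(y, rec$rate)
}

#' LPC model order from the sampling rate
#'
#' `round(rate/1000) + 2` with round-half-up, e.g. order 32 at 30 kHz.
#'
#' @param rate Sampling rate, Hz.
#' @return Integer model order.
#' @export
lpc_order <- function(rate) {
  as.integer(floor(rate / 1000 + 0.5)) + 2L
}

# Levinson-Durbin recursion: autocorrelation r[0..p] -> list(a, err)
# a = c(1, a1..ap) of A(z) = 1 + a1 z^-1 + ... ; err = final prediction error
levinson_durbin <- function(r, p) {
  a <- numeric(p + 1)
  a[1] <- 1
  err <- r[1]
  if (err <= 0) return(NULL)
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc + sum(a[2:i] * r[i:2])
    k <- -acc / err
    a_new <- a
    a_new[i + 1] <- k
    if (i > 1) a_new[2:i] <- a[2:i] + k * rev(a[2:i])
    a <- a_new
    err <- err * (1 - k^2)
    if (err <= 0) return(NULL)
  }
  list(a = a, err = err)
}

# one frame: samples -> up to n_formants (frequency, bandwidth) pairs
lpc_frame_formants <- function(frame, rate, order, min_freq, max_bandwidth,
                               n_formants) {
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_along(frame) - 1) / (length(frame) - 1))
  xw <- (frame - mean(frame)) * w
  n <- length(xw)
  if (sum(xw^2) <= 0) return(NULL)
  # autocorrelation by FFT
  nfft <- 2^ceiling(log2(2 * n))
  r <- Re(stats::fft(Mod(stats::fft(c(xw, numeric(nfft - n))))^2,
                     inverse = TRUE))[1:(order + 1)] / nfft
  ld <- levinson_durbin(r, order)
  if (is.null(ld)) return(NULL)
  roots <- polyroot(rev(ld$a)) # A(z) in powers of z: a_p + ... + a_1 z^(p-1) + z^p
  roots <- roots[Im(roots) > 0]
  if (!length(roots)) return(NULL)
  freq <- Arg(roots) * rate / (2 * pi)
  bw <- -(rate / pi) * log(Mod(roots))
  keep <- freq > min_freq & bw < max_bandwidth & bw > 0
  if (!any(keep)) return(NULL)
  ord <- order(freq[keep])
  f <- freq[keep][ord]
  b <- bw[keep][ord]
  take <- seq_len(min(n_formants, length(f)))
  list(frequency = f[take], bandwidth = b[take])
}

#' LPC formant track of a vowel segment
#'
#' The segment (already pre-emphasized) is analysed in Hamming-windowed
#' frames; each frame is fitted with an autocorrelation-method LPC model
#' (Levinson-Durbin) whose polynomial roots give candidate resonances:
#' frequency from the root angle, bandwidth from the root radius. Roots
#' below `min_freq` or wider than `max_bandwidth` are discarded and the
#' first `n_formants` survivors by ascending frequency are the frame's
#' formants.
#'
#' @param segment An [audio_recording()] holding one vowel (pre-emphasized;
#'   see [preemphasize()]).
#' @param config A [formant_config()].
#' @return A tibble of class `formant_track`: columns `time`, `f1`...`f4`,
#'   `b1`...`b4` (Hz; `NA` where a formant is missing or the frame failed).
#' @export
lpc_formant_track <- function(segment, config = formant_config()) {
  stopifnot(inherits(segment, "audio_recording"))
  fs <- segment$rate
  win_n <- round(config$frame_len * fs)
  if (length(segment$samples) < win_n) {
    stop("segment shorter than one analysis frame", call. = FALSE)
  }
  hop_n <- max(1L, round(win_n * (1 - config$overlap)))
  order <- lpc_order(fs)
  starts <- seq(1L, length(segment$samples) - win_n + 1L, by = hop_n)
  nf <- config$n_formants

  rows <- lapply(starts, function(s) {
    res <- lpc_frame_formants(segment$samples[s:(s + win_n - 1L)], fs, order,
                              config$min_freq, config$max_bandwidth, nf)
    f <- rep(NA_real_, nf)
    b <- rep(NA_real_, nf)
    if (!is.null(res)) {
      k <- length(res$frequency)
      f[seq_len(k)] <- res$frequency
      b[seq_len(k)] <- res$bandwidth
    }
    c((s - 1L + win_n / 2) / fs, f, b)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("time", paste0("f", seq_len(nf)), paste0("b", seq_len(nf)))
  structure(tibble::as_tibble(as.data.frame(m)),
            class = c("formant_track", class(tibble::tibble())),
            config = config)
}

#' Per-vowel formant summary with smoothing, time-warping and truncation
#'
#' For F1 and F2: frames with a missing value are dropped, the sequence is
#' smoothed with a window-3 running median, resampled by cubic spline to
#' `warp_points` points spanning the vowel, truncated to `keep_range`
#' (points 15-85 inclusive by default, i.e. the central 70%, 71 points), and
#' averaged. The warping makes trials of different durations comparable.
#'
#' @param track A `formant_track` from [lpc_formant_track()].
#' @param config A [formant_config()].
#' @return A one-row tibble: `mean_f1`, `mean_f2`, `n_frames_used` (number
#'   of retained warped points), `n_raw_frames`. All-`NA` row (with
#'   `n_frames_used = 0`) when fewer than 4 usable frames exist.
#' @export
summarize_vowel_formants <- function(track, config = formant_config()) {
  warp_one <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 4) return(NULL)
    x <- v[ok]
    x <- stats::runmed(x, min(3L, length(x) - (1 - length(x) %% 2)),
                       endrule = "median")
    u <- seq(0, 1, length.out = length(x))
    warped <- stats::spline(u, x, xout = seq(0, 1, length.out = config$warp_points),
                            method = "natural")$y
    kept <- warped[config$keep_range[1]:config$keep_range[2]]
    kept
  }
  k1 <- warp_one(track$f1)
  k2 <- warp_one(track$f2)
  if (is.null(k1) || is.null(k2)) {
    return(tibble::tibble(mean_f1 = NA_real_, mean_f2 = NA_real_,
                          n_frames_used = 0L, n_raw_frames = nrow(track)))
  }
  tibble::tibble(
    mean_f1 = mean(k1),
    mean_f2 = mean(k2),
    n_frames_used = length(k1),
    n_raw_frames = nrow(track)
  )
}

#' Percent change of vowel formants between conditions
#'
#' `100 * (mean_ON - mean_OFF) / mean_OFF` per formant, where each condition
#' mean averages the per-trial summaries.
#'
#' @param off_summaries,on_summaries Tibbles of per-trial summaries
#'   ([summarize_vowel_formants()] rows) for the OFF and ON condition.
#' @return A tibble with columns `formant` (`"F1"`, `"F2"`), `mean_off`,
#'   `mean_on`, `pct_change`.
#' @export
formant_percent_change <- function(off_summaries, on_summaries) {
  stopifnot(nrow(off_summaries) > 0, nrow(on_summaries) > 0)
  out <- lapply(c(f1 = "mean_f1", f2 = "mean_f2"), function(col) {
    m_off <- mean(off_summaries[[col]], na.rm = TRUE)
    m_on <- mean(on_summaries[[col]], na.rm = TRUE)
    if (!is.finite(m_off) || m_off == 0) {
      stop("OFF-condition mean is zero or undefined", call. = FALSE)
    }
    c(m_off, m_on, 100 * (m_on - m_off) / m_off)
  })
  tibble::tibble(
    formant = c("F1", "F2"),
    mean_off = c(out$f1[1], out$f2[1]),
    mean_on = c(out$f1[2], out$f2[2]),
    pct_change = c(out$f1[3], out$f2[3])
  )
}
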