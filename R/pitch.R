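#' Pitch-tracking configuration
#'
#' Defaults follow standard voice-pathology practice: search range 75-400 Hz
#' and a permissive voicing threshold of 0.25 so that irregular phonation is
#' still tracked.
#'
#' @param floor,ceiling Pitch search range, Hz.
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced. Default 0.25.
#' @param frame_len Analysis frame length, seconds. Default `3 / floor`
#'   (three periods of the lowest trackable pitch).
#' @param hop Frame hop, seconds. Default 0.010.
#' @param prefilter_cutoff Low-pass prefilter cutoff, Hz. Default `ceiling`.
#' @return A list of class `pitch_config`.
#' @export
pitch_config <- function(floor = 75, ceiling = 400, voicing_threshold = 0.25,
                         frame_len = 3 / floor, hop = 0.010,
                         prefilter_cutoff = ceiling) {
  stopifnot(floor > 0, floor < ceiling, voicing_threshold > 0, hop > 0)
  structure(list(floor = floor, ceiling = ceiling,
                 voicing_threshold = voicing_threshold,
                 frame_len = frame_len, hop = hop,
                 prefilter_cutoff = prefilter_cutoff),
            class = "pitch_config")
}

#' Track fundamental frequency by filtered autocorrelation
#'
#' The recording is low-pass prefiltered at the pitch ceiling (zero-phase
#' Butterworth), then per frame: mean removal, Hann window, autocorrelation
#' normalized by the window's own autocorrelation, candidate-peak search with
#' parabolic lag refinement. The lag search extends above the ceiling so that
#' periodicity faster than the ceiling (e.g. a 500 Hz tone) is recognised and
#' marked unvoiced rather than aliased onto a period multiple. Voiced-run
#' f0 values are median-3 smoothed.
#'
#' @param rec An [audio_recording()].
#' @param config A [pitch_config()].
#' @return A tibble of class `pitch_track` with columns `time` (frame centre,
#'   s), `f0` (Hz, `NA` when unvoiced), `strength` (normalized peak value) and
#'   `voiced` (logical). Attribute `config` carries the configuration.
#' @export
track_pitch <- function(rec, config = pitch_config()) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$rate < 2 * config$ceiling) {
    stop("sampling rate below 2 x pitch ceiling", call. = FALSE)
  }
  fs <- rec$rate
  win_n <- round(config$frame_len * fs)
  if (length(rec$samples) < win_n) stop("recording shorter than one frame", call. = FALSE)
  hop_n <- max(1L, round(config$hop * fs))

  # zero-phase low-pass prefilter at the ceiling
  bf <- signal::butter(4, min(0.99, config$prefilter_cutoff / (fs / 2)), "low")
  x <- as.numeric(signal::filtfilt(bf, rec$samples))

  lag_min <- max(2L, floor(fs / config$ceiling))
  lag_max <- min(win_n - 2L, ceiling(fs / config$floor))
  lag_ext <- max(2L, floor(fs / (3 * config$ceiling))) # catches f0 up to 3x ceiling

  w <- hann_window(win_n)
  nfft <- 2^ceiling(log2(2 * win_n))
  rw <- Re(stats::fft(Mod(stats::fft(c(w, numeric(nfft - win_n))))^2,
                      inverse = TRUE))[1:(lag_max + 2)]
  rw <- rw / rw[1]

  starts <- seq(1L, length(x) - win_n + 1L, by = hop_n)
  n_frames <- length(starts)
  f0 <- rep(NA_real_, n_frames)
  strength <- numeric(n_frames)

  norm_ac <- function(frame) {
    frame <- (frame - mean(frame)) * w
    if (sum(frame^2) <= 0) return(NULL)
    rx <- Re(stats::fft(Mod(stats::fft(c(frame, numeric(nfft - win_n))))^2,
                        inverse = TRUE))[1:(lag_max + 2)]
    if (rx[1] <= 0) return(NULL)
    (rx / rx[1]) / pmax(rw, 0.1)
  }

  for (k in seq_len(n_frames)) {
    idx <- starts[k]:(starts[k] + win_n - 1L)
    rho <- norm_ac(x[idx])
    if (is.null(rho)) next
    lags <- lag_ext:lag_max
    vals <- rho[lags + 1L]
    m <- max(vals)
    if (m <= 0) next
    # local maxima at or above 90% of the global max; take the shortest lag
    is_max <- vals >= c(vals[1] - 1, vals[-length(vals)]) &
              vals >= c(vals[-1], vals[length(vals)] - 1) &
              vals >= 0.9 * m
    if (!any(is_max)) next
    lag0 <- lags[which(is_max)[1]]
    ref <- parabolic_peak(rho, lag0 + 1L)
    lag_star <- ref$x - 1
    # the prefilter leaves low-pass noise correlated at pitch-period lags;
    # demand periodicity in the raw frame too before calling a frame voiced
    rho_raw <- norm_ac(rec$samples[idx])
    s_raw <- if (is.null(rho_raw)) 0 else
      max(rho_raw[max(1L, lag0):min(length(rho_raw), lag0 + 2L)])
    s <- min(1, ref$y, s_raw)
    strength[k] <- s
    cand_f0 <- fs / lag_star
    if (s >= config$voicing_threshold &&
        cand_f0 >= config$floor && cand_f0 <= config$ceiling) {
      f0[k] <- cand_f0
    }
  }

  voiced <- !is.na(f0)
  f0 <- smooth_voiced_runs(f0, voiced)

  structure(
    tibble::tibble(
      time = (starts - 1L + win_n / 2) / fs,
      f0 = f0, strength = strength, voiced = voiced
    ),
    class = c("pitch_track", class(tibble::tibble())),
    config = config
  )
}

# parabolic interpolation around index i of vector v (1-based)
parabolic_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(list(x = i, y = v[i]))
  a <- v[i - 1]; b <- v[i]; c <- v[i + 1]
  denom <- a - 2 * b + c
  if (denom == 0) return(list(x = i, y = b))
  d <- 0.5 * (a - c) / denom
  d <- max(-0.5, min(0.5, d))
  list(x = i + d, y = b - 0.25 * (a - c) * d)
}

# median-3 smoothing of f0 within each voiced run
smooth_voiced_runs <- function(f0, voiced) {
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    if (length(idx) >= 3) {
      f0[idx] <- stats::runmed(f0[idx], 3, endrule = "median")
    }
  }
  f0
}

#' Extract glottal pulse times from a pitch track
#'
#' Within each voiced run, pulses are placed at the absolute-amplitude peak
#' of the waveform inside successive windows one period long, each window
#' advanced pulse-to-pulse. Candidate peaks are gated on amplitude — both
#' relative to the running median pulse amplitude (decaying resonance tails
#' at the edge of a silent gap must not register as pulses) and relative to
#' the recording's global peak — so that inserted silent gaps translate into
#' long inter-pulse intervals.
#'
#' @param rec The [audio_recording()] the track was computed from.
#' @param track A `pitch_track` from [track_pitch()].
#' @param min_peak_frac Reject a candidate pulse whose amplitude is below
#'   this fraction of the running median pulse amplitude. Default 0.45
#'   (a free resonance decay over half a period falls below this for any
#'   bandwidth above ~55 Hz, while true glottal pulses stay above it).
#' @param silence_frac Reject candidates below this fraction of the global
#'   absolute peak. Default 0.1.
#' @return Numeric vector of strictly increasing pulse times (seconds),
#'   class `pulse_train`.
#' @export
extract_pulses <- function(rec, track, min_peak_frac = 0.45,
                           silence_frac = 0.1) {
  stopifnot(inherits(rec, "audio_recording"), inherits(track, "pitch_track"))
  fs <- rec$rate
  x <- rec$samples
  abs_gate <- silence_frac * max(abs(x))
  r <- rle(track$voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cfg <- attr(track, "config")
  half_win <- cfg$frame_len / 2

  pulses <- numeric(0)
  for (k in which(r$values)) {
    fr <- starts[k]:ends[k]
    run_t0 <- max(0, track$time[fr[1]] - half_win)
    run_t1 <- min(rec$duration, track$time[fr[length(fr)]] + half_win)
    # period at time t from the nearest voiced frame of this run
    period_at <- function(t) {
      1 / track$f0[fr[which.min(abs(track$time[fr] - t))]]
    }
    amps <- numeric(0)
    t <- run_t0
    while (TRUE) {
      p <- period_at(t)
      i0 <- max(1L, floor(t * fs) + 1L)
      i1 <- min(length(x), ceiling((t + p) * fs))
      if (i0 >= i1 || t >= run_t1) break
      seg <- x[i0:i1]
      j <- which.max(abs(seg))
      amp <- abs(seg[j])
      pt <- (i0 + j - 2L) / fs
      ok <- amp >= abs_gate &&
        (length(amps) < 3 || amp >= min_peak_frac * stats::median(amps))
      if (ok) {
        if (!length(pulses) || pt > pulses[length(pulses)]) {
          pulses <- c(pulses, pt)
          amps <- c(amps, amp)
        }
        t <- pt + 0.5 * period_at(pt)
      } else {
        t <- t + p
      }
    }
  }
  structure(sort(unique(pulses)), class = "pulse_train")
}

#' Count voice breaks from a pulse train
#'
#' A voice break is an inter-pulse interval strictly longer than
#' `threshold_s` occurring between the first and the last voiced frame
#' (leading and trailing silence never count). The default threshold,
#' 1.25 / 75 Hz = 16.67 ms, is 1.25 periods of the pitch floor.
#'
#' @param pulses A `pulse_train` from [extract_pulses()].
#' @param track The `pitch_track` the pulses were derived from.
#' @param threshold_s Break threshold in seconds. Default `1.25 / 75`.
#' @return A list of class `voice_break_report`: `n_breaks`,
#'   `break_intervals` (tibble `start`, `end`, `duration`), `threshold`.
#' @export
count_voice_breaks <- function(pulses, track, threshold_s = 1.25 / 75) {
  stopifnot(threshold_s > 0)
  empty <- tibble::tibble(start = numeric(), end = numeric(),
                          duration = numeric())
  if (length(pulses) < 2) {
    warning("fewer than 2 pulses; reporting 0 breaks", call. = FALSE)
    return(structure(list(n_breaks = 0L, break_intervals = empty,
                          threshold = threshold_s),
                     class = "voice_break_report"))
  }
  vt <- track$time[track$voiced]
  lo <- if (length(vt)) min(vt) - attr(track, "config")$frame_len else -Inf
  hi <- if (length(vt)) max(vt) + attr(track, "config")$frame_len else Inf
  p0 <- pulses[-length(pulses)]
  p1 <- pulses[-1]
  gap <- p1 - p0
  is_break <- gap > threshold_s & p0 >= lo & p1 <= hi
  structure(
    list(
      n_breaks = sum(is_break),
      break_intervals = tibble::tibble(start = p0[is_break], end = p1[is_break],
                                       duration = gap[is_break]),
      threshold = threshold_s
    ),
    class = "voice_break_report"
  )
}

#' @export
print.voice_break_report <- function(x, ...) {
  cat(sprintf("<voice_break_report> %d break(s) > %.4f s\n",
              x$n_breaks, x$threshold))
  if (x$n_breaks > 0) print(x$break_intervals)
  invisible(x)
}
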