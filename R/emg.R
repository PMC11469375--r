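#' Construct a multichannel EMG recording
#'
#' @param channels Named list (or data frame) of equal-length numeric
#'   amplitude vectors, one per muscle (e.g. `MASS`, `ORIS`, `MYLO`, `CRICO`).
#' @param rate Sampling rate, Hz.
#' @param stim_events Optional numeric vector of stimulation trigger times, s.
#' @param movement_events Optional data frame with `start`, `end` (s) and
#'   optionally `condition`, `trial`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(channels, rate, stim_events = NULL,
                          movement_events = NULL) {
  channels <- as.list(channels)
  stopifnot(length(channels) >= 1, rate > 0)
  n <- unique(vapply(channels, length, integer(1)))
  if (length(n) != 1) stop("channels must have equal length", call. = FALSE)
  dur <- n / rate
  if (!is.null(stim_events) && any(stim_events < 0 | stim_events > dur)) {
    stop("stim_events outside the recording", call. = FALSE)
  }
  if (!is.null(movement_events) &&
      any(movement_events$start < 0 | movement_events$end > dur)) {
    stop("movement_events outside the recording", call. = FALSE)
  }
  structure(list(channels = channels, rate = rate, n = n, duration = dur,
                 stim_events = stim_events, movement_events = movement_events),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channel(s) [%s] @ %g Hz, %.2f s, %d trigger(s)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$rate, x$duration, length(x$stim_events)))
  invisible(x)
}

#' Read an EMG CSV (time column + one column per muscle)
#'
#' The sampling rate is taken from a `# rate: <Hz>` comment on the first
#' line if present, otherwise inferred from the time column.
#'
#' @param path CSV path. First column is time (s), remaining columns muscles.
#' @param rate Sampling rate override, Hz.
#' @return An [emg_recording()].
#' @export
read_emg_csv <- function(path, rate = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(rate) && grepl("^#\\s*rate:", first)) {
    rate <- as.numeric(sub("^#\\s*rate:\\s*", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(rate)) rate <- 1 / stats::median(diff(df[[1]]))
  emg_recording(df[-1], rate)
}

#' MEP analysis configuration
#'
#' @param window Post-trigger integration window, s. Default `c(0.010, 0.075)`.
#' @param trial_span Length of each trigger-aligned trial, s. Default 0.100.
#' @return A list of class `mep_config`.
#' @export
mep_config <- function(window = c(0.010, 0.075), trial_span = 0.100) {
  stopifnot(window[1] >= 0, window[1] < window[2], window[2] <= trial_span)
  structure(list(window = window, trial_span = trial_span),
            class = "mep_config")
}

#' Stimulation-triggered MEP area under the curve
#'
#' Per muscle: rectified trigger-aligned trials are averaged and the average
#' is integrated (trapezoid) over the post-trigger window (10-75 ms by
#' default), yielding one AUC per muscle.
#'
#' @param rec An [emg_recording()] with `stim_events`.
#' @param config A [mep_config()].
#' @param rectify Rectify trials before averaging (default TRUE; a signed
#'   average can cancel the evoked response).
#' @return A tibble: `muscle`, `auc` (amplitude*s), `n_trials`.
#' @export
mep_auc <- function(rec, config = mep_config(), rectify = TRUE) {
  stopifnot(inherits(rec, "emg_recording"))
  if (is.null(rec$stim_events) || !length(rec$stim_events)) {
    stop("no stimulation events in recording", call. = FALSE)
  }
  if (rec$rate < 6000) {
    warning("sampling rate below 6 kHz; MEP AUC may be under-resolved",
            call. = FALSE)
  }
  span_n <- round(config$trial_span * rec$rate)
  usable <- rec$stim_events[round(rec$stim_events * rec$rate) + span_n <= rec$n]
  n_skipped <- length(rec$stim_events) - length(usable)
  if (n_skipped > 0) {
    message(n_skipped, " trigger(s) too close to record end; skipped")
  }
  if (!length(usable)) stop("no usable triggers", call. = FALSE)

  t_rel <- (seq_len(span_n) - 1) / rec$rate
  in_win <- t_rel >= config$window[1] & t_rel <= config$window[2]
  out <- lapply(names(rec$channels), function(mu) {
    x <- rec$channels[[mu]]
    trials <- vapply(usable, function(ev) {
      i0 <- round(ev * rec$rate) + 1L
      seg <- x[i0:(i0 + span_n - 1L)]
      if (rectify) abs(seg) else seg
    }, numeric(span_n))
    avg <- rowMeans(trials)
    tibble::tibble(muscle = mu,
                   auc = trapz(t_rel[in_win], avg[in_win]),
                   n_trials = length(usable))
  })
  dplyr::bind_rows(out)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' EMG envelope configuration
#'
#' @param bp_low,bp_high Bandpass corners, Hz. Defaults 60 and 500.
#' @param lp_cutoff Envelope low-pass cutoff, Hz. Default 6.
#' @param filter_order Butterworth order (applied zero-phase). Default 2.
#' @param rectify Full-wave rectify between the two filters. Default TRUE.
#' @return A list of class `envelope_config`.
#' @export
envelope_config <- function(bp_low = 60, bp_high = 500, lp_cutoff = 6,
                            filter_order = 2, rectify = TRUE) {
  stopifnot(bp_low > 0, bp_low < bp_high, lp_cutoff > 0)
  structure(list(bp_low = bp_low, bp_high = bp_high, lp_cutoff = lp_cutoff,
                 filter_order = filter_order, rectify = rectify),
            class = "envelope_config")
}

#' Voluntary-EMG envelope
#'
#' Per channel: zero-phase second-order Butterworth bandpass (60-500 Hz),
#' full-wave rectification, zero-phase second-order low-pass at 6 Hz, and a
#' floor at zero (filter ringing can dip slightly negative). Zero-phase
#' (forward-backward) filtering keeps envelope timing aligned with the
#' behavioral events.
#'
#' @param rec An [emg_recording()].
#' @param config An [envelope_config()].
#' @return An `emg_recording` whose channels hold the envelopes.
#' @export
emg_envelope <- function(rec, config = envelope_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$rate / 2
  if (nyq <= config$bp_high) {
    stop("sampling rate too low for the bandpass (need > 2 x bp_high)",
         call. = FALSE)
  }
  bp <- signal::butter(config$filter_order,
                       c(config$bp_low, config$bp_high) / nyq, "pass")
  lp <- signal::butter(config$filter_order, config$lp_cutoff / nyq, "low")
  env <- lapply(rec$channels, function(x) {
    y <- as.numeric(signal::filtfilt(bp, x))
    if (config$rectify) y <- abs(y)
    pmax(0, as.numeric(signal::filtfilt(lp, y)))
  })
  emg_recording(env, rec$rate, stim_events = rec$stim_events,
                movement_events = rec$movement_events)
}

#' Per-movement envelope AUC with OFF-referenced z-scores
#'
#' Trapezoidal AUC of the envelope over each movement event, per muscle.
#' When events carry a `condition` column, each AUC additionally gets a
#' z-score against the OFF-condition distribution of the same muscle:
#' `z = (auc - mean_OFF) / sd_OFF`. With fewer than 2 OFF trials or zero OFF
#' variance, z is `NA` and `z_defined` is FALSE.
#'
#' @param env An enveloped [emg_recording()] (see [emg_envelope()]).
#' @param events Data frame with `start`, `end` (s), optionally `condition`
#'   (`"OFF"`/`"ON"`) and `trial`; defaults to `env$movement_events`.
#' @return A tibble: `muscle`, `trial`, `condition`, `start`, `end`, `auc`,
#'   `z`, `z_defined`.
#' @export
movement_auc <- function(env, events = env$movement_events) {
  stopifnot(inherits(env, "emg_recording"), !is.null(events))
  events <- tibble::as_tibble(events)
  if (!"condition" %in% names(events)) events$condition <- NA_character_
  if (!"trial" %in% names(events)) events$trial <- seq_len(nrow(events))
  ord <- order(events$start)
  if (any(events$end[ord][-nrow(events)] > events$start[ord][-1] + 1e-12)) {
    stop("movement events overlap", call. = FALSE)
  }
  t_all <- (seq_len(env$n) - 1) / env$rate
  out <- lapply(names(env$channels), function(mu) {
    x <- env$channels[[mu]]
    auc <- vapply(seq_len(nrow(events)), function(k) {
      sel <- t_all >= events$start[k] & t_all <= events$end[k]
      trapz(t_all[sel], x[sel])
    }, numeric(1))
    tibble::tibble(muscle = mu, trial = events$trial,
                   condition = events$condition,
                   start = events$start, end = events$end, auc = auc)
  })
  res <- dplyr::bind_rows(out)
  res |>
    dplyr::group_by(.data$muscle) |>
    dplyr::mutate(
      z = off_zscore(.data$auc, .data$condition),
      z_defined = !is.na(.data$z)
    ) |>
    dplyr::ungroup()
}

off_zscore <- function(auc, condition) {
  off <- auc[!is.na(condition) & condition == "OFF"]
  if (length(off) < 2) return(rep(NA_real_, length(auc)))
  s <- stats::sd(off)
  if (!is.finite(s) || s <= 1e-8 * max(abs(mean(off)), .Machine$double.xmin)) {
    return(rep(NA_real_, length(auc)))
  }
  (auc - mean(off)) / s
}
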