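#' Specification of a synthetic vowel
#'
#' Source-filter description: a glottal impulse train at `f0` (with optional
#' cycle-to-cycle jitter) driving a cascade of second-order resonators (one
#' per formant), RMS-scaled, with optional additive white noise and inserted
#' silent gaps (voice breaks). A cascade (not parallel) of resonators gives
#' an all-pole spectrum matching the LPC analysis model, so formant recovery
#' is well posed.
#'
#' @param f0 Nominal fundamental frequency, Hz (60-500). With declination,
#'   the instantaneous f0 sweeps linearly from `f0 * (1 + declination/200)`
#'   down to `f0 * (1 - declination/200)`, so `f0` stays the median.
#' @param jitter Cycle-to-cycle period jitter, percent (sd of the Gaussian
#'   perturbation of each period). Default 0.
#' @param declination Total linear f0 declination over the vowel, percent.
#'   Default 4 (natural pitch declination; a perfectly flat f0 is not
#'   phonatory-realistic and makes spectrum-sampling artifacts coherent
#'   across the whole vowel).
#' @param formants List of `c(frequency, bandwidth)` pairs, Hz. Default four
#'   resonances resembling an open central vowel:
#'   700/80, 1200/90, 2600/120, 3500/150.
#' @param duration Seconds. Default 0.5.
#' @param rms_db Target RMS level, dB re 1.0. Default -20.
#' @param snr_db Signal-to-noise ratio of added white noise, dB;
#'   `Inf` = clean. Default `Inf`.
#' @param breaks Data frame with `start`, `length` (s) of silent gaps, or
#'   NULL. Gaps pause the pulse train: the next pulse is delayed so the
#'   inter-pulse interval equals the gap length (never less than one
#'   period), and the span in between is zeroed with 5 ms cosine ramps.
#' @param rate Sampling rate, Hz. Default 16000.
#' @param seed Integer seed. Default 1.
#' @return A list of class `vowel_spec`.
#' @export
vowel_spec <- function(f0 = 120, jitter = 0, declination = 4,
                       formants = list(c(700, 80), c(1200, 90),
                                       c(2600, 120), c(3500, 150)),
                       duration = 0.5, rms_db = -20, snr_db = Inf,
                       breaks = NULL, rate = 16000, seed = 1) {
  stopifnot(f0 >= 60, f0 <= 500, duration > 0, rate > 0)
  ff <- vapply(formants, `[`, numeric(1), 1)
  if (any(ff >= rate / 2)) stop("formant frequency above Nyquist", call. = FALSE)
  if (!is.null(breaks)) {
    breaks <- breaks[order(breaks$start), , drop = FALSE]
    ends <- breaks$start + breaks$length
    if (any(breaks$start[-1] < ends[-nrow(breaks)])) {
      stop("overlapping breaks", call. = FALSE)
    }
  }
  structure(list(f0 = f0, jitter = jitter, declination = declination,
                 formants = formants,
                 duration = duration, rms_db = rms_db, snr_db = snr_db,
                 breaks = breaks, rate = rate, seed = seed),
            class = "vowel_spec")
}

# second-order resonator cascade; x filtered in place
resonate <- function(x, formants, rate) {
  for (fm in formants) {
    r <- exp(-pi * fm[2] / rate)
    theta <- 2 * pi * fm[1] / rate
    x <- as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2),
                                  method = "recursive"))
  }
  x
}

#' Synthesize a vowel from a spec
#'
#' Deterministic given the spec (and its seed). Pulse times are integer
#' sample positions; a requested gap of length `g` produces an inter-pulse
#' interval of exactly `max(period, floor(g * rate)) / rate` seconds, so the
#' number of qualifying voice breaks is known by construction.
#'
#' @param spec A [vowel_spec()].
#' @return A list: `recording` ([audio_recording()]) and `truth` (list with
#'   `f0`, `formants`, `pulse_times`, `gap_intervals`, realized
#'   `n_breaks(threshold)` helper fields `n_breaks_16_67` for the default
#'   1.25/75 s threshold, and `rms_db`).
#' @export
synth_vowel <- function(spec) {
  stopifnot(inherits(spec, "vowel_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  fs <- spec$rate
  n <- round(spec$duration * fs)
  period <- fs / spec$f0 # samples, real-valued

  # pulse placement with pause-insertion break semantics
  brk <- spec$breaks
  bi <- 1L
  pulse_samp <- integer(0)
  gap_intervals <- numeric(0)
  gap_after <- integer(0) # index of the pulse preceding each real gap
  t <- 1 # sample position (1-based, real-valued accumulator)
  decl <- spec$declination / 100
  while (t <= n) {
    pulse_samp <- c(pulse_samp, round(t))
    step <- period / (1 + decl * (0.5 - t / n)) # linear f0 declination
    if (spec$jitter > 0) {
      step <- step * (1 + spec$jitter / 100 * stats::rnorm(1))
      step <- max(2, step)
    }
    nxt <- t + step
    if (!is.null(brk) && bi <= nrow(brk) &&
        nxt > brk$start[bi] * fs + 1) {
      gap_samp <- max(floor(step), floor(brk$length[bi] * fs))
      nxt <- round(t) + gap_samp
      gap_intervals <- c(gap_intervals, gap_samp / fs)
      if (gap_samp > ceiling(period) + 1) {
        gap_after <- c(gap_after, length(pulse_samp))
      }
      bi <- bi + 1L
    }
    t <- nxt
  }
  in_range <- pulse_samp >= 1 & pulse_samp <= n
  gap_after <- match(gap_after, which(in_range))
  pulse_samp <- pulse_samp[in_range]

  src <- numeric(n)
  src[pulse_samp] <- 1
  x <- resonate(src, spec$formants, fs)

  target_rms <- 10^(spec$rms_db / 20)
  x <- x * target_rms / sqrt(mean(x^2))
  if (is.finite(spec$snr_db)) {
    x <- x + stats::rnorm(n, sd = target_rms * 10^(-spec$snr_db / 20))
  }

  # zero the gap spans (between bounding pulses) with 5 ms cosine ramps
  gap_after <- gap_after[!is.na(gap_after) & gap_after < length(pulse_samp)]
  if (length(gap_after)) {
    p <- pulse_samp
    ramp_n <- round(0.005 * fs)
    for (g in gap_after) {
      i0 <- p[g] + round(0.25 * period)
      i1 <- p[g + 1] - round(0.25 * period)
      if (i1 - i0 < 2 * ramp_n + 2) next
      idx <- i0:i1
      env <- rep(0, length(idx))
      env[1:ramp_n] <- 0.5 + 0.5 * cos(pi * (0:(ramp_n - 1)) / (ramp_n - 1))
      env[(length(idx) - ramp_n + 1):length(idx)] <- rev(env[1:ramp_n])
      x[idx] <- x[idx] * env
    }
  }

  thr <- 1.25 / 75
  truth <- list(
    f0 = spec$f0,
    formants = spec$formants,
    pulse_times = (pulse_samp - 1) / fs,
    gap_intervals = gap_intervals,
    n_breaks_16_67 = sum(gap_intervals > thr),
    rms_db = 20 * log10(sqrt(mean(x^2)))
  )
  list(recording = audio_recording(x, fs), truth = truth)
}

#' Synthesize a consonant-vowel-consonant word with its TextGrid
#'
#' Noise-burst "consonants" (band-limited white noise with cosine ramps)
#' flank the vowel; the phoneme interval boundaries are exact by
#' construction.
#'
#' @param spec A [vowel_spec()] for the vowel nucleus.
#' @param consonant_dur Burst duration, s. Default 0.08.
#' @param consonant_level_db Burst RMS, dB re 1.0. Default `spec$rms_db - 10`.
#' @param labels ARPABET labels, `c(consonant, vowel, consonant)`.
#'   Default `c("B", "AA", "B")`.
#' @return A list: `recording`, `phonemes` (tibble `label`, `start`, `end`,
#'   `kind`), `truth` (from [synth_vowel()]).
#' @export
synth_word <- function(spec, consonant_dur = 0.08,
                       consonant_level_db = spec$rms_db - 10,
                       labels = c("B", "AA", "B")) {
  vw <- synth_vowel(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)
  fs <- spec$rate
  nc <- round(consonant_dur * fs)
  burst <- function() {
    b <- stats::rnorm(nc)
    bf <- signal::butter(2, c(min(0.45, 2000 / (fs / 2)),
                              min(0.9, 6000 / (fs / 2))), "pass")
    b <- as.numeric(signal::filtfilt(bf, b))
    ramp_n <- max(2L, round(0.005 * fs))
    env <- rep(1, nc)
    env[1:ramp_n] <- seq(0, 1, length.out = ramp_n)
    env[(nc - ramp_n + 1):nc] <- seq(1, 0, length.out = ramp_n)
    b <- b * env
    b * 10^(consonant_level_db / 20) / sqrt(mean(b^2))
  }
  c1 <- burst()
  c2 <- burst()
  x <- c(c1, vw$recording$samples, c2)
  vdur <- vw$recording$duration
  phonemes <- tibble::tibble(
    label = labels,
    start = c(0, consonant_dur, consonant_dur + vdur),
    end = c(consonant_dur, consonant_dur + vdur, 2 * consonant_dur + vdur),
    kind = arpabet_kind(labels)
  )
  list(recording = audio_recording(x, fs), phonemes = phonemes,
       truth = vw$truth)
}

#' Specification of a two-condition (OFF/ON) synthetic dataset
#'
#' @param n_trials Trials per condition (>= 2). Default 20.
#' @param effects Named list of effects applied to the ON condition:
#'   `intensity_db` (additive level shift, dB), `f1_pct`/`f2_pct`
#'   (multiplicative formant-frequency shift, percent), `breaks_delta`
#'   (change in inserted gaps per trial; e.g. `-1` removes the OFF
#'   condition's one gap), `snr_db` (replaces the base SNR), `jitter`
#'   (replaces the base jitter, percent). Empty list = null dataset.
#' @param base A [vowel_spec()] describing the OFF condition.
#' @param off_breaks Gaps inserted in every OFF trial (data frame
#'   `start`/`length`, or NULL).
#' @param trial_sd Natural trial-to-trial variability: list with
#'   `f0_range_pct` (per-trial f0 drawn uniformly in +/- this percent of the
#'   base f0 — repetitions of a word drift in pitch over a session),
#'   `formant_pct` and `level_db` (Gaussian standard deviations).
#'   Default 8% f0 half-range, 1% formants, 0.5 dB level.
#' @param seed Master seed; per-trial seeds are derived from it.
#' @return A list of class `condition_effect_spec`.
#' @export
condition_effect_spec <- function(n_trials = 20, effects = list(),
                                  base = vowel_spec(),
                                  off_breaks = NULL,
                                  trial_sd = list(f0_range_pct = 8,
                                                  formant_pct = 1,
                                                  level_db = 0.5),
                                  seed = 1) {
  stopifnot(n_trials >= 2)
  known <- c("intensity_db", "f1_pct", "f2_pct", "breaks_delta", "snr_db",
             "jitter")
  bad <- setdiff(names(effects), known)
  if (length(bad)) stop("unknown effect(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(n_trials = n_trials, effects = effects, base = base,
                 off_breaks = off_breaks, trial_sd = trial_sd, seed = seed),
            class = "condition_effect_spec")
}

#' Generate a two-condition synthetic dataset
#'
#' Writes (or returns in memory) OFF trials drawn from the base spec and ON
#' trials with the requested effects applied, each trial perturbed by the
#' natural-variability model, with a truth table recording every injected
#' effect.
#'
#' @param spec A [condition_effect_spec()].
#' @param out_dir Optional directory; when given, WAV + TextGrid + manifest
#'   CSV + truth CSV are written there.
#' @param word Word label used in the manifest. Default `"ba"`.
#' @param session Session label. Default `"S1"`.
#' @return A list: `manifest` (tibble; with `recording`/`phonemes`
#'   list-columns when in memory, file paths when written) and `truth`
#'   (tibble of per-trial ground truth).
#' @export
synth_condition_dataset <- function(spec, out_dir = NULL, word = "ba",
                                    session = "S1") {
  stopifnot(inherits(spec, "condition_effect_spec"))
  ef <- spec$effects
  base <- spec$base
  rows <- list()
  truth <- list()
  for (cond in c("OFF", "ON")) {
    for (k in seq_len(spec$n_trials)) {
      trial_seed <- (spec$seed %% 10000L) * 100000L +
        (cond == "ON") * 50000L + k
      old <- .Random.seed_save()
      set.seed(trial_seed)
      v <- spec$trial_sd
      f0_k <- base$f0 * (1 + v$f0_range_pct / 100 * stats::runif(1, -1, 1))
      fm_jit <- 1 + v$formant_pct / 100 * stats::rnorm(length(base$formants))
      fm_k <- Map(function(fm, j) c(fm[1] * j, fm[2]), base$formants,
                  as.list(fm_jit))
      lvl_k <- base$rms_db + v$level_db * stats::rnorm(1)
      .Random.seed_restore(old)

      snr_k <- base$snr_db
      jit_k <- base$jitter
      brk_k <- spec$off_breaks
      if (cond == "ON") {
        if (!is.null(ef$intensity_db)) lvl_k <- lvl_k + ef$intensity_db
        if (!is.null(ef$f1_pct)) fm_k[[1]][1] <- fm_k[[1]][1] * (1 + ef$f1_pct / 100)
        if (!is.null(ef$f2_pct)) fm_k[[2]][1] <- fm_k[[2]][1] * (1 + ef$f2_pct / 100)
        if (!is.null(ef$snr_db)) snr_k <- ef$snr_db
        if (!is.null(ef$jitter)) jit_k <- ef$jitter
        if (!is.null(ef$breaks_delta) && !is.null(brk_k)) {
          keep <- nrow(brk_k) + ef$breaks_delta
          brk_k <- if (keep <= 0) NULL else brk_k[seq_len(keep), , drop = FALSE]
        }
      }
      sp <- vowel_spec(f0 = min(500, max(60, f0_k)), jitter = jit_k,
                       formants = fm_k, duration = base$duration,
                       rms_db = lvl_k, snr_db = snr_k, breaks = brk_k,
                       rate = base$rate, seed = trial_seed)
      wd <- synth_word(sp)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        word = word, session = session, condition = cond, repetition = k,
        recording = list(wd$recording), phonemes = list(wd$phonemes)
      )
      truth[[length(truth) + 1L]] <- tibble::tibble(
        condition = cond, repetition = k, seed = trial_seed,
        f0 = sp$f0, f1 = fm_k[[1]][1], f2 = fm_k[[2]][1],
        rms_db = lvl_k, snr_db = snr_k, jitter = jit_k,
        n_breaks = wd$truth$n_breaks_16_67
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(seq_len(nrow(manifest)), function(i) {
      stem <- sprintf("%s_%s_%s_r%02d", word, session,
                      manifest$condition[i], manifest$repetition[i])
      wav <- file.path(out_dir, paste0(stem, ".wav"))
      tg <- file.path(out_dir, paste0(stem, ".TextGrid"))
      write_wav(manifest$recording[[i]], wav)
      write_textgrid(manifest$phonemes[[i]], tg,
                     xmax = manifest$recording[[i]]$duration)
      wav
    }, character(1))
    manifest$audio <- paths
    manifest$textgrid <- sub("\\.wav$", ".TextGrid", paths)
    out <- manifest[, c("audio", "textgrid", "word", "session",
                        "condition", "repetition")]
    utils::write.csv(out, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, truth = truth)
}

#' Synthesize burst-like EMG over baseline noise
#'
#' A band-limited (60-500 Hz) Gaussian-noise carrier amplitude-modulated by
#' Hann burst envelopes, added to baseline noise. Ground-truth movement
#' events are returned with the recording.
#'
#' @param burst_amplitude Envelope peak amplitude (carrier units). One value
#'   or one per burst.
#' @param burst_times Data frame with `start`, `end` (s) of each burst.
#' @param baseline_sd Baseline noise sd. Default 0.05.
#' @param duration Seconds. Default computed from the last burst + 0.5.
#' @param rate Hz. Default 2000.
#' @param muscle Channel name. Default `"MASS"`.
#' @param seed Integer seed.
#' @return A list: `recording` ([emg_recording()] with `movement_events`)
#'   and `truth`.
#' @export
synth_emg <- function(burst_amplitude = 1, burst_times,
                      baseline_sd = 0.05, duration = NULL, rate = 2000,
                      muscle = "MASS", seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(duration)) duration <- max(burst_times$end) + 0.5
  n <- round(duration * rate)
  amp <- rep_len(burst_amplitude, nrow(burst_times))
  bf <- signal::butter(2, c(60, 500) / (rate / 2), "pass")
  carrier <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
  carrier <- carrier / stats::sd(carrier)
  env <- numeric(n)
  for (k in seq_len(nrow(burst_times))) {
    i0 <- round(burst_times$start[k] * rate) + 1L
    i1 <- min(n, round(burst_times$end[k] * rate))
    env[i0:i1] <- amp[k] * hann_window(i1 - i0 + 1L)
  }
  x <- carrier * env + stats::rnorm(n, sd = baseline_sd)
  rec <- emg_recording(stats::setNames(list(x), muscle), rate,
                       movement_events = tibble::as_tibble(burst_times))
  list(recording = rec,
       truth = list(burst_amplitude = amp, burst_times = burst_times,
                    baseline_sd = baseline_sd))
}

#' Synthesize a stimulation-triggered MEP recording
#'
#' Gaussian-shaped evoked potentials at a fixed latency after each trigger,
#' over baseline noise.
#'
#' @param n_trials Number of stimulation triggers. Default 20.
#' @param peak MEP peak amplitude. Default 0.5.
#' @param sigma MEP Gaussian sd, s. Default 0.005.
#' @param latency MEP centre after the trigger, s. Default 0.030.
#' @param baseline_sd Baseline noise sd. Default 0.01.
#' @param rate Hz. Default 6000.
#' @param muscle Channel name. Default `"MASS"`.
#' @param seed Integer seed.
#' @return A list: `recording` (with `stim_events`) and `truth` (including
#'   the closed-form rectified-average AUC over a window, as
#'   `auc_closed_form(window)` via fields `peak`, `sigma`, `latency`).
#' @export
synth_mep <- function(n_trials = 20, peak = 0.5, sigma = 0.005,
                      latency = 0.030, baseline_sd = 0.01, rate = 6000,
                      muscle = "MASS", seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  span <- 0.2
  n <- round(n_trials * span * rate) + rate
  x <- stats::rnorm(n, sd = baseline_sd)
  triggers <- (seq_len(n_trials) - 1) * span + 0.05
  tt <- (seq_len(n) - 1) / rate
  for (tr in triggers) {
    x <- x + peak * exp(-0.5 * ((tt - tr - latency) / sigma)^2)
  }
  rec <- emg_recording(stats::setNames(list(x), muscle), rate,
                       stim_events = triggers)
  list(recording = rec,
       truth = list(peak = peak, sigma = sigma, latency = latency,
                    baseline_sd = baseline_sd))
}

#' Synthesize an oscillatory landmark trajectory
#'
#' Repetitions of one-period sinusoidal vertical displacement separated by
#' rest, with Gaussian positional jitter; ground-truth movement events are
#' emitted alongside.
#'
#' @param amplitude_px Peak displacement, pixels. Default 20.
#' @param freq_hz Movement frequency, Hz. Default 1.
#' @param n_reps Repetitions. Default 5.
#' @param rest_s Rest between repetitions, s. Default 0.5.
#' @param fps Frame rate, Hz. Default 30.
#' @param noise_sd_px Positional jitter sd, pixels. Default 0.
#' @param label Articulator label. Default `"lower lip"`.
#' @param seed Integer seed.
#' @return A list: `trajectory` ([landmark_trajectory()]), `events` (tibble
#'   `start`, `end`, 1-based frames), `truth`.
#' @export
synth_trajectory <- function(amplitude_px = 20, freq_hz = 1, n_reps = 5,
                             rest_s = 0.5, fps = 30, noise_sd_px = 0,
                             label = "lower lip", seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  period <- 1 / freq_hz
  move_n <- round(period * fps)
  rest_n <- round(rest_s * fps)
  y <- rep(0, rest_n)
  events <- list()
  for (k in seq_len(n_reps)) {
    start <- max(1L, length(y)) # the resting (neutral) frame opens the event
    tt <- seq_len(move_n) / fps
    y <- c(y, amplitude_px * sin(2 * pi * freq_hz * tt), rep(0, rest_n))
    events[[k]] <- tibble::tibble(start = start, end = start + move_n + 2L)
  }
  n <- length(y)
  x <- rep(100, n)
  if (noise_sd_px > 0) {
    x <- x + stats::rnorm(n, sd = noise_sd_px)
    y <- y + stats::rnorm(n, sd = noise_sd_px)
  }
  list(
    trajectory = landmark_trajectory(x, 200 + y, fps, label),
    events = dplyr::bind_rows(events),
    truth = list(amplitude_px = amplitude_px, freq_hz = freq_hz,
                 n_reps = n_reps)
  )
}
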