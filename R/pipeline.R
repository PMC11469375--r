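#' Pipeline run configuration
#'
#' Bundles the per-module configurations, the trial-selection policy and the
#' bootstrap settings used by [run_speech_pipeline()] and
#' [run_motor_pipeline()].
#'
#' @param intensity An [intensity_config()].
#' @param pitch A [pitch_config()].
#' @param cepstral A [cepstral_config()].
#' @param formant A [formant_config()].
#' @param mep A [mep_config()].
#' @param envelope An [envelope_config()].
#' @param exclude_first_repetition Selection policy flag. Default FALSE
#'   (synthetic datasets have no initiation artifacts; set TRUE for
#'   patient-style data).
#' @param n_resamples Bootstrap resamples. Default 10000.
#' @param alphas Bootstrap alpha levels. Default `c(0.05, 0.01, 0.001)`.
#' @param seed Master seed for all stochastic steps.
#' @param max_skip_frac Abort when more than this fraction of trials fails
#'   to load. Default 0.2.
#' @return A list of class `run_config`.
#' @export
run_config <- function(intensity = intensity_config(),
                       pitch = pitch_config(),
                       cepstral = cepstral_config(),
                       formant = formant_config(),
                       mep = mep_config(),
                       envelope = envelope_config(),
                       exclude_first_repetition = FALSE,
                       n_resamples = 10000,
                       alphas = c(0.05, 0.01, 0.001),
                       seed = 1,
                       max_skip_frac = 0.2) {
  structure(list(intensity = intensity, pitch = pitch, cepstral = cepstral,
                 formant = formant, mep = mep, envelope = envelope,
                 exclude_first_repetition = exclude_first_repetition,
                 n_resamples = n_resamples, alphas = alphas, seed = seed,
                 max_skip_frac = max_skip_frac),
            class = "run_config")
}

# load one manifest row: in-memory list-columns take precedence over paths
load_trial <- function(row) {
  rec <- if ("recording" %in% names(row) && !is.null(row$recording[[1]])) {
    row$recording[[1]]
  } else {
    read_wav(row$audio)
  }
  ph <- if ("phonemes" %in% names(row) && !is.null(row$phonemes[[1]])) {
    row$phonemes[[1]]
  } else {
    parse_textgrid(row$textgrid)
  }
  list(recording = rec, phonemes = ph)
}

#' Run the speech-analysis pipeline over a trial manifest
#'
#' For each selected trial: speech intensity (median of the median-filtered
#' spectrogram power trace), voice breaks (pitch track, pulse train, break
#' count), CPPS, and per-vowel F1/F2 summaries. Then condition comparisons:
#' per-word intensity (bootstrap OFF vs ON, banded classification), pooled
#' voice-break distribution (per-condition mode), pooled CPPS percent change
#' vs the OFF median (bootstrap), and per-vowel formant percent change with
#' bootstrap significance.
#'
#' @param manifest A manifest tibble: columns `word`, `session`, `condition`,
#'   `repetition` plus either `audio`/`textgrid` paths or in-memory
#'   `recording`/`phonemes` list-columns (as produced by
#'   [synth_condition_dataset()]).
#' @param config A [run_config()].
#' @return A list of class `speech_pipeline_result`:
#'   `trial_metrics` (one row per trial: `intensity_db`, `n_breaks`,
#'   `cpps_db`, `vowel`, `mean_f1`, `mean_f2`),
#'   `intensity_comparison` (per word), `break_summary` (per condition),
#'   `cpps_comparison`, `formant_comparison` (per vowel/formant), `skipped`.
#' @export
run_speech_pipeline <- function(manifest, config = run_config()) {
  manifest <- select_trials(tibble::as_tibble(manifest),
                            config$exclude_first_repetition)
  n_total <- nrow(manifest)
  stopifnot(n_total > 0)

  rows <- vector("list", n_total)
  skipped <- character(0)
  for (i in seq_len(n_total)) {
    row <- manifest[i, ]
    trial <- tryCatch(load_trial(row), error = function(e) {
      message("skipping trial ", i, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(trial)) {
      skipped <- c(skipped, sprintf("%s/%s/%s/r%d", row$word, row$session,
                                    row$condition, row$repetition))
      next
    }
    rec <- trial$recording
    trace <- spectrogram_power(rec, config$intensity)
    intensity_db <- trial_intensity(trace, config$intensity)
    track <- track_pitch(rec, config$pitch)
    pulses <- extract_pulses(rec, track)
    vb <- suppressWarnings(count_voice_breaks(pulses, track))
    cpps_db <- cpps_of(rec, config$cepstral)

    vowels <- trial$phonemes[trial$phonemes$kind == "vowel", , drop = FALSE]
    vowel <- NA_character_
    mean_f1 <- mean_f2 <- NA_real_
    if (nrow(vowels) > 0) {
      vrow <- vowels[which.max(vowels$end - vowels$start), ]
      seg <- crop_recording(rec, vrow$start, vrow$end)
      seg <- preemphasize(seg, config$formant$preemph_coeff)
      tk <- lpc_formant_track(seg, config$formant)
      sm <- summarize_vowel_formants(tk, config$formant)
      vowel <- vrow$label
      mean_f1 <- sm$mean_f1
      mean_f2 <- sm$mean_f2
    }
    rows[[i]] <- tibble::tibble(
      word = row$word, session = row$session, condition = row$condition,
      repetition = row$repetition, intensity_db = intensity_db,
      n_breaks = vb$n_breaks, cpps_db = cpps_db, vowel = vowel,
      mean_f1 = mean_f1, mean_f2 = mean_f2
    )
  }
  if (length(skipped) / n_total > config$max_skip_frac) {
    stop(sprintf("%d of %d trials skipped (> %.0f%%); aborting run",
                 length(skipped), n_total, 100 * config$max_skip_frac),
         call. = FALSE)
  }
  tm <- dplyr::bind_rows(rows)

  list_result <- list(
    trial_metrics = tm,
    intensity_comparison = compare_intensity(tm, config),
    break_summary = summarize_breaks(tm),
    cpps_comparison = compare_cpps(tm, config),
    formant_comparison = compare_formants(tm, config),
    skipped = skipped
  )
  structure(list_result, class = "speech_pipeline_result")
}

compare_intensity <- function(tm, config) {
  words <- unique(tm$word)
  out <- lapply(seq_along(words), function(wi) {
    d <- tm[tm$word == words[wi], ]
    off <- d$intensity_db[d$condition == "OFF"]
    on <- d$intensity_db[d$condition != "OFF"]
    if (length(off) < 2 || length(on) < 2) return(NULL)
    b <- bootstrap_diff_means(on, off, config$n_resamples, config$alphas,
                              seed = config$seed + wi)
    tibble::tibble(
      word = words[wi], n_off = length(off), n_on = length(on),
      mean_off_db = mean(off), mean_on_db = mean(on),
      delta_db = b$observed_diff,
      category = classify_intensity_change(b$observed_diff),
      stars = significance_stars(b),
      ci_low_05 = b$ci$lower[b$ci$alpha == 0.05],
      ci_high_05 = b$ci$upper[b$ci$alpha == 0.05]
    )
  })
  dplyr::bind_rows(out)
}

summarize_breaks <- function(tm) {
  tm |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      total_breaks = sum(.data$n_breaks),
      mode_breaks = distribution_mode(.data$n_breaks),
      mean_breaks = mean(.data$n_breaks),
      .groups = "drop"
    )
}

distribution_mode <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

compare_cpps <- function(tm, config) {
  off <- tm$cpps_db[tm$condition == "OFF"]
  on <- tm$cpps_db[tm$condition != "OFF"]
  if (length(off) < 2 || length(on) < 2) return(tibble::tibble())
  pct_on <- percent_change_vs_off_median(on, off)
  pct_off <- percent_change_vs_off_median(off, off)
  b <- bootstrap_diff_means(pct_on, pct_off, config$n_resamples,
                            config$alphas, seed = config$seed + 101L)
  tibble::tibble(
    metric = "cpps_pct_change_vs_off_median",
    n_off = length(off), n_on = length(on),
    median_pct_change_on = stats::median(pct_on),
    mean_diff_pct = b$observed_diff,
    stars = significance_stars(b),
    ci_low_05 = b$ci$lower[b$ci$alpha == 0.05],
    ci_high_05 = b$ci$upper[b$ci$alpha == 0.05]
  )
}

compare_formants <- function(tm, config) {
  vowels <- unique(stats::na.omit(tm$vowel))
  out <- lapply(seq_along(vowels), function(vi) {
    d <- tm[!is.na(tm$vowel) & tm$vowel == vowels[vi], ]
    off <- d[d$condition == "OFF", ]
    on <- d[d$condition != "OFF", ]
    if (nrow(off) < 2 || nrow(on) < 2) return(NULL)
    pc <- formant_percent_change(off, on)
    pc$vowel <- vowels[vi]
    pc$stars <- vapply(c("mean_f1", "mean_f2"), function(col) {
      b <- bootstrap_diff_means(on[[col]][!is.na(on[[col]])],
                                off[[col]][!is.na(off[[col]])],
                                config$n_resamples, config$alphas,
                                seed = config$seed + 200L + vi)
      significance_stars(b)
    }, character(1))
    pc
  })
  dplyr::bind_rows(out)
}

#' @export
print.speech_pipeline_result <- function(x, ...) {
  cat(sprintf("<speech_pipeline_result> %d trial(s), %d skipped\n",
              nrow(x$trial_metrics), length(x$skipped)))
  cat("-- intensity (per word) --\n"); print(x$intensity_comparison)
  cat("-- voice breaks --\n"); print(x$break_summary)
  cat("-- CPPS --\n"); print(x$cpps_comparison)
  cat("-- formants --\n"); print(x$formant_comparison)
  invisible(x)
}

#' Run the motor (EMG / kinematics / swallow) pipeline
#'
#' All sections are optional; supply what you have.
#'
#' @param mep List with `off` and `on` [emg_recording()]s carrying
#'   `stim_events`; reported as percent MEP AUC increase per muscle.
#' @param movement An [emg_recording()] with `movement_events` that include
#'   a `condition` column; envelope AUC and OFF-referenced z-scores.
#' @param kinematics List with `off` and `on` lists, each holding `traj`
#'   (a [landmark_trajectory()]) and `events`; per-event amplitude
#'   normalized by the OFF-condition mean amplitude, and velocity change.
#' @param aperture List with `off` and `on` lists, each holding `xs`, `ys`
#'   matrices; percent variation of the mean aperture area.
#' @param swallow Tibble with `bolus`, `condition`, and either duration
#'   fields (`first_barium_frame`, `swallow_end_frame`, `fps`) or a
#'   `residue_fraction` column; paired one-tailed t-tests across boluses.
#' @param config A [run_config()].
#' @return A list of class `motor_pipeline_result` with one comparison
#'   tibble per supplied section.
#' @export
run_motor_pipeline <- function(mep = NULL, movement = NULL,
                               kinematics = NULL, aperture = NULL,
                               swallow = NULL, config = run_config()) {
  out <- list()

  if (!is.null(mep)) {
    a_off <- mep_auc(mep$off, config$mep)
    a_on <- mep_auc(mep$on, config$mep)
    out$mep <- dplyr::inner_join(a_off, a_on, by = "muscle",
                                 suffix = c("_off", "_on")) |>
      dplyr::mutate(pct_increase =
        100 * (.data$auc_on - .data$auc_off) / .data$auc_off)
  }

  if (!is.null(movement)) {
    env <- emg_envelope(movement, config$envelope)
    out$movement <- movement_auc(env)
  }

  if (!is.null(kinematics)) {
    m_off <- movement_amplitude_velocity(kinematics$off$traj,
                                         kinematics$off$events)
    m_on <- movement_amplitude_velocity(kinematics$on$traj,
                                        kinematics$on$events)
    base_amp <- mean(m_off$amplitude_px)
    out$kinematics <- dplyr::bind_rows(
      dplyr::mutate(m_off, condition = "OFF"),
      dplyr::mutate(m_on, condition = "ON")
    ) |>
      dplyr::mutate(norm_amplitude = .data$amplitude_px / base_amp)
    out$kinematics_summary <- tibble::tibble(
      mean_norm_amplitude_on = mean(m_on$amplitude_px) / base_amp,
      velocity_pct_change = 100 * (mean(m_on$mean_velocity_px_s) -
        mean(m_off$mean_velocity_px_s)) / mean(m_off$mean_velocity_px_s)
    )
  }

  if (!is.null(aperture)) {
    a_off <- mean(mouth_aperture(aperture$off$xs, aperture$off$ys))
    a_on <- mean(mouth_aperture(aperture$on$xs, aperture$on$ys))
    out$aperture <- tibble::tibble(
      mean_area_off = a_off, mean_area_on = a_on,
      pct_variation = 100 * (a_on - a_off) / a_off
    )
  }

  if (!is.null(swallow)) {
    sw <- tibble::as_tibble(swallow)
    if (!"duration_s" %in% names(sw) && "first_barium_frame" %in% names(sw)) {
      sw <- swallow_duration(sw)
    }
    metrics <- intersect(c("duration_s", "residue_fraction"), names(sw))
    out$swallow <- dplyr::bind_rows(lapply(metrics, function(mcol) {
      wide <- tidyr::pivot_wider(sw[, c("bolus", "condition", mcol)],
                                 names_from = "condition",
                                 values_from = dplyr::all_of(mcol))
      ht <- paired_t(wide$ON, wide$OFF, tail = "less")
      tibble::tibble(metric = mcol,
                     mean_off = mean(wide$OFF), mean_on = mean(wide$ON),
                     t = ht$statistic, p = ht$p_value,
                     degenerate = ht$degenerate)
    }))
  }

  structure(out, class = "motor_pipeline_result")
}

#' @export
print.motor_pipeline_result <- function(x, ...) {
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(x[[nm]])
  }
  invisible(x)
}
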