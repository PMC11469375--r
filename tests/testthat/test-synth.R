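test_that("synthesis is a pure function of spec and seed", {
  sp <- vowel_spec(f0 = 140, jitter = 2, snr_db = 20, seed = 9)
  v1 <- synth_vowel(sp)
  v2 <- synth_vowel(sp)
  expect_identical(v1$recording$samples, v2$recording$samples)
  v3 <- synth_vowel(vowel_spec(f0 = 140, jitter = 2, snr_db = 20, seed = 10))
  expect_false(identical(v1$recording$samples, v3$recording$samples))
})

test_that("the synthesized RMS level and f0 match the spec", {
  v <- synth_vowel(vowel_spec(f0 = 120, rms_db = -20, seed = 4))
  expect_equal(20 * log10(sqrt(mean(v$recording$samples^2))), -20,
               tolerance = 0.01)
  tr <- track_pitch(v$recording)
  expect_equal(median(tr$f0, na.rm = TRUE), 120, tolerance = 1.2 / 120)
})

test_that("constructed gaps map one-to-one onto counted voice breaks", {
  thr <- 1.25 / 75
  v <- synth_vowel(vowel_spec(f0 = 125, duration = 1.4, seed = 6,
        breaks = data.frame(start = c(0.3, 0.6, 0.9, 1.2),
                            length = c(0.010, 0.040, thr, 0.050))))
  expect_equal(v$truth$n_breaks_16_67, 2L)
  tr <- track_pitch(v$recording)
  vb <- count_voice_breaks(extract_pulses(v$recording, tr), tr)
  expect_equal(vb$n_breaks, v$truth$n_breaks_16_67)
  expect_error(synth_vowel(vowel_spec(breaks = data.frame(
    start = c(0.1, 0.11), length = c(0.05, 0.05)))), "overlap")
})

test_that("synth_word emits a CVC TextGrid whose vowel closes the loop", {
  sp <- vowel_spec(f0 = 110, duration = 0.35, seed = 12,
                   formants = list(c(600, 80), c(1400, 90), c(2600, 120)))
  wd <- synth_word(sp)
  expect_equal(nrow(wd$phonemes), 3)
  expect_equal(wd$phonemes$kind, c("consonant", "vowel", "consonant"))
  expect_true(all(diff(wd$phonemes$start) > 0))
  vrow <- wd$phonemes[2, ]
  seg <- preemphasize(crop_recording(wd$recording, vrow$start, vrow$end))
  sm <- summarize_vowel_formants(lpc_formant_track(seg))
  expect_equal(sm$mean_f1, 600, tolerance = 0.05)
  expect_equal(sm$mean_f2, 1400, tolerance = 0.05)
})

test_that("noise bursts alone carry no voicing", {
  sp <- vowel_spec(duration = 0.2, seed = 3)
  wd <- synth_word(sp)
  burst <- crop_recording(wd$recording, 0, wd$phonemes$end[1])
  # analyse the burst padded to one pitch frame
  padded <- audio_recording(c(burst$samples, numeric(16000 * 0.1)), 16000)
  expect_lt(mean(track_pitch(padded)$voiced), 0.2)
})

test_that("condition datasets carry truth and honor injected effects", {
  ds <- synth_condition_dataset(condition_effect_spec(
    n_trials = 3, effects = list(intensity_db = 6, f1_pct = 8),
    base = vowel_spec(duration = 0.3), seed = 2))
  expect_equal(nrow(ds$manifest), 6)
  expect_equal(nrow(ds$truth), 6)
  on <- ds$truth[ds$truth$condition == "ON", ]
  off <- ds$truth[ds$truth$condition == "OFF", ]
  expect_equal(mean(on$rms_db) - mean(off$rms_db), 6, tolerance = 1)
  # per-trial natural variation plus the exact multiplicative f1 shift
  expect_gt(mean(on$f1) / mean(off$f1), 1.05)
  # determinism of the whole dataset
  ds2 <- synth_condition_dataset(condition_effect_spec(
    n_trials = 3, effects = list(intensity_db = 6, f1_pct = 8),
    base = vowel_spec(duration = 0.3), seed = 2))
  expect_identical(ds$truth, ds2$truth)
  expect_identical(ds$manifest$recording[[1]]$samples,
                   ds2$manifest$recording[[1]]$samples)
})

test_that("written datasets load back through the file-based pipeline path", {
  dir <- withr::local_tempdir()
  ds <- synth_condition_dataset(condition_effect_spec(
    n_trials = 2, base = vowel_spec(duration = 0.25), seed = 3),
    out_dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  rec <- read_wav(man$audio[1])
  expect_equal(rec$rate, 16000)
  ph <- parse_textgrid(man$textgrid[1])
  expect_equal(nrow(ph), 3)
  expect_equal(ph$kind[2], "vowel")
})

test_that("synthetic EMG bursts and trajectories match their ground truth", {
  s <- synth_emg(burst_amplitude = 2,
                 burst_times = data.frame(start = c(0.5, 2), end = c(1, 2.5)),
                 seed = 8)
  expect_equal(length(s$recording$channels$MASS),
               round(s$recording$duration * s$recording$rate))
  env <- emg_envelope(s$recording)
  in_burst <- mean(env$channels$MASS[round(0.6 * 2000):round(0.9 * 2000)])
  at_rest <- mean(env$channels$MASS[round(1.2 * 2000):round(1.8 * 2000)])
  expect_gt(in_burst, 3 * at_rest)

  tj <- synth_trajectory(amplitude_px = 20, seed = 5)
  m <- movement_amplitude_velocity(tj$trajectory, tj$events)
  expect_equal(m$amplitude_px, rep(20, 5), tolerance = 1 / 20)
  still <- synth_trajectory(amplitude_px = 0, n_reps = 2, seed = 5)
  m0 <- movement_amplitude_velocity(still$trajectory, still$events)
  expect_equal(m0$amplitude_px, c(0, 0))
})
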