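test_that("pre-emphasis implements y[n] = x[n] - c x[n-1]", {
  r <- audio_recording(rep(1, 5), 8000)
  expect_equal(preemphasize(r, 0.63)$samples, c(1, rep(0.37, 4)))
  expect_equal(preemphasize(r, 0)$samples, r$samples)
  imp <- audio_recording(c(1, 0, 0, 0), 8000)
  expect_equal(preemphasize(imp, 0.63)$samples, c(1, -0.63, 0, 0))
})

test_that("LPC order follows round(rate/1000) + 2", {
  expect_equal(lpc_order(30000), 32L)
  expect_equal(lpc_order(16000), 18L)
  expect_equal(lpc_order(44100), 46L)
  expect_equal(lpc_order(22500), 25L) # round-half-up
})

test_that("a synthetic two-resonance vowel recovers its formants", {
  sp <- vowel_spec(f0 = 120, formants = list(c(700, 80), c(1200, 90)),
                   duration = 0.4, rate = 16000, seed = 3)
  seg <- preemphasize(synth_vowel(sp)$recording)
  tk <- lpc_formant_track(seg)
  expect_equal(median(tk$f1, na.rm = TRUE), 700, tolerance = 35 / 700)
  expect_equal(median(tk$f2, na.rm = TRUE), 1200, tolerance = 60 / 1200)
})

test_that("emitted formants always satisfy the 90 Hz / 400 Hz gates, ascending", {
  for (seed in 1:3) {
    seg <- preemphasize(test_vowel(seed = seed))
    tk <- lpc_formant_track(seg)
    f <- as.matrix(tk[, c("f1", "f2", "f3", "f4")])
    b <- as.matrix(tk[, c("b1", "b2", "b3", "b4")])
    expect_true(all(f > 90, na.rm = TRUE))
    expect_true(all(b < 400, na.rm = TRUE))
    expect_true(all(b > 0, na.rm = TRUE))
    ord_ok <- apply(f, 1, function(row) {
      row <- row[!is.na(row)]
      length(row) < 2 || all(diff(row) > 0)
    })
    expect_true(all(ord_ok))
  }
})

test_that("formant tracks are deterministic", {
  seg <- preemphasize(test_vowel(seed = 5))
  expect_identical(lpc_formant_track(seg), lpc_formant_track(seg))
})

test_that("vowel summary keeps 71 warped points and handles ramps/outliers", {
  cfg <- formant_config()
  mk_track <- function(f1, f2) {
    n <- length(f1)
    structure(tibble::tibble(time = seq_len(n) * 0.003,
                             f1 = f1, f2 = f2,
                             f3 = rep(NA_real_, n), f4 = rep(NA_real_, n),
                             b1 = 80, b2 = 90, b3 = NA_real_, b4 = NA_real_),
              class = c("formant_track", class(tibble::tibble())))
  }
  const <- summarize_vowel_formants(mk_track(rep(500, 10), rep(1500, 10)), cfg)
  expect_equal(const$mean_f1, 500)
  expect_equal(const$n_frames_used, 71L)

  ramp <- summarize_vowel_formants(
    mk_track(seq(400, 600, length.out = 20), rep(1500, 20)), cfg)
  expect_equal(ramp$mean_f1, 500, tolerance = 2 / 500)

  spiked <- c(rep(500, 6), 900, rep(500, 7))
  spike <- summarize_vowel_formants(mk_track(spiked, rep(1500, 14)), cfg)
  expect_equal(spike$mean_f1, 500, tolerance = 1 / 500)

  few <- summarize_vowel_formants(mk_track(rep(500, 3), rep(1500, 3)), cfg)
  expect_true(is.na(few$mean_f1))
  expect_equal(few$n_frames_used, 0L)
})

test_that("formant percent change is plain arithmetic on condition means", {
  off <- tibble::tibble(mean_f1 = c(500, 500), mean_f2 = c(1500, 1500))
  on_same <- off
  expect_equal(formant_percent_change(off, on_same)$pct_change, c(0, 0))
  on_up <- tibble::tibble(mean_f1 = c(550, 550), mean_f2 = c(1500, 1500))
  pc <- formant_percent_change(off, on_up)
  expect_equal(pc$pct_change[pc$formant == "F1"], 10)
  off0 <- tibble::tibble(mean_f1 = 0, mean_f2 = 1500)
  expect_error(formant_percent_change(off0, on_up), "zero")
})

test_that("short segments are rejected", {
  expect_error(lpc_formant_track(audio_recording(numeric(50) + 1, 16000)),
               "short")
})
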