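test_that("MEP AUC of simple channels matches hand values", {
  rate <- 6000
  n <- 2 * rate
  triggers <- c(0.2, 0.6, 1.0)
  zero <- emg_recording(list(MASS = numeric(n)), rate, stim_events = triggers)
  expect_equal(mep_auc(zero)$auc, 0)

  const <- emg_recording(list(MASS = rep(1, n)), rate, stim_events = triggers)
  expect_equal(mep_auc(const)$auc, 0.065, tolerance = 1e-3)
})

test_that("Gaussian MEP AUC matches the closed-form integral within 1%", {
  m <- synth_mep(n_trials = 20, peak = 0.5, sigma = 0.005, latency = 0.030,
                 baseline_sd = 0, seed = 1)
  got <- mep_auc(m$recording)$auc
  cf <- stats::integrate(function(t) {
    0.5 * exp(-0.5 * ((t - 0.030) / 0.005)^2)
  }, 0.010, 0.075)$value
  expect_equal(got, cf, tolerance = 0.01)
})

test_that("MEP AUC is invariant to trial order and baseline-trial dilution", {
  m <- synth_mep(n_trials = 20, baseline_sd = 0.01, seed = 2)
  a <- mep_auc(m$recording)$auc
  rev_rec <- m$recording
  rev_rec$stim_events <- rev(rev_rec$stim_events)
  expect_equal(mep_auc(rev_rec)$auc, a)
  # triggers landing on pure baseline shift the average by < 1% per the
  # averaging contract at n >= 20
  m2 <- synth_mep(n_trials = 40, baseline_sd = 0, seed = 2)
  a_clean20 <- mep_auc(synth_mep(n_trials = 20, baseline_sd = 0, seed = 2)$recording)$auc
  expect_equal(mep_auc(m2$recording)$auc, a_clean20, tolerance = 0.01)
})

test_that("triggers too close to the record end are skipped with a message", {
  rate <- 6000
  rec <- emg_recording(list(M = rep(1, rate)), rate,
                       stim_events = c(0.1, 0.95))
  expect_message(res <- mep_auc(rec), "skipped")
  expect_equal(res$n_trials, 1L)
})

test_that("the envelope of a 300 Hz sine settles near its rectified mean", {
  fs <- 2000
  t <- seq(0, 5, by = 1 / fs)
  env <- emg_envelope(emg_recording(list(M = sin(2 * pi * 300 * t)), fs))
  steady <- env$channels$M[(2 * fs):(3 * fs)]
  expect_equal(mean(steady), 2 / pi, tolerance = 0.05 / (2 / pi))

  # below-band input is almost fully attenuated
  env10 <- emg_envelope(emg_recording(list(M = sin(2 * pi * 10 * t)), fs))
  expect_lt(max(env10$channels$M[(2 * fs):(3 * fs)]), 0.05)

  envz <- emg_envelope(emg_recording(list(M = numeric(fs)), fs))
  expect_equal(max(envz$channels$M), 0)
})

test_that("envelope scales linearly with input amplitude", {
  s <- synth_emg(burst_amplitude = 1,
                 burst_times = data.frame(start = 0.5, end = 1.0), seed = 3,
                 baseline_sd = 0)
  e1 <- emg_envelope(s$recording)$channels$MASS
  rec3 <- s$recording
  rec3$channels$MASS <- rec3$channels$MASS * 3
  e3 <- emg_envelope(rec3)$channels$MASS
  expect_equal(e3, 3 * e1, tolerance = 1e-8)
})

test_that("movement AUC integrates events and z-scores against OFF", {
  fs <- 1000
  rec <- emg_recording(list(M = rep(1, 4 * fs)), fs)
  ev <- tibble::tibble(start = c(0.5, 2.0), end = c(1.5, 3.0),
                       condition = c("OFF", "ON"))
  ma <- movement_auc(rec, ev)
  expect_equal(ma$auc, c(1, 1), tolerance = 1e-3)
  expect_false(any(ma$z_defined)) # single OFF trial: z undefined

  # degenerate OFF variance flags z undefined
  ev3 <- tibble::tibble(start = c(0.2, 1.0, 1.8, 2.6),
                        end = c(0.7, 1.5, 2.3, 3.1),
                        condition = c("OFF", "OFF", "OFF", "ON"))
  ma3 <- movement_auc(rec, ev3)
  expect_false(any(ma3$z_defined))

  expect_error(movement_auc(rec, tibble::tibble(start = c(0, 0.5),
                                                end = c(1, 1.5))),
               "overlap")
})

test_that("doubled ON burst amplitude drives large positive z", {
  starts <- seq(0.5, by = 1.5, length.out = 10)
  s <- synth_emg(burst_amplitude = c(rep(1, 5), rep(2, 5)),
                 burst_times = data.frame(start = starts, end = starts + 0.5),
                 seed = 4)
  ev <- s$recording$movement_events
  ev$condition <- rep(c("OFF", "ON"), each = 5)
  ma <- movement_auc(emg_envelope(s$recording), ev)
  z_on <- ma$z[ma$condition == "ON"]
  expect_gt(mean(z_on), 2)
  expect_true(all(z_on > 0))
})

test_that("AUC is additive over disjoint sub-windows", {
  fs <- 1000
  set.seed(5)
  x <- abs(stats::rnorm(2 * fs))
  rec <- emg_recording(list(M = x), fs)
  whole <- movement_auc(rec, tibble::tibble(start = 0.2, end = 1.8))$auc
  halves <- movement_auc(rec, tibble::tibble(start = c(0.2, 1.0),
                                             end = c(1.0, 1.8)))$auc
  expect_equal(sum(halves), whole, tolerance = 2 / fs)
})

test_that("EMG CSV round-trip preserves channels and rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time = (0:99) / 1000, MASS = sin(1:100), ORIS = cos(1:100))
  writeLines("# rate: 1000", path)
  suppressWarnings(utils::write.table(df, path, sep = ",", append = TRUE,
                                      row.names = FALSE, quote = FALSE))
  rec <- read_emg_csv(path)
  expect_equal(rec$rate, 1000)
  expect_equal(names(rec$channels), c("MASS", "ORIS"))
  expect_equal(rec$channels$MASS, df$MASS, tolerance = 1e-6)
})
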