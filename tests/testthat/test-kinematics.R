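test_that("amplitude and velocity follow from simple motions", {
  fps <- 30
  static <- landmark_trajectory(rep(5, 60), rep(5, 60), fps)
  ev <- tibble::tibble(start = 1, end = 31)
  m <- movement_amplitude_velocity(static, ev)
  expect_equal(m$amplitude_px, 0)
  expect_equal(m$mean_velocity_px_s, 0)

  lin <- landmark_trajectory(seq(0, 10, length.out = 31), rep(0, 31), fps)
  m2 <- movement_amplitude_velocity(lin, tibble::tibble(start = 1, end = 32))
  expect_equal(m2$amplitude_px, 10)
  expect_equal(m2$mean_velocity_px_s, 10, tolerance = 1e-6)

  # one period of a 20 px, 1 Hz sinusoid at 30 fps
  tj <- synth_trajectory(amplitude_px = 20, freq_hz = 1, n_reps = 1,
                         fps = 30, seed = 1)
  m3 <- movement_amplitude_velocity(tj$trajectory, tj$events)
  expect_equal(m3$amplitude_px, 20, tolerance = 1 / 20)
  expect_equal(m3$mean_velocity_px_s, 80, tolerance = 0.05)

  expect_error(movement_amplitude_velocity(static,
                                           tibble::tibble(start = 1, end = 2)),
               "2 frames")
})

test_that("amplitude is translation invariant; velocity scales with fps", {
  tj <- synth_trajectory(amplitude_px = 15, seed = 2)
  m <- movement_amplitude_velocity(tj$trajectory, tj$events)
  shifted <- landmark_trajectory(tj$trajectory$x + 500, tj$trajectory$y - 200,
                                 tj$trajectory$fps)
  m_sh <- movement_amplitude_velocity(shifted, tj$events)
  expect_equal(m_sh$amplitude_px, m$amplitude_px)
  double_fps <- landmark_trajectory(tj$trajectory$x, tj$trajectory$y,
                                    2 * tj$trajectory$fps)
  m_2x <- movement_amplitude_velocity(double_fps, tj$events)
  expect_equal(m_2x$mean_velocity_px_s, 2 * m$mean_velocity_px_s)
})

test_that("automatic segmentation reproduces constructed events within 2 frames", {
  for (seed in 1:3) {
    tj <- synth_trajectory(amplitude_px = 20, n_reps = 4, seed = seed,
                           noise_sd_px = 0.05)
    auto <- segment_movements(tj$trajectory)
    expect_equal(nrow(auto), 4)
    expect_true(all(abs(auto$start - tj$events$start) <= 2))
    expect_true(all(abs(auto$end - tj$events$end) <= 2))
  }
})

test_that("low-likelihood frames are interpolated away", {
  x <- c(0, 1, 2, 3, 4)
  y <- c(0, 0, 50, 0, 0) # glitch at frame 3
  lk <- c(1, 1, 0.1, 1, 1)
  tj <- landmark_trajectory(x, y, 30, likelihood = lk)
  expect_equal(tj$y[3], 0)
  expect_equal(tj$x[3], 2)
})

test_that("shoelace aperture is exact on tabulated shapes", {
  expect_equal(mouth_aperture(matrix(c(0, 3, 0), 1), matrix(c(0, 0, 4), 1)), 6)
  sq_x <- matrix(c(0, 1, 1, 0), 1)
  sq_y <- matrix(c(0, 0, 1, 1), 1)
  expect_equal(mouth_aperture(sq_x, sq_y), 1)
  # reversed orientation gives the same absolute area
  expect_equal(mouth_aperture(sq_x[, 4:1, drop = FALSE],
                              sq_y[, 4:1, drop = FALSE]), 1)
  # colinear points give zero, not an error
  expect_equal(mouth_aperture(matrix(c(0, 1, 2), 1), matrix(c(0, 1, 2), 1)), 0)
})

test_that("aperture is translation invariant and scales quadratically", {
  set.seed(4)
  xs <- matrix(stats::runif(40, 0, 100), ncol = 4)
  ys <- matrix(stats::runif(40, 0, 100), ncol = 4)
  a <- mouth_aperture(xs, ys)
  expect_equal(mouth_aperture(xs + 37, ys - 12), a)
  expect_equal(mouth_aperture(2.5 * xs, 2.5 * ys), 2.5^2 * a)
})

test_that("swallow duration divides frame spans by fps", {
  tr <- tibble::tibble(bolus = c("5ml", "10ml"),
                       first_barium_frame = c(30, 10),
                       swallow_end_frame = c(120, 11), fps = 30)
  d <- swallow_duration(tr)
  expect_equal(d$duration_s, c(3, 1 / 30))
  bad <- tibble::tibble(first_barium_frame = 10, swallow_end_frame = 10,
                        fps = 30)
  expect_error(swallow_duration(bad), "exceed")
})

test_that("residue fractions normalize ROI areas by the frame area", {
  r <- residue_fraction(c(vallecula = 5000), 640, 480)
  expect_equal(r$fraction[r$region == "total"], 5000 / (640 * 480))
  expect_equal(r$fraction[r$region == "total"], 0.016276, tolerance = 1e-4)

  r2 <- residue_fraction(c(vallecula = 1000, esophagus = 2000), 1000, 1000)
  expect_equal(r2$fraction[r2$region == "total"], 0.003)

  empty <- residue_fraction(numeric(0), 640, 480)
  expect_equal(empty$fraction, 0)

  expect_error(residue_fraction(c(v = 1e7), 640, 480), "larger")
})

test_that("pose-export and tidy landmark CSVs both parse", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "frames,jaw,jaw,jaw,chin,chin,chin",
    "coords,x,y,likelihood,x,y,likelihood",
    "0,10,20,0.99,30,40,0.99",
    "1,11,21,0.99,31,41,0.99"
  ), path)
  lm <- read_landmarks(path, fps = 30)
  expect_named(lm, c("jaw", "chin"))
  expect_equal(lm$jaw$x, c(10, 11))
  expect_equal(lm$chin$y, c(40, 41))

  tidy_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(frame = c(1, 2, 1, 2),
                              articulator = c("jaw", "jaw", "chin", "chin"),
                              x = c(10, 11, 30, 31), y = c(20, 21, 40, 41),
                              likelihood = 1), tidy_path, row.names = FALSE)
  lm2 <- read_landmarks(tidy_path, fps = 30)
  expect_equal(lm2$jaw$x, lm$jaw$x)
})
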