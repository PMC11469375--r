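test_that("degenerate constant groups give zero-width CIs and no rejection", {
  b <- bootstrap_diff_means(rep(5, 10), rep(5, 10), n_resamples = 1000, seed = 1)
  expect_equal(b$observed_diff, 0)
  expect_true(all(b$ci$lower == 0 & b$ci$upper == 0))
  expect_false(any(b$ci$significant))
})

test_that("bootstrap is bit-identical under a fixed seed and leaves the RNG alone", {
  set.seed(99)
  x <- stats::rnorm(30, 1)
  y <- stats::rnorm(30)
  state <- .GlobalEnv$.Random.seed
  b1 <- bootstrap_diff_means(x, y, seed = 42)
  expect_identical(state, .GlobalEnv$.Random.seed)
  b2 <- bootstrap_diff_means(x, y, seed = 42)
  expect_identical(b1$resamples, b2$resamples)
  expect_identical(tidy(b1), tidy(b2))
  b3 <- bootstrap_diff_means(x, y, seed = 43)
  expect_false(identical(b1$resamples, b3$resamples))
})

test_that("CIs are nested across alpha levels", {
  set.seed(7)
  for (k in 1:5) {
    b <- bootstrap_diff_means(stats::rnorm(20, k / 3), stats::rnorm(25),
                              n_resamples = 2000, seed = k)
    ci <- b$ci[order(b$ci$alpha, decreasing = TRUE), ] # 0.05, 0.01, 0.001
    expect_true(all(diff(ci$lower) <= 1e-12))
    expect_true(all(diff(ci$upper) >= -1e-12))
  }
})

test_that("a large separation is detected at alpha 0.001", {
  set.seed(3)
  hits <- vapply(1:20, function(k) {
    b <- bootstrap_diff_means(stats::rnorm(30, 2), stats::rnorm(30),
                              n_resamples = 2000, seed = 1000 + k)
    b$ci$significant[b$ci$alpha == 0.001]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("significance stars follow the figure convention", {
  mk <- function(sig) {
    structure(list(ci = tibble::tibble(alpha = c(0.05, 0.01, 0.001),
                                       significant = sig)),
              class = "bootstrap_result")
  }
  expect_equal(significance_stars(mk(c(FALSE, FALSE, FALSE))), "ns")
  expect_equal(significance_stars(mk(c(TRUE, FALSE, FALSE))), "*")
  expect_equal(significance_stars(mk(c(TRUE, TRUE, FALSE))), "**")
  expect_equal(significance_stars(mk(c(TRUE, TRUE, TRUE))), "***")
})

test_that("bonferroni divides alpha by the family size", {
  expect_equal(bonferroni(0.05, 4), 0.0125)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.01, 5), 0.002)
  expect_error(bonferroni(0.05, 0), ">= 1")
})

test_that("paired t matches the hand-computed textbook case", {
  ht <- paired_t(c(1, 2, 3), c(2, 3, 5))
  # d = (-1, -1, -2): mean -4/3, sd 1/sqrt(3), t = -4, df = 2
  expect_equal(ht$statistic, -4)
  expect_equal(ht$df, 2)
  expect_equal(ht$p_value, 2 * stats::pt(-4, 2))
  one <- paired_t(c(1, 2, 3), c(2, 3, 5), tail = "less")
  expect_equal(one$p_value, stats::pt(-4, 2))
})

test_that("zero-variance differences are flagged degenerate", {
  ht <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(ht$degenerate)
  expect_true(is.na(ht$p_value))
  expect_equal(ht$mean_diff, 1)
})

test_that("the sign-flip permutation test agrees with t on a clear effect", {
  set.seed(21)
  x <- stats::rnorm(25, 1)
  y <- stats::rnorm(25)
  pt_ <- paired_t(x, y)
  pp <- paired_t(x, y, method = "permutation", seed = 5)
  expect_lt(pp$p_value, 0.05)
  expect_lt(pt_$p_value, 0.05)
  # permutation p reproducible from seed
  expect_identical(pp$p_value,
                   paired_t(x, y, method = "permutation", seed = 5)$p_value)
})

test_that("percent change vs OFF median follows its definition", {
  expect_equal(percent_change_vs_off_median(c(11, 12), c(8, 10, 12)),
               c(10, 20))
  v <- c(3, 9, 5)
  expect_equal(percent_change_vs_off_median(v, v)[3], 0) # median element
  expect_error(percent_change_vs_off_median(1, c(0, 0, 0)), "zero")
  # a multiplicative shift of the whole distribution moves the median
  # percent change by exactly that factor
  set.seed(2)
  off <- stats::rnorm(200, 20, 2)
  expect_equal(median(percent_change_vs_off_median(1.109 * off, off)), 10.9,
               tolerance = 1e-6)
})

test_that("phoneme presence rates pool phonemes across words", {
  rec <- tibble::tibble(
    session = "S1", condition = "OFF",
    phoneme = c(rep("T", 10), rep("K", 4)),
    word = c(rep("tack", 4), rep("tick", 6), rep("kit", 4)),
    judged = c(rep("present", 8), rep("distorted_or_absent", 2),
               rep("present", 1), rep("distorted_or_absent", 3))
  )
  r <- phoneme_presence_rate(rec)
  expect_equal(r$pct_present[r$phoneme == "T"], 80)
  expect_equal(r$pct_present[r$phoneme == "K"], 25)
  # pooled-across-words semantics: 3/4 + 1/4 -> 50%
  two_words <- tibble::tibble(
    session = "S1", condition = "ON", phoneme = "S",
    word = rep(c("sun", "bus"), each = 4),
    judged = c(rep("present", 3), "distorted_or_absent",
               "present", rep("distorted_or_absent", 3))
  )
  expect_equal(phoneme_presence_rate(two_words)$pct_present, 50)
})

test_that("consensus errors need two listeners with matching time and type", {
  ann <- tibble::tibble(listener = c("A", "B"), time = c(2.50, 2.52),
                        type = "slur")
  expect_equal(nrow(consensus_errors(ann)), 1)
  mismatch <- tibble::tibble(listener = c("A", "B"), time = 2.50,
                             type = c("slur", "stutter"))
  expect_equal(nrow(consensus_errors(mismatch)), 0)
  lone <- tibble::tibble(listener = c("A", "B"), time = c(2.5, 9.0),
                         type = "slur")
  expect_equal(nrow(consensus_errors(lone)), 0)
})

test_that("consensus counting is symmetric under listener relabeling and 1-1", {
  ann <- tibble::tibble(
    listener = c("A", "A", "B", "B", "C"),
    time = c(1.00, 3.00, 1.03, 3.04, 1.01),
    type = c("slur", "stutter", "slur", "stutter", "slur")
  )
  r1 <- consensus_errors(ann)
  relabeled <- ann
  relabeled$listener <- c("C", "C", "A", "A", "B")
  r2 <- consensus_errors(relabeled)
  expect_equal(nrow(r1), 2)
  expect_equal(r1$type, r2$type)
  expect_equal(r1$n_listeners, c(3, 2))
  # each annotation used at most once: two A-marks cannot both match one B-mark
  dup <- tibble::tibble(listener = c("A", "A", "B"),
                        time = c(1.00, 1.02, 1.01), type = "slur")
  expect_equal(nrow(consensus_errors(dup)), 1)
})

test_that("fatigue durations time the first and last five-word blocks", {
  words <- paste0("w", 1:12)
  timeline <- tibble::tibble(
    word = rep(words, each = 2),
    cue_time = rep(seq(0, by = 10, length.out = 12), each = 2),
    end_time = rep(seq(0, by = 10, length.out = 12), each = 2) + c(4, 8)
  )
  fd <- fatigue_durations(timeline)
  expect_equal(fd$duration_s[fd$block == "first_five"], 48) # 0 -> 40+8
  expect_equal(fd$duration_s[fd$block == "last_five"], 48) # 70 -> 110+8
  expect_error(fatigue_durations(timeline[1:8, ]), "10 unique")
})

test_that("95% bootstrap CIs cover a known mean difference at nominal rate", {
  delta <- 1
  covered <- vapply(1:1000, function(k) {
    set.seed(80000 + k)
    x <- stats::rnorm(30, delta)
    y <- stats::rnorm(30)
    b <- bootstrap_diff_means(x, y, n_resamples = 2000, seed = 80000 + k)
    ci <- b$ci[b$ci$alpha == 0.05, ]
    ci$lower <= delta && delta <= ci$upper
  }, logical(1))
  expect_equal(mean(covered), 0.95, tolerance = 0.02 / 0.95)
})
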