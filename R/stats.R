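#' Percentile-bootstrap difference in means
#'
#' Resamples each group with replacement (preserving its size), records the
#' difference of resampled means, and forms two-tailed percentile confidence
#' intervals at each alpha. The null hypothesis of equal means is rejected
#' at a given alpha when 0 lies outside that alpha's interval. Fully
#' reproducible from `seed`.
#'
#' @param x,y Numeric vectors (e.g. ON and OFF condition metric values),
#'   each of length >= 2.
#' @param n_resamples Number of bootstrap resamples. Default 10000.
#' @param alphas Two-tailed alpha levels. Default `c(0.05, 0.01, 0.001)`.
#' @param seed Integer seed.
#' @return An object of class `bootstrap_result`: `observed_diff`
#'   (`mean(x) - mean(y)`), `ci` (tibble `alpha`, `lower`, `upper`,
#'   `significant`), `n_x`, `n_y`, `n_resamples`, `seed`, and `resamples`
#'   (the resampled differences).
#' @examples
#' b <- bootstrap_diff_means(rnorm(30, 1), rnorm(30), seed = 1)
#' tidy(b)
#' @export
bootstrap_diff_means <- function(x, y, n_resamples = 10000,
                                 alphas = c(0.05, 0.01, 0.001), seed = 1) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  stopifnot(n_resamples >= 1000, all(alphas > 0 & alphas < 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nx <- length(x)
  ny <- length(y)
  bx <- matrix(sample.int(nx, n_resamples * nx, replace = TRUE), n_resamples)
  by <- matrix(sample.int(ny, n_resamples * ny, replace = TRUE), n_resamples)
  diffs <- rowMeans(matrix(x[bx], n_resamples)) -
           rowMeans(matrix(y[by], n_resamples))
  alphas <- sort(alphas, decreasing = TRUE)
  ci <- tibble::tibble(
    alpha = alphas,
    lower = vapply(alphas, function(a)
      stats::quantile(diffs, a / 2, names = FALSE, type = 7), numeric(1)),
    upper = vapply(alphas, function(a)
      stats::quantile(diffs, 1 - a / 2, names = FALSE, type = 7), numeric(1))
  )
  ci$significant <- ci$lower > 0 | ci$upper < 0
  structure(
    list(observed_diff = mean(x) - mean(y), ci = ci,
         n_x = nx, n_y = ny, n_resamples = n_resamples, seed = seed,
         resamples = diffs),
    class = "bootstrap_result"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> diff = %.4g (n = %d vs %d, %d resamples, seed %d) %s\n",
              x$observed_diff, x$n_x, x$n_y, x$n_resamples, x$seed,
              significance_stars(x)))
  print(x$ci)
  invisible(x)
}

#' Significance stars for a bootstrap result
#'
#' `"*"` for rejection at 0.05, `"**"` at 0.01, `"***"` at 0.001, `"ns"`
#' otherwise, following the convention p<0.05 (*), p<0.01 (**), p<0.001 (***).
#'
#' @param result A `bootstrap_result`.
#' @return A single character string.
#' @export
significance_stars <- function(result) {
  sig <- result$ci[result$ci$significant, , drop = FALSE]
  if (!nrow(sig)) return("ns")
  strrep("*", c(`0.05` = 1, `0.01` = 2, `0.001` = 3)[as.character(min(sig$alpha))])
}

#' Bonferroni-adjusted alpha
#'
#' @param alpha Family-wise alpha.
#' @param m Number of pairwise comparisons in the family.
#' @return `alpha / m`.
#' @examples bonferroni(0.05, 4)
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  alpha / m
}

#' Paired t-test (classic or sign-flip permutation)
#'
#' Classic paired t on the within-pair differences, one- or two-tailed.
#' `method = "permutation"` instead builds the null by randomly flipping the
#' signs of the differences. Zero-variance differences are flagged
#' degenerate (no p-value) rather than raising an error.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @param tail `"two"` (default), `"less"` (mean difference < 0) or
#'   `"greater"`.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Permutations when `method = "permutation"`. Default 10000.
#' @param seed Seed for the permutation null. Default 1.
#' @return A list of class `paired_test`: `statistic`, `p_value`, `df`,
#'   `mean_diff`, `tail`, `method`, `degenerate`.
#' @export
paired_t <- function(x, y, tail = c("two", "less", "greater"),
                     method = c("t", "permutation"), n_perm = 10000,
                     seed = 1) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          df = n - 1, mean_diff = mean(d), tail = tail,
                          method = method, degenerate = TRUE),
                     class = "paired_test"))
  }
  alt <- switch(tail, two = "two.sided", less = "less", greater = "greater")
  if (method == "t") {
    ht <- stats::t.test(x, y, paired = TRUE, alternative = alt)
    out <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
                df = unname(ht$parameter))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    obs <- mean(d)
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm)
    null <- rowMeans(sweep(flips, 2, d, `*`))
    p <- switch(tail,
      two = mean(abs(null) >= abs(obs)),
      greater = mean(null >= obs),
      less = mean(null <= obs))
    out <- list(statistic = obs / (stats::sd(d) / sqrt(n)), p_value = p,
                df = NA_real_)
  }
  structure(c(out, list(mean_diff = mean(d), tail = tail, method = method,
                        degenerate = FALSE)),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  if (x$degenerate) {
    cat("<paired_test> degenerate (zero-variance differences), no p-value\n")
  } else {
    cat(sprintf("<paired_test> t = %.3f, p = %.4g (%s-tailed, %s), mean diff %.4g\n",
                x$statistic, x$p_value, x$tail, x$method, x$mean_diff))
  }
  invisible(x)
}

#' Percent change relative to the OFF-condition median
#'
#' `100 * (v - median(off)) / median(off)` for each value; the normalisation
#' used to pool a metric (e.g. CPPS) across words and sessions.
#'
#' @param values Numeric vector to normalise.
#' @param off_values OFF-condition values supplying the reference median.
#' @return Numeric vector of percent changes.
#' @export
percent_change_vs_off_median <- function(values, off_values) {
  if (!length(off_values)) stop("`off_values` is empty", call. = FALSE)
  m <- stats::median(off_values)
  if (m == 0) stop("OFF median is zero", call. = FALSE)
  100 * (values - m) / m
}

#' Phoneme presence rates
#'
#' Percentage of phonemes judged *present* (vs *distorted or absent*) per
#' group, concatenating phonemes across words within each group.
#'
#' @param records Tibble with a `judged` column
#'   (`"present"`/`"distorted_or_absent"`) plus grouping columns.
#' @param by Character vector of grouping columns. Default
#'   `c("session", "condition", "phoneme")`.
#' @return A tibble: grouping columns, `n_present`, `n_total`, `pct_present`.
#' @export
phoneme_presence_rate <- function(records,
                                  by = c("session", "condition", "phoneme")) {
  stopifnot(nrow(records) > 0, "judged" %in% names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_present = sum(.data$judged == "present"),
      n_total = dplyr::n(),
      pct_present = 100 * .data$n_present / .data$n_total,
      .groups = "drop"
    )
}

#' Consensus speech-error counting across listeners
#'
#' Greedy one-to-one matching of error annotations across listeners: two
#' annotations agree when their types are identical and their times differ
#' by at most `time_tolerance_s`. An error is counted when at least two
#' listeners agree; each annotation is used at most once. The result is
#' invariant to listener relabelling.
#'
#' @param annotations Tibble with `listener`, `time` (s), `type` columns.
#' @param time_tolerance_s Matching tolerance, s. Default 0.05.
#' @return A tibble of counted errors: `time` (mean of the matched
#'   annotations), `type`, `n_listeners`.
#' @export
consensus_errors <- function(annotations, time_tolerance_s = 0.05) {
  stopifnot(all(c("listener", "time", "type") %in% names(annotations)))
  if (length(unique(annotations$listener)) < 2) {
    stop("need annotations from at least 2 listeners", call. = FALSE)
  }
  ann <- annotations[order(annotations$time), , drop = FALSE]
  ann$used <- FALSE
  out <- list()
  for (i in seq_len(nrow(ann))) {
    if (ann$used[i]) next
    grp_i <- i
    members <- ann$listener[i]
    for (j in seq_len(nrow(ann))) {
      if (j == i || ann$used[j]) next
      if (ann$listener[j] %in% members) next
      if (ann$type[j] != ann$type[i]) next
      if (abs(ann$time[j] - ann$time[i]) > time_tolerance_s) next
      grp_i <- c(grp_i, j)
      members <- c(members, ann$listener[j])
    }
    if (length(grp_i) >= 2) {
      ann$used[grp_i] <- TRUE
      out[[length(out) + 1L]] <- tibble::tibble(
        time = mean(ann$time[grp_i]),
        type = ann$type[i],
        n_listeners = length(grp_i)
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(time = numeric(), type = character(),
                          n_listeners = integer()))
  }
  dplyr::bind_rows(out)
}

#' Fatigue durations of the first and last five-word blocks
#'
#' Time a speaker needs to complete repetitions of the first five and the
#' last five unique words of a session: per block, the end of the last
#' repetition minus the go cue of the block's first word. Longer durations
#' indicate fatigue.
#'
#' @param timeline Tibble with `word`, `cue_time`, `end_time` (s), rows in
#'   task order; multiple repetitions per word allowed.
#' @return A tibble: `block` (`"first_five"`, `"last_five"`), `duration_s`.
#' @export
fatigue_durations <- function(timeline) {
  words <- unique(timeline$word)
  if (length(words) < 10) {
    stop("need at least 10 unique words for fatigue timing", call. = FALSE)
  }
  block_dur <- function(block_words) {
    rows <- timeline[timeline$word %in% block_words, , drop = FALSE]
    max(rows$end_time) - min(rows$cue_time)
  }
  tibble::tibble(
    block = c("first_five", "last_five"),
    duration_s = c(block_dur(words[1:5]),
                   block_dur(words[(length(words) - 4):length(words)]))
  )
}
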