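#' Read or write a trial manifest
#'
#' The manifest is the bookkeeping table that drives the pipelines: one row
#' per recorded trial with the audio path, its TextGrid, the word spoken, the
#' session, the stimulation condition and the repetition index.
#'
#' @param path Manifest CSV path with header columns
#'   `audio`, `textgrid`, `word`, `session`, `condition`, `repetition`.
#' @return A tibble with those columns; `condition` is validated against
#'   `OFF`/`ON`/`ON_130HZ` and `(word, session, condition, repetition)` must
#'   be unique.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(tibble::as_tibble(df))
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  need <- c("audio", "textgrid", "word", "session", "condition", "repetition")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    stop("manifest lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(manifest$condition), c("OFF", "ON", "ON_130HZ"))
  if (length(bad)) {
    stop("unknown condition value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(manifest$word, manifest$session, manifest$condition,
               manifest$repetition)
  if (anyDuplicated(key)) {
    stop("manifest rows not unique on (word, session, condition, repetition)",
         call. = FALSE)
  }
  manifest
}

#' Segment a long recording into word-level trials
#'
#' Finds maximal runs of frames whose energy exceeds `silence_db` relative to
#' the peak frame energy, separated by pauses of at least `min_pause_s`.
#' Segment boundaries are snapped outward to the nearest zero-crossing so
#' cuts do not click.
#'
#' @param rec An [audio_recording()].
#' @param silence_db Silence threshold in dB relative to the peak frame
#'   energy; must be negative. Default -40.
#' @param min_pause_s Minimum pause separating two trials, seconds. Default 0.15.
#' @param hop_s Energy frame hop, seconds. Default 0.01.
#' @return A tibble with columns `trial`, `start`, `end` (seconds) and a
#'   list-column `recording` of `audio_recording` segments. Zero rows for
#'   all-silent input.
#' @export
segment_words <- function(rec, silence_db = -40, min_pause_s = 0.15,
                          hop_s = 0.01) {
  stopifnot(inherits(rec, "audio_recording"))
  if (silence_db >= 0) stop("`silence_db` must be negative (dB re peak)", call. = FALSE)
  if (min_pause_s <= 0) stop("`min_pause_s` must be positive", call. = FALSE)

  hop <- max(1L, round(hop_s * rec$rate))
  n_frames <- max(1L, floor(length(rec$samples) / hop))
  idx <- (seq_len(n_frames) - 1L) * hop
  energy <- vapply(idx, function(i) {
    seg <- rec$samples[(i + 1):min(i + hop, length(rec$samples))]
    mean(seg^2)
  }, numeric(1))
  peak <- max(energy)
  if (peak <= 0) {
    return(tibble::tibble(trial = integer(), start = numeric(),
                          end = numeric(), recording = list()))
  }
  active <- 10 * log10(energy / peak + 1e-300) > silence_db

  # merge active runs separated by pauses shorter than min_pause_s
  r <- rle(active)
  min_pause_frames <- ceiling(min_pause_s / hop_s)
  keep_silent <- r$values == FALSE & r$lengths >= min_pause_frames
  merged <- inverse.rle(list(lengths = r$lengths,
                             values = r$values | !keep_silent))
  # runs of merged-active frames are trials (trim leading/trailing silence)
  m <- rle(merged)
  m_ends <- cumsum(m$lengths)
  m_starts <- m_ends - m$lengths + 1L
  out <- list()
  for (k in which(m$values)) {
    f0 <- m_starts[k]
    f1 <- m_ends[k]
    # trim frames below threshold at the edges of the merged run
    while (f0 <= f1 && !active[f0]) f0 <- f0 + 1L
    while (f1 >= f0 && !active[f1]) f1 <- f1 - 1L
    if (f0 > f1) next
    s0 <- (f0 - 1L) * hop + 1L
    s1 <- min(f1 * hop, length(rec$samples))
    s0 <- snap_zero_crossing(rec$samples, s0, -1L)
    s1 <- snap_zero_crossing(rec$samples, s1, +1L)
    out[[length(out) + 1L]] <- list(start = (s0 - 1L) / rec$rate,
                                    end = s1 / rec$rate,
                                    rec = audio_recording(rec$samples[s0:s1], rec$rate))
  }
  tibble::tibble(
    trial = seq_along(out),
    start = vapply(out, `[[`, numeric(1), "start"),
    end = vapply(out, `[[`, numeric(1), "end"),
    recording = lapply(out, `[[`, "rec")
  )
}

# walk outward from index i (direction -1 left / +1 right) to the nearest
# sign change or zero sample; bounded search of 10 ms
snap_zero_crossing <- function(x, i, direction) {
  lim <- length(x)
  for (step in 0:(min(lim, 480L))) {
    j <- i + direction * step
    if (j < 1L || j >= lim) return(max(1L, min(j, lim)))
    if (x[j] == 0 || x[j] * x[j + 1L] <= 0) return(j)
  }
  i
}

#' Apply a trial-selection policy
#'
#' Drops the first repetition of each (word, session, condition) group when
#' `exclude_first_repetition` is set (initiation errors such as coughing or
#' speaking over the go cue concentrate in the first attempt), and drops any
#' trial whose `flag` value is in `exclude_flags`. Row order is preserved.
#'
#' @param trials A tibble with at least `word`, `session`, `condition`,
#'   `repetition`; optionally a `flag` column of annotation labels.
#' @param exclude_first_repetition Drop repetition 1 per group? Default TRUE.
#' @param exclude_flags Character vector of flags to drop (e.g. `"cough"`).
#' @return The filtered tibble, original order preserved.
#' @export
select_trials <- function(trials, exclude_first_repetition = TRUE,
                          exclude_flags = character()) {
  keep <- rep(TRUE, nrow(trials))
  if (exclude_first_repetition) {
    keep <- keep & trials$repetition != 1
  }
  if (length(exclude_flags) && "flag" %in% names(trials)) {
    keep <- keep & !(trials$flag %in% exclude_flags)
  }
  trials[keep, , drop = FALSE]
}
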