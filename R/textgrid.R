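#' @keywords internal
# ARPABET vowel nuclei (monophthongs + diphthongs + rhotic vowel); everything
# else in the set is treated as a consonant. Stress digits are stripped first.
ARPABET_VOWELS <- c(
  "AA", "AE", "AH", "AO", "AW", "AY", "EH", "ER", "EY",
  "IH", "IY", "OW", "OY", "UH", "UW", "UX", "AX", "AXR", "IX"
)

#' Classify an ARPABET phoneme label as vowel or consonant
#'
#' Stress markers (trailing digits) are ignored, so `"AA1"` is a vowel.
#'
#' @param label Character vector of ARPABET labels.
#' @return Character vector, `"vowel"` or `"consonant"`.
#' @examples
#' arpabet_kind(c("AA1", "B", "ER0"))
#' @export
arpabet_kind <- function(label) {
  core <- toupper(gsub("[0-9]+$", "", trimws(label)))
  ifelse(core %in% ARPABET_VOWELS, "vowel", "consonant")
}

#' Parse a Praat TextGrid phones tier
#'
#' Reads both the long ("verbose") and short TextGrid dialects, extracts the
#' interval tier holding phoneme labels, drops empty (silence) intervals and
#' classifies each label as vowel or consonant from the ARPABET set.
#'
#' @param path Path to a `.TextGrid` file.
#' @param tier Name of the tier to extract (default `"phones"`).
#' @return A tibble with columns `label`, `start`, `end` (seconds) and
#'   `kind` (`"vowel"`/`"consonant"`), sorted by `start`.
#' @export
parse_textgrid <- function(path, tier = "phones") {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  is_long <- grepl("item\\s*\\[", txt)
  tiers <- if (is_long) parse_textgrid_long(lines) else parse_textgrid_short(lines)
  if (!tier %in% names(tiers)) {
    stop(sprintf("no tier named '%s'; available tiers: %s",
                 tier, paste(names(tiers), collapse = ", ")), call. = FALSE)
  }
  iv <- tiers[[tier]]
  iv <- iv[nzchar(trimws(iv$label)), , drop = FALSE]
  iv <- iv[order(iv$start), , drop = FALSE]
  tibble::tibble(
    label = trimws(iv$label),
    start = iv$start,
    end = iv$end,
    kind = arpabet_kind(iv$label)
  )
}

# long format: item [k] blocks with class = "IntervalTier", name = "...",
# intervals [i]: xmin = / xmax = / text = "..."
parse_textgrid_long <- function(lines) {
  tiers <- list()
  cur_name <- NULL
  cur <- NULL
  xmin <- xmax <- NA_real_
  is_interval_tier <- FALSE
  num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  str <- function(l) {
    m <- regmatches(l, regexpr('"[^"]*"', l))
    if (length(m)) substr(m, 2, nchar(m) - 1) else ""
  }
  flush <- function() {
    if (!is.null(cur_name) && is_interval_tier && !is.null(cur)) {
      tiers[[cur_name]] <<- do.call(rbind, cur)
    }
  }
  for (l in lines) {
    t <- trimws(l)
    if (grepl("^class\\s*=", t)) {
      is_interval_tier <- grepl("IntervalTier", t)
    } else if (grepl("^name\\s*=", t)) {
      flush()
      cur_name <- str(t)
      cur <- list()
    } else if (grepl("^xmin\\s*=", t)) {
      xmin <- num(t)
    } else if (grepl("^xmax\\s*=", t)) {
      xmax <- num(t)
    } else if (grepl("^text\\s*=", t)) {
      cur[[length(cur) + 1L]] <- data.frame(
        label = str(t), start = xmin, end = xmax, stringsAsFactors = FALSE
      )
    }
  }
  flush()
  tiers
}

# short format: header (File type, Object class, xmin, xmax, <exists>, ntiers)
# then per tier: "IntervalTier", name, xmin, xmax, n, then n * (xmin, xmax, text)
parse_textgrid_short <- function(lines) {
  t <- trimws(lines)
  t <- t[nzchar(t)]
  unq <- function(s) gsub('^"|"$', "", s)
  # skip the two header lines and file xmin/xmax; find tier count line
  i <- which(grepl("IntervalTier|TextTier", t))[1]
  if (is.na(i)) stop("no tiers found in short TextGrid", call. = FALSE)
  tiers <- list()
  n_total <- length(t)
  while (!is.na(i) && i <= n_total) {
    cls <- unq(t[i])
    name <- unq(t[i + 1])
    n <- as.integer(t[i + 4])
    if (cls == "IntervalTier") {
      rows <- lapply(seq_len(n), function(k) {
        j <- i + 5 + (k - 1) * 3
        data.frame(label = unq(t[j + 2]),
                   start = as.numeric(t[j]), end = as.numeric(t[j + 1]),
                   stringsAsFactors = FALSE)
      })
      tiers[[name]] <- do.call(rbind, rows)
      i <- i + 5 + n * 3
    } else {
      i <- i + 5 + n * 2 # point tier: time + mark
    }
    if (i > n_total || !grepl("Tier", t[i] %||% "")) break
  }
  tiers
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Write a minimal long-format TextGrid with a phones tier
#'
#' @param intervals Data frame with `label`, `start`, `end` (seconds).
#'   Gaps between intervals are emitted as empty (silence) intervals.
#' @param path Output path.
#' @param xmax Total duration in seconds (default: max end).
#' @param tier Tier name (default `"phones"`).
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(intervals, path, xmax = max(intervals$end),
                           tier = "phones") {
  iv <- intervals[order(intervals$start), , drop = FALSE]
  # fill gaps with empty intervals so the tier tiles [0, xmax]
  full <- list()
  cursor <- 0
  for (r in seq_len(nrow(iv))) {
    if (iv$start[r] > cursor + 1e-9) {
      full[[length(full) + 1L]] <- list(label = "", start = cursor, end = iv$start[r])
    }
    full[[length(full) + 1L]] <- list(label = iv$label[r], start = iv$start[r], end = iv$end[r])
    cursor <- iv$end[r]
  }
  if (cursor < xmax - 1e-9) {
    full[[length(full) + 1L]] <- list(label = "", start = cursor, end = xmax)
  }
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    sprintf("xmax = %.10g", xmax),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    sprintf('        name = "%s"', tier),
    "        xmin = 0",
    sprintf("        xmax = %.10g", xmax),
    sprintf("        intervals: size = %d", length(full))
  )
  for (k in seq_along(full)) {
    f <- full[[k]]
    out <- c(out,
      sprintf("        intervals [%d]:", k),
      sprintf("            xmin = %.10g", f$start),
      sprintf("            xmax = %.10g", f$end),
      sprintf('            text = "%s"', f$label)
    )
  }
  writeLines(out, path)
  invisible(path)
}
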