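#' Construct an audio recording
#'
#' A minimal mono audio container: a numeric sample vector with its sampling
#' rate. All acoustic analyses in the package (`spectrogram_power()`,
#' `track_pitch()`, `power_cepstrogram()`, `lpc_formant_track()`) consume this
#' object.
#'
#' @param samples Numeric vector of amplitudes, nominal range \[-1, 1\].
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class `audio_recording`: a list with elements
#'   `samples`, `rate` and `duration` (seconds, `length(samples)/rate`).
#' @examples
#' rec <- audio_recording(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' rec$duration
#' @export
audio_recording <- function(samples, rate) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  structure(
    list(
      samples = as.numeric(samples),
      rate = as.numeric(rate),
      duration = length(samples) / rate
    ),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf(
    "<audio_recording> %d samples @ %g Hz (%.3f s), peak %.3f\n",
    length(x$samples), x$rate, x$duration, max(abs(x$samples))
  ))
  invisible(x)
}

#' Extract a time slice of a recording
#'
#' @param rec An [audio_recording()].
#' @param start,end Slice bounds in seconds, half-open `[start, end)`.
#' @return An `audio_recording` holding the slice.
#' @export
crop_recording <- function(rec, start, end) {
  stopifnot(inherits(rec, "audio_recording"), start < end)
  i0 <- max(1L, floor(start * rec$rate) + 1L)
  i1 <- min(length(rec$samples), ceiling(end * rec$rate))
  audio_recording(rec$samples[i0:i1], rec$rate)
}

#' Read a mono WAV file
#'
#' Reads RIFF/WAVE files holding mono PCM16, PCM24 or IEEE float32 data.
#' Integer samples are scaled by the full-scale positive value (32767 for
#' PCM16, 8388607 for PCM24) so that the result lies in \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_recording()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format = sum(as.integer(body[1:2]) * c(1, 256)),
        channels = sum(as.integer(body[3:4]) * c(1, 256)),
        rate = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$channels != 1) {
    stop(sprintf("expected mono, got %d channels", fmt$channels), call. = FALSE)
  }

  samples <- if (fmt$format == 1 && fmt$bits == 16) {
    ints <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                    signed = TRUE, endian = "little")
    ints / 32767
  } else if (fmt$format == 1 && fmt$bits == 24) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3
    idx <- 3 * seq_len(n)
    v <- b[idx - 2] + 256 * b[idx - 1] + 65536 * b[idx]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388607
  } else if (fmt$format == 3 && fmt$bits == 32) {
    readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$format, fmt$bits), call. = FALSE)
  }
  audio_recording(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param rec An [audio_recording()]. Samples are clipped to \[-1, 1\].
#' @param path Output path.
#' @param bits 16 (PCM16, default) or 32 (IEEE float32).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16) {
  stopifnot(inherits(rec, "audio_recording"), bits %in% c(16, 32))
  x <- pmin(1, pmax(-1, rec$samples))
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(rec$rate), con, 4, endian = "little")
  writeBin(as.integer(rec$rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
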