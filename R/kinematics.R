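#' Construct a facial-landmark trajectory
#'
#' Per-frame x/y pixel coordinates of one articulator from markerless pose
#' estimation. Frames whose likelihood falls below `min_likelihood` are
#' replaced by linear interpolation from their neighbours.
#'
#' @param x,y Numeric pixel coordinates per frame (origin top-left).
#' @param fps Video frame rate, Hz.
#' @param label Articulator label (e.g. `"lower lip"`, `"jaw L"`).
#' @param likelihood Optional per-frame tracking confidence in `[0, 1]`.
#' @param min_likelihood Interpolation threshold. Default 0.6.
#' @return An object of class `landmark_trajectory`.
#' @export
landmark_trajectory <- function(x, y, fps, label = "landmark",
                                likelihood = NULL, min_likelihood = 0.6) {
  stopifnot(length(x) == length(y), fps > 0, length(x) >= 1)
  if (!is.null(likelihood)) {
    stopifnot(length(likelihood) == length(x))
    bad <- likelihood < min_likelihood
    if (any(bad) && !all(bad)) {
      idx <- seq_along(x)
      x[bad] <- stats::approx(idx[!bad], x[!bad], idx[bad], rule = 2)$y
      y[bad] <- stats::approx(idx[!bad], y[!bad], idx[bad], rule = 2)$y
    }
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), fps = fps,
                 label = label, n = length(x)),
            class = "landmark_trajectory")
}

#' Read a pose-estimation landmark CSV
#'
#' Accepts the pose-estimation export layout (three header rows: articulator
#' name, coordinate, likelihood-flag) or a plain tidy CSV with columns
#' `frame`, `articulator`, `x`, `y` and optionally `likelihood`.
#'
#' @param path CSV path.
#' @param fps Frame rate, Hz.
#' @param min_likelihood Interpolation threshold passed through. Default 0.6.
#' @return A named list of [landmark_trajectory()] objects.
#' @export
read_landmarks <- function(path, fps, min_likelihood = 0.6) {
  head2 <- readLines(path, n = 2)
  tidy <- grepl("articulator", head2[1])
  if (tidy) {
    df <- utils::read.csv(path)
    split(df, df$articulator) |>
      lapply(function(d) {
        landmark_trajectory(d$x, d$y, fps, d$articulator[1],
                            likelihood = d$likelihood,
                            min_likelihood = min_likelihood)
      })
  } else {
    hdr_art <- strsplit(head2[1], ",")[[1]]
    hdr_coord <- strsplit(head2[2], ",")[[1]]
    df <- utils::read.csv(path, skip = 2, header = FALSE)
    arts <- unique(hdr_art[-1])
    out <- lapply(arts, function(a) {
      cols <- which(hdr_art == a)
      xi <- cols[hdr_coord[cols] == "x"]
      yi <- cols[hdr_coord[cols] == "y"]
      li <- cols[hdr_coord[cols] == "likelihood"]
      landmark_trajectory(df[[xi]], df[[yi]], fps, a,
                          likelihood = if (length(li)) df[[li]] else NULL,
                          min_likelihood = min_likelihood)
    })
    stats::setNames(out, arts)
  }
}

#' Movement amplitude and mean velocity per event
#'
#' Amplitude is the maximum Euclidean distance from the event's first-frame
#' (neutral) position; mean velocity is the mean framewise Euclidean
#' displacement times the frame rate. Events are `[start, end)` frame
#' intervals, 1-based inclusive start, exclusive end.
#'
#' @param traj A [landmark_trajectory()].
#' @param events Data frame with `start`, `end` frame columns (and any
#'   grouping columns, which are carried through).
#' @return A tibble: event columns plus `amplitude_px`, `mean_velocity_px_s`.
#' @export
movement_amplitude_velocity <- function(traj, events) {
  stopifnot(inherits(traj, "landmark_trajectory"))
  events <- tibble::as_tibble(events)
  if (any(events$end - events$start < 2)) {
    stop("events must span at least 2 frames", call. = FALSE)
  }
  if (any(events$start < 1 | events$end > traj$n + 1)) {
    stop("events outside trajectory", call. = FALSE)
  }
  met <- lapply(seq_len(nrow(events)), function(k) {
    idx <- events$start[k]:(events$end[k] - 1L)
    dx <- traj$x[idx] - traj$x[idx[1]]
    dy <- traj$y[idx] - traj$y[idx[1]]
    amp <- max(sqrt(dx^2 + dy^2))
    step <- sqrt(diff(traj$x[idx])^2 + diff(traj$y[idx])^2)
    tibble::tibble(amplitude_px = amp,
                   mean_velocity_px_s = mean(step) * traj$fps)
  })
  dplyr::bind_cols(events, dplyr::bind_rows(met))
}

#' Automatic movement-event segmentation (optional)
#'
#' Frames whose smoothed speed exceeds `threshold_frac` of the peak speed
#' start an event; the event ends when speed stays below threshold for
#' `hysteresis` frames. Intended for synthetic or well-behaved trajectories;
#' manually identified events take precedence in the pipelines.
#'
#' @param traj A [landmark_trajectory()].
#' @param threshold_frac Fraction of peak speed. Default 0.10.
#' @param hysteresis Frames of sub-threshold speed ending an event. Default 3.
#' @param min_event_frames Shorter candidate events (noise spikes) are
#'   discarded. Default `hysteresis + 2`.
#' @return A tibble with `start`, `end` frame columns.
#' @export
segment_movements <- function(traj, threshold_frac = 0.10, hysteresis = 3,
                              min_event_frames = hysteresis + 2) {
  speed <- c(0, sqrt(diff(traj$x)^2 + diff(traj$y)^2)) * traj$fps
  if (length(speed) >= 5) speed <- stats::runmed(speed, 5, endrule = "median")
  thr <- threshold_frac * max(speed)
  if (max(speed) == 0) return(tibble::tibble(start = integer(), end = integer()))
  active <- speed > thr
  # close sub-threshold gaps shorter than `hysteresis`
  r <- rle(active)
  short_gap <- !r$values & r$lengths < hysteresis
  inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  r$values[short_gap & inner] <- TRUE
  active <- inverse.rle(r)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_event_frames
  tibble::tibble(start = starts[keep], end = ends[keep] + 1L)
}

#' Mouth-aperture area series
#'
#' Polygon area (shoelace formula, absolute value) spanned by 3 or 4
#' landmark vertices per frame. Vertex order must be consistent across
#' frames (clockwise or counter-clockwise; orientation does not matter).
#'
#' @param xs,ys Numeric matrices, frames x vertices (3 or 4 columns).
#' @return Numeric vector of areas in pixels^2, one per frame.
#' @examples
#' mouth_aperture(matrix(c(0, 3, 0), 1), matrix(c(0, 0, 4), 1)) # 6
#' @export
mouth_aperture <- function(xs, ys) {
  xs <- as.matrix(xs)
  ys <- as.matrix(ys)
  stopifnot(all(dim(xs) == dim(ys)), ncol(xs) %in% c(3, 4))
  nxt <- c(2:ncol(xs), 1)
  abs(rowSums(xs * ys[, nxt, drop = FALSE] - xs[, nxt, drop = FALSE] * ys)) / 2
}

#' Swallow duration from a videofluoroscopic trial
#'
#' `(swallow_end_frame - first_barium_frame) / fps`: the frame span from the
#' first appearance of modified barium in the oral cavity to completion of
#' the swallow, converted to seconds.
#'
#' @param trial Data frame (one or more rows) with `first_barium_frame`,
#'   `swallow_end_frame` and optionally `fps` (default 30).
#' @return The input tibble with a `duration_s` column appended.
#' @export
swallow_duration <- function(trial) {
  trial <- tibble::as_tibble(trial)
  if (!"fps" %in% names(trial)) trial$fps <- 30
  if (any(trial$swallow_end_frame <= trial$first_barium_frame)) {
    stop("swallow_end_frame must exceed first_barium_frame", call. = FALSE)
  }
  dplyr::mutate(trial, duration_s =
    (.data$swallow_end_frame - .data$first_barium_frame) / .data$fps)
}

#' Post-swallow residue as a fraction of the frame
#'
#' Region-of-interest pixel areas (vallecula, pyriform sinus, esophagus, ...)
#' normalized by the full frame's pixel area; an empty ROI set gives 0.
#'
#' @param roi_areas Named numeric vector of ROI areas, pixels^2 (may be
#'   empty).
#' @param frame_width,frame_height Frame dimensions, pixels.
#' @return A tibble: one row per region plus a `total` row, with columns
#'   `region` and `fraction`.
#' @export
residue_fraction <- function(roi_areas, frame_width, frame_height) {
  stopifnot(frame_width > 0, frame_height > 0)
  denom <- frame_width * frame_height
  if (length(roi_areas) && any(roi_areas > denom)) {
    stop("ROI larger than the frame", call. = FALSE)
  }
  if (length(roi_areas) && is.null(names(roi_areas))) {
    names(roi_areas) <- paste0("roi", seq_along(roi_areas))
  }
  tibble::tibble(
    region = c(names(roi_areas), "total"),
    fraction = unname(c(roi_areas / denom, sum(roi_areas) / denom))
  )
}
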