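# Video heart-rate extraction: ROI intensity traces, common-mode
# (ventilation) reference subtraction, 21-frame moving average, end-of-
# diastole minima, interbeat intervals, beat-by-beat and steady-state rates.

#' Video frame stack
#'
#' @param frames numeric array `H x W x T` of grayscale intensities
#'   (`>= 0`), or `H x W x 3 x T` RGB which is converted to ITU-R 601 luma.
#' @param fps frame rate in frames/second (`> 0`).
#' @return an object of class `frame_stack` with fields `frames`
#'   (`H x W x T`) and `fps`.
#' @export
frame_stack <- function(frames, fps) {
  if (!is_scalar_num(fps) || fps <= 0) abort_domain("fps must be > 0")
  d <- dim(frames)
  if (length(d) == 2L) frames <- array(frames, c(d, 1L))
  else if (length(d) == 4L && d[3] == 3L) frames <- rgb_to_luma(frames)
  else if (length(d) != 3L)
    abort_domain("frames must be an H x W x T (or H x W x 3 x T) array")
  if (any(frames < 0)) abort_domain("frame intensities must be >= 0")
  structure(list(frames = frames, fps = fps), class = "frame_stack")
}

# ITU-R 601 luminance from an H x W x 3 x T array
rgb_to_luma <- function(a) {
  0.299 * a[, , 1, , drop = TRUE] + 0.587 * a[, , 2, , drop = TRUE] +
    0.114 * a[, , 3, , drop = TRUE]
}

#' Rectangular region of interest
#'
#' Rectangles use 0-based, half-open index conventions
#' `[row0, row1) x [col0, col1)` so that width = `col1 - col0`, matching the
#' JSON interchange format.
#'
#' @param row0,col0,row1,col1 integer bounds, 0-based half-open.
#' @return an object of class `roi`.
#' @export
roi <- function(row0, col0, row1, col1) {
  v <- c(row0, col0, row1, col1)
  if (any(v != round(v)) || any(v < 0) || row1 <= row0 || col1 <= col0)
    abort_domain("roi must satisfy 0 <= row0 < row1, 0 <= col0 < col1")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1)),
            class = "roi")
}

.roi_overlaps <- function(a, b) {
  a$row0 < b$row1 && b$row0 < a$row1 && a$col0 < b$col1 && b$col0 < a$col1
}

#' Heart and reference ROI set
#'
#' Exactly three rectangles over the heart region plus one reference
#' rectangle outside it; the reference captures body movement attributable
#' to ventilation and must not overlap any heart ROI.
#'
#' @param heart_rois list of exactly 3 [roi()] objects.
#' @param reference_roi a single [roi()].
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(heart_rois, reference_roi) {
  if (length(heart_rois) != 3L ||
      !all(vapply(heart_rois, inherits, TRUE, "roi")))
    abort_domain("heart_rois must be a list of exactly 3 roi objects")
  stopifnot(inherits(reference_roi, "roi"))
  for (h in heart_rois)
    if (.roi_overlaps(h, reference_roi))
      abort_domain("reference ROI must not overlap any heart ROI")
  structure(list(heart_rois = heart_rois, reference_roi = reference_roi),
            class = "roi_set")
}

#' Per-frame scalar intensity trace
#'
#' @param values numeric vector, one finite value per frame.
#' @param fps frame rate in frames/second.
#' @return an object of class `intensity_trace`.
#' @export
intensity_trace <- function(values, fps) {
  if (length(values) < 1L || any(!is.finite(values)))
    abort_domain("trace values must be finite and non-empty")
  if (!is_scalar_num(fps) || fps <= 0) abort_domain("fps must be > 0")
  structure(list(values = as.numeric(values), fps = fps),
            class = "intensity_trace")
}

#' Mean ROI intensity per frame
#'
#' Digitizes one rectangle of the video: the arithmetic mean of the pixel
#' intensities inside the half-open rectangle, per frame.
#'
#' @param stack a [frame_stack()].
#' @param roi a [roi()] within the frame bounds.
#' @return an [intensity_trace()].
#' @export
roi_mean_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "roi"))
  d <- dim(stack$frames)
  if (roi$row1 > d[1] || roi$col1 > d[2])
    abort_domain("roi exceeds frame bounds (", d[1], " x ", d[2], ")")
  rows <- (roi$row0 + 1L):roi$row1
  cols <- (roi$col0 + 1L):roi$col1
  sub <- stack$frames[rows, cols, , drop = FALSE]
  intensity_trace(apply(sub, 3L, mean), stack$fps)
}

#' Cardiac signal by reference subtraction
#'
#' Mean of the three heart-ROI traces minus the reference trace, frame by
#' frame. Any signal common to all four ROIs -- in practice the body
#' movement caused by ventilation -- cancels exactly.
#'
#' @param heart_traces list of 3 [intensity_trace()] objects.
#' @param reference_trace an [intensity_trace()] of the same length and fps.
#' @return an [intensity_trace()].
#' @export
cardiac_signal <- function(heart_traces, reference_trace) {
  if (length(heart_traces) != 3L)
    abort_domain("heart_traces must contain exactly 3 traces")
  lens <- vapply(heart_traces, function(tr) length(tr$values), 1L)
  fpss <- vapply(heart_traces, function(tr) tr$fps, 1)
  if (length(unique(c(lens, length(reference_trace$values)))) != 1L)
    abort_domain("all traces must have the same length")
  if (length(unique(c(fpss, reference_trace$fps))) != 1L)
    abort_domain("all traces must share one frame rate")
  h <- (heart_traces[[1]]$values + heart_traces[[2]]$values +
          heart_traces[[3]]$values) / 3
  intensity_trace(h - reference_trace$values, reference_trace$fps)
}

#' Centred moving average
#'
#' Moving average over an odd window (default 21 frames). At the trace edges
#' the window is truncated to the available frames, so the output keeps the
#' input length and no data are fabricated by reflection or padding.
#'
#' @param trace an [intensity_trace()].
#' @param window odd positive window length in frames, `<=` trace length.
#' @return a smoothed [intensity_trace()] of the same length.
#' @export
smooth_trace <- function(trace, window = 21L) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (!is_count(window) || window < 1L || window %% 2L == 0L)
    abort_domain("window must be an odd positive integer")
  x <- trace$values
  n <- length(x)
  if (window > n) abort_domain("window exceeds trace length")
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  intensity_trace((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L), trace$fps)
}

#' Detect end-of-diastole intensity minima
#'
#' Local minima of the (smoothed) cardiac trace mark the end of diastole and
#' delimit the beats. A candidate is a strict local minimum after merging
#' plateaus (a flat run counts once, at its centre). Candidates are filtered
#' by topographic prominence and then kept greedily, deepest first, subject
#' to a minimum pairwise separation.
#'
#' @param trace an [intensity_trace()], length `>= 3`.
#' @param min_separation minimum frames between accepted minima; defaults to
#'   `fps / 5`, i.e. a 300 bpm physiological ceiling.
#' @param min_prominence minimum prominence in intensity units; defaults to
#'   25% of the interquartile range of the trace.
#' @return strictly increasing integer vector of frame indices (1-based);
#'   empty for a constant trace.
#' @export
detect_diastole_minima <- function(trace, min_separation = NULL,
                                   min_prominence = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- trace$values
  n <- length(x)
  if (n < 3L) abort_domain("trace too short for minima detection (< 3)")
  if (is.null(min_separation)) min_separation <- max(1L, round(trace$fps / 5))
  if (!is_scalar_num(min_separation) || min_separation < 1)
    abort_domain("min_separation must be >= 1")
  if (is.null(min_prominence))
    min_prominence <- 0.25 * stats::IQR(x)
  if (diff(range(x)) == 0) return(integer(0))

  # plateau-merged candidates: run-length encode, then compare run levels
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_min <- c(FALSE,
              r$values[2:(k - 1)] < r$values[1:(k - 2)] &
                r$values[2:(k - 1)] < r$values[3:k],
              FALSE)
  cand <- as.integer(round((starts[is_min] + ends[is_min]) / 2))
  if (length(cand) == 0L) return(integer(0))

  prom <- vapply(cand, function(i) .min_prominence(x, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0L) return(integer(0))

  # greedy: deepest first, enforce pairwise separation
  ord <- cand[order(x[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_separation)) kept <- c(kept, i)
  }
  sort(kept)
}

# topographic prominence of a minimum: on each side, walk to the first value
# below x[i] (or the boundary); the smaller of the two highest interleaving
# values, minus x[i].
.min_prominence <- function(x, i) {
  n <- length(x)
  left <- if (i == 1L) x[i] else {
    j <- i - 1L
    hi <- x[j]
    while (j >= 1L && x[j] >= x[i]) {
      if (x[j] > hi) hi <- x[j]
      j <- j - 1L
    }
    hi
  }
  right <- if (i == n) x[i] else {
    j <- i + 1L
    hi <- x[j]
    while (j <= n && x[j] >= x[i]) {
      if (x[j] > hi) hi <- x[j]
      j <- j + 1L
    }
    hi
  }
  min(left, right) - x[i]
}

#' Interbeat intervals from detected minima
#'
#' @param minima strictly increasing frame indices (`>= 2` of them).
#' @return successive differences, in frames.
#' @export
interbeat_intervals <- function(minima) {
  if (length(minima) < 2L) abort_domain("need >= 2 minima for intervals")
  ib <- diff(minima)
  if (any(ib <= 0)) abort_domain("minima must be strictly increasing")
  ib
}

#' Beat-by-beat heart rate
#'
#' @param ibis_frames interbeat intervals in frames (`> 0`).
#' @param fps frame rate, frames/second (`> 0`).
#' @return heart rate in beats per minute, one per interval:
#'   `fps * 60 / ibi`.
#' @export
beat_by_beat_hr <- function(ibis_frames, fps) {
  if (any(ibis_frames <= 0)) abort_domain("interbeat intervals must be > 0")
  if (!is_scalar_num(fps) || fps <= 0) abort_domain("fps must be > 0")
  fps * 60 / ibis_frames
}

#' Detected beats as a unit
#'
#' @param minima_indices strictly increasing frame indices of diastole
#'   minima.
#' @param fps frame rate in frames/second.
#' @return an object of class `beat_series` with `minima_indices`,
#'   `ibis_frames`, `hr_bpm` and `fps`.
#' @export
beat_series <- function(minima_indices, fps) {
  ib <- interbeat_intervals(minima_indices)
  structure(list(minima_indices = minima_indices, ibis_frames = ib,
                 hr_bpm = beat_by_beat_hr(ib, fps), fps = fps),
            class = "beat_series")
}

#' Steady-state heart rate over a time window
#'
#' Averages the beat-by-beat rates over a window (default the first 3
#' minutes). A beat contributes if and only if both of its delimiting
#' minima fall inside the window. The spread is reported as a standard
#' deviation.
#'
#' @param beats a [beat_series()].
#' @param window_seconds window length in seconds (default 180).
#' @param start_seconds window start in seconds from the recording start.
#' @return an object of class `heart_rate_summary`: `mean_bpm`, `sd_bpm`,
#'   `n_beats`, `window_seconds`, `start_seconds`.
#' @export
steady_state_hr <- function(beats, window_seconds = 180,
                            start_seconds = 0) {
  stopifnot(inherits(beats, "beat_series"))
  if (!is_scalar_num(window_seconds) || window_seconds <= 0)
    abort_domain("window_seconds must be > 0")
  t_min <- (beats$minima_indices - 1) / beats$fps
  in_win <- t_min >= start_seconds & t_min < start_seconds + window_seconds
  # beat i spans minima i and i+1
  use <- in_win[-length(in_win)] & in_win[-1]
  if (sum(use) < 2L)
    abort_domain("fewer than 2 beats inside the averaging window")
  hr <- beats$hr_bpm[use]
  structure(list(mean_bpm = mean(hr), sd_bpm = stats::sd(hr),
                 n_beats = sum(use), window_seconds = window_seconds,
                 start_seconds = start_seconds),
            class = "heart_rate_summary")
}

#' Full video heart-rate pipeline
#'
#' Composition of the whole procedure: ROI digitization, reference
#' subtraction, 21-frame moving average, diastole-minima detection,
#' interbeat intervals, beat-by-beat rates and the steady-state (3-min)
#' average. All intermediates are returned for audit.
#'
#' @param stack a [frame_stack()].
#' @param rois a [roi_set()].
#' @param window moving-average window in frames (odd; default 21).
#' @param window_seconds,start_seconds steady-state averaging window.
#' @param min_separation,min_prominence passed to
#'   [detect_diastole_minima()].
#' @param subtract_reference set `FALSE` to skip the reference subtraction
#'   (for assessing how much the ventilation artifact matters).
#' @return an object of class `heartrate_result`: `summary`
#'   (a `heart_rate_summary`, or `NULL` if fewer than 3 minima were found),
#'   `beats` (`beat_series` or `NULL`), `n_minima`, and the intermediate
#'   traces `heart_traces`, `reference_trace`, `cardiac`, `smoothed`.
#' @export
run_heartrate_pipeline <- function(stack, rois, window = 21L,
                                   window_seconds = 180, start_seconds = 0,
                                   min_separation = NULL,
                                   min_prominence = NULL,
                                   subtract_reference = TRUE) {
  stopifnot(inherits(stack, "frame_stack"), inherits(rois, "roi_set"))
  heart <- lapply(rois$heart_rois, function(r) roi_mean_trace(stack, r))
  ref <- roi_mean_trace(stack, rois$reference_roi)
  run_heartrate_traces(heart, ref, fps = stack$fps, window = window,
                       window_seconds = window_seconds,
                       start_seconds = start_seconds,
                       min_separation = min_separation,
                       min_prominence = min_prominence,
                       subtract_reference = subtract_reference)
}

#' @rdname run_heartrate_pipeline
#' @param heart_traces list of 3 [intensity_trace()] objects (the trace-level
#'   entry point, for data already digitized to ROI means).
#' @param reference_trace the reference [intensity_trace()].
#' @param fps frame rate in frames/second.
#' @export
run_heartrate_traces <- function(heart_traces, reference_trace, fps,
                                 window = 21L, window_seconds = 180,
                                 start_seconds = 0, min_separation = NULL,
                                 min_prominence = NULL,
                                 subtract_reference = TRUE) {
  cardiac <- if (subtract_reference) {
    cardiac_signal(heart_traces, reference_trace)
  } else {
    zero_ref <- intensity_trace(rep(0, length(reference_trace$values)), fps)
    cardiac_signal(heart_traces, zero_ref)
  }
  sm <- smooth_trace(cardiac, window)
  minima <- detect_diastole_minima(sm, min_separation, min_prominence)
  beats <- if (length(minima) >= 2L) beat_series(minima, fps) else NULL
  summary <- NULL
  if (!is.null(beats) && length(minima) >= 3L) {
    summary <- tryCatch(
      steady_state_hr(beats, window_seconds, start_seconds),
      error = function(e) NULL)
  }
  structure(
    list(summary = summary, beats = beats, n_minima = length(minima),
         heart_traces = heart_traces, reference_trace = reference_trace,
         cardiac = cardiac, smoothed = sm),
    class = "heartrate_result")
}

#' @export
print.heart_rate_summary <- function(x, ...) {
  cat(sprintf(
    "Steady-state heart rate: %.1f bpm (SD %.1f, %d beats over %gs)\n",
    x$mean_bpm, x$sd_bpm, x$n_beats, x$window_seconds))
  invisible(x)
}

#' Export traces and beats as CSV
#'
#' Writes two CSV files: `<stem>_trace.csv` with per-frame raw mean heart
#' intensity, cardiac (reference-subtracted) and smoothed values, and
#' `<stem>_beats.csv` with one row per beat.
#'
#' @param result a `heartrate_result`.
#' @param stem output path stem.
#' @return character vector of the paths written, invisibly.
#' @export
write_heartrate_csv <- function(result, stem) {
  stopifnot(inherits(result, "heartrate_result"))
  hmean <- (result$heart_traces[[1]]$values +
              result$heart_traces[[2]]$values +
              result$heart_traces[[3]]$values) / 3
  trace_path <- paste0(stem, "_trace.csv")
  utils::write.csv(
    data.frame(frame_index = seq_along(hmean) - 1L,
               raw = hmean,
               reference = result$reference_trace$values,
               cardiac = result$cardiac$values,
               smoothed = result$smoothed$values),
    trace_path, row.names = FALSE)
  paths <- trace_path
  if (!is.null(result$beats)) {
    b <- result$beats
    beat_path <- paste0(stem, "_beats.csv")
    utils::write.csv(
      data.frame(beat_index = seq_along(b$ibis_frames) - 1L,
                 minima_frame = b$minima_indices[-length(b$minima_indices)] - 1L,
                 ibi_frames = b$ibis_frames,
                 hr_bpm = b$hr_bpm),
      beat_path, row.names = FALSE)
    paths <- c(paths, beat_path)
  }
  invisible(paths)
}
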