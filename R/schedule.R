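#' Dynamic frame schedule
#'
#' A frame schedule is the ordered set of reconstruction time frames of a
#' dynamic PET acquisition, stored as start/end times in seconds post
#' injection. Frames must be ordered and non-overlapping; gaps are allowed.
#'
#' @param frame_start numeric vector of frame start times (seconds).
#' @param frame_end numeric vector of frame end times (seconds), same length.
#' @return An object of class `frame_schedule`: a data.frame with columns
#'   `frame_start` and `frame_end` (seconds).
#' @examples
#' frame_schedule(c(0, 10), c(10, 20))
#' @export
frame_schedule <- function(frame_start, frame_end) {
  if (length(frame_start) != length(frame_end) || length(frame_start) == 0L)
    stop("frame_start and frame_end must be non-empty vectors of equal length")
  frame_start <- as.numeric(frame_start)
  frame_end <- as.numeric(frame_end)
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end)))
    stop("frame times must be finite")
  if (any(frame_end <= frame_start))
    stop("every frame must satisfy frame_end > frame_start")
  if (is.unsorted(frame_start, strictly = TRUE))
    stop("frame_start must be strictly increasing")
  if (any(frame_start[-1] < frame_end[-length(frame_end)] - 1e-9))
    stop("frames must not overlap")
  structure(
    data.frame(frame_start = frame_start, frame_end = frame_end),
    class = c("frame_schedule", "data.frame")
  )
}

#' Frame schedule from a run-length pattern
#'
#' Builds a contiguous schedule from repeated frame durations, e.g.
#' `c(12, 6)` frames of `c(10, 30)` seconds.
#'
#' @param n integer vector: number of frames per block.
#' @param duration_s numeric vector: frame duration of each block (seconds).
#' @return A [frame_schedule()].
#' @export
frame_schedule_pattern <- function(n, duration_s) {
  if (length(n) != length(duration_s)) stop("n and duration_s lengths differ")
  durations <- rep(duration_s, times = n)
  ends <- cumsum(durations)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

#' Default 30-minute dynamic acquisition schedule
#'
#' The 26-frame schedule used throughout this package for 30-min carbon-11
#' cardiorenal scans: 12 x 10 s, 6 x 30 s, 6 x 150 s, 2 x 300 s, spanning
#' 0--1800 s contiguously.
#'
#' @return A [frame_schedule()] with 26 frames covering 0--1800 s.
#' @examples
#' fs <- default_frame_schedule()
#' nrow(fs)            # 26
#' max(fs$frame_end)   # 1800
#' @export
default_frame_schedule <- function() {
  frame_schedule_pattern(n = c(12L, 6L, 6L, 2L),
                         duration_s = c(10, 30, 150, 300))
}

#' Frame mid-times
#'
#' @param fs a [frame_schedule()].
#' @param units `"min"` (default) or `"s"`.
#' @return Numeric vector of frame mid-times.
#' @export
frame_mid <- function(fs, units = c("min", "s")) {
  units <- match.arg(units)
  mid <- (fs$frame_start + fs$frame_end) / 2
  if (units == "min") mid / 60 else mid
}

#' Frame durations
#'
#' @param fs a [frame_schedule()].
#' @param units `"min"` (default) or `"s"`.
#' @return Numeric vector of frame durations.
#' @export
frame_duration <- function(fs, units = c("min", "s")) {
  units <- match.arg(units)
  d <- fs$frame_end - fs$frame_start
  if (units == "min") d / 60 else d
}
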