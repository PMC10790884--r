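#' Frame schedules for dynamic PET
#'
#' A frame schedule is the ordered set of acquisition intervals of a dynamic
#' PET scan: each frame has a start time and a duration (seconds from
#' injection). All time-activity curves in the package are sampled on a frame
#' schedule, and frames are assumed contiguous (each frame starts where the
#' previous one ends, the first at t = 0).
#'
#' @param spec a list (or 2-column matrix) of `(count, duration_seconds)`
#'   pairs, e.g. `list(c(4, 15), c(4, 30))` for four 15-s frames followed by
#'   four 30-s frames.
#' @return an object of class `frame_schedule`: a list with numeric vectors
#'   `start` and `duration` (seconds).
#' @examples
#' sched <- load_frame_schedule(list(c(2, 10), c(1, 20)))
#' sched$start      # 0 10 20
#' frame_midpoints(sched)
#' @export
load_frame_schedule <- function(spec) {
  if (is.matrix(spec)) spec <- lapply(seq_len(nrow(spec)), function(i) spec[i, ])
  if (length(spec) == 0L) stop("empty frame specification")
  counts <- vapply(spec, function(p) p[[1]], numeric(1))
  durs <- vapply(spec, function(p) p[[2]], numeric(1))
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("frame counts must be positive integers")
  }
  if (any(durs <= 0)) stop("frame durations must be positive")
  duration <- rep(durs, times = counts)
  start <- cumsum(c(0, duration[-length(duration)]))
  frame_schedule(start, duration)
}

#' Construct a frame schedule from explicit starts and durations
#'
#' @param start frame start times in seconds; strictly increasing, first 0.
#' @param duration frame durations in seconds, all positive; frames must be
#'   contiguous (`start[i + 1] == start[i] + duration[i]`).
#' @return a `frame_schedule` object.
#' @export
frame_schedule <- function(start, duration) {
  if (length(start) < 1L || length(start) != length(duration)) {
    stop("start and duration must be nonempty and of equal length")
  }
  if (any(duration <= 0)) stop("frame durations must be positive")
  if (any(diff(start) <= 0)) stop("frame starts must be strictly increasing")
  ends <- start + duration
  if (length(start) > 1L &&
      max(abs(start[-1L] - ends[-length(ends)])) > 1e-9) {
    stop("frames must be contiguous: start[i+1] = start[i] + duration[i]")
  }
  structure(list(start = as.numeric(start), duration = as.numeric(duration)),
            class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start)

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.0f s total (%.1f min)\n",
              length(x), frame_end(x), frame_end(x) / 60))
  invisible(x)
}

#' Frame midpoint times
#'
#' Midpoints place the interval-averaged frame measurements on the model time
#' axis.
#'
#' @param schedule a `frame_schedule`.
#' @return numeric vector of midpoint times in seconds, strictly increasing.
#' @export
frame_midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$start + schedule$duration / 2
}

#' End of the last frame (total scan duration, seconds)
#' @param schedule a `frame_schedule`.
#' @export
frame_end <- function(schedule) {
  n <- length(schedule)
  schedule$start[n] + schedule$duration[n]
}

#' Re-compress an expanded schedule into (count, duration) pairs
#'
#' Inverse of [load_frame_schedule()]: runs of equal durations are collapsed
#' back into `(count, duration)` pairs.
#'
#' @param schedule a `frame_schedule`.
#' @return list of `c(count, duration)` pairs.
#' @export
compress_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  r <- rle(schedule$duration)
  mapply(function(n, d) c(n, d), r$lengths, r$values, SIMPLIFY = FALSE)
}

#' The 30-frame 90-minute acquisition protocol
#'
#' The default protocol used throughout the package: 4 x 15, 4 x 30, 3 x 60,
#' 2 x 120, 5 x 240 and 12 x 300 s frames (30 frames, 5400 s).
#'
#' @return a `frame_schedule` of 30 frames totalling 90 min.
#' @export
default_frame_schedule <- function() {
  load_frame_schedule(list(c(4, 15), c(4, 30), c(3, 60),
                           c(2, 120), c(5, 240), c(12, 300)))
}
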