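# TagTrace: regular multichannel kinematic time series for one deployment.

#' Construct a tag trace
#'
#' A validated 10 Hz (by default) multichannel kinematic time series:
#' time (s from deployment start), depth (m, positive down), body pitch
#' (rad), forward speed (m s^-1), and y-axis gyroscope (rad s^-1). The time
#' grid must be strictly increasing and regular to within 1e-6 s; channels
#' must share a length. NA gaps are permitted on ingestion and flagged in a
#' logical `masked` column; masked spans are excluded from lunge detection.
#'
#' @param t time (s), strictly increasing regular grid.
#' @param depth depth (m).
#' @param pitch body pitch (rad).
#' @param speed forward speed (m s^-1).
#' @param gyro_y y-axis gyroscope (rad s^-1).
#' @param sample_rate nominal sampling rate (Hz), default 10.
#' @return Object of classes `tag_trace` and `data.frame` with attribute
#'   `sample_rate`.
#' @export
tag_trace <- function(t, depth, pitch, speed, gyro_y, sample_rate = 10) {
  n <- length(t)
  if (n < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  lens <- c(length(depth), length(pitch), length(speed), length(gyro_y))
  if (any(lens != n)) stop("all channels must have the same length as t", call. = FALSE)
  if (any(!is.finite(t))) stop("time grid must be finite", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6) {
    stop("time grid irregular beyond 1e-6 s; resample first (see read_tag_trace)",
         call. = FALSE)
  }
  masked <- !is.finite(depth) | !is.finite(pitch) | !is.finite(speed) |
    !is.finite(gyro_y)
  df <- data.frame(t = t, depth = depth, pitch = pitch, speed = speed,
                   gyro_y = gyro_y, masked = masked)
  structure(df, class = c("tag_trace", "data.frame"),
            sample_rate = sample_rate)
}

#' @export
print.tag_trace <- function(x, ...) {
  cat(sprintf("<tag_trace> %d samples @ %g Hz, %.1f s, depth %.1f-%.1f m, %d masked\n",
              nrow(x), attr(x, "sample_rate"), x$t[nrow(x)] - x$t[1],
              min(x$depth, na.rm = TRUE), max(x$depth, na.rm = TRUE),
              sum(x$masked)))
  invisible(x)
}

#' Sample interval of a trace
#' @param trace a [tag_trace()].
#' @return dt in seconds.
#' @export
trace_dt <- function(trace) 1 / attr(trace, "sample_rate")

#' Orientation-corrected depth-rate speed estimate
#'
#' `speed = depth_rate / sin(pitch)`, valid only when the body pitch is
#' steep enough that the geometric correction is stable. Samples with
#' `|pitch| < min_pitch` are returned as `NA` (excluded), never zero, so a
#' level-swimming sample can never fabricate a division-by-zero speed.
#'
#' @param depth_rate vertical speed (m s^-1, positive down).
#' @param pitch body pitch (rad).
#' @param min_pitch minimum absolute pitch (rad) for a valid estimate;
#'   default 0.35 (about 20 degrees).
#' @return Speed (m s^-1) with `NA` at excluded samples.
#' @examples
#' speed_from_ocdr(1, pi / 6)     # 2
#' speed_from_ocdr(1, 0.01)       # NA: too shallow
#' @export
speed_from_ocdr <- function(depth_rate, pitch, min_pitch = 0.35) {
  if (min_pitch <= 0) stop_domain("min_pitch", "must be > 0")
  out <- rep(NA_real_, length(depth_rate))
  ok <- is.finite(depth_rate) & is.finite(pitch) & abs(pitch) >= min_pitch
  out[ok] <- depth_rate[ok] / sin(pitch[ok])
  out
}

#' Identify dives in a trace
#'
#' A dive is a contiguous span with depth > `threshold` (default 1 m)
#' bounded by shallower samples. Returns a data.frame with `dive_id`,
#' start/end indices and times, and maximum depth.
#'
#' @param trace a [tag_trace()].
#' @param threshold dive depth threshold (m).
#' @return data.frame of dives (zero rows if none).
#' @export
find_dives <- function(trace, threshold = 1) {
  deep <- !is.na(trace$depth) & trace$depth > threshold
  runs <- true_runs(deep)
  if (!nrow(runs)) {
    return(data.frame(dive_id = integer(), i_start = integer(),
                      i_end = integer(), t_start = numeric(),
                      t_end = numeric(), max_depth = numeric()))
  }
  data.frame(
    dive_id = seq_len(nrow(runs)),
    i_start = runs$start, i_end = runs$end,
    t_start = trace$t[runs$start], t_end = trace$t[runs$end],
    max_depth = vapply(seq_len(nrow(runs)), function(i) {
      max(trace$depth[runs$start[i]:runs$end[i]], na.rm = TRUE)
    }, numeric(1))
  )
}
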