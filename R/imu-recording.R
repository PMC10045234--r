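#' Inertial measurement unit recording
#'
#' Container for one sensor site's uniformly sampled tri-axial gyroscope (and
#' optionally accelerometer) stream. Sample `k` (0-based) is taken at
#' `t0_s + k / rate_hz` on the session clock.
#'
#' @param subject_id Subject identifier (single string).
#' @param site Sensor site, one of `"left_foot"`, `"right_foot"`, `"left_hip"`.
#' @param rate_hz Sampling rate in samples per second (positive).
#' @param t0_s Session-clock time of the first sample, in seconds.
#' @param gyro Numeric matrix with columns x, y, z; angular velocity in deg/s.
#' @param accel Optional numeric matrix with columns x, y, z in g, with the
#'   same number of rows as `gyro`, or `NULL` if the accelerometer stream is
#'   absent.
#'
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, site, rate_hz, t0_s = 0, gyro,
                          accel = NULL) {
  site <- match.arg(site, imu_sites())
  gyro <- as_xyz_matrix(gyro, "gyro")
  if (!is.null(accel)) {
    accel <- as_xyz_matrix(accel, "accel")
    if (nrow(accel) != nrow(gyro)) {
      stop("`accel` must have the same number of samples as `gyro`",
           call. = FALSE)
    }
  }
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(t0_s) || length(t0_s) != 1L || !is.finite(t0_s)) {
    stop("`t0_s` must be a single finite number", call. = FALSE)
  }
  if (nrow(gyro) < 1L) stop("recording must contain at least one sample",
                            call. = FALSE)
  structure(
    list(subject_id = subject_id, site = site, rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s), gyro = gyro, accel = accel),
    class = "imu_recording"
  )
}

imu_sites <- function() c("left_foot", "right_foot", "left_hip")

as_xyz_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) {
    stop(sprintf("`%s` must have 3 columns (x, y, z)", what), call. = FALSE)
  }
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    stop(sprintf("`%s` must be finite numeric", what), call. = FALSE)
  }
  colnames(m) <- c("x", "y", "z")
  m
}

#' Number of samples in a recording
#' @param rec An [imu_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  nrow(rec$gyro)
}

#' Sample timestamps of a recording-like object
#'
#' @param x An object with `rate_hz`, `t0_s` and a per-sample length
#'   ([imu_recording()], [activity_mask()] or [probability_trace()]).
#' @return Numeric vector of session-clock times in seconds.
#' @export
sample_times <- function(x) {
  n <- if (inherits(x, "imu_recording")) nrow(x$gyro)
       else if (inherits(x, "activity_mask")) length(x$flags)
       else if (inherits(x, "probability_trace")) length(x$p)
       else stop("unsupported object", call. = FALSE)
  x$t0_s + (seq_len(n) - 1) / x$rate_hz
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- nrow(x$gyro)
  cat(sprintf("<imu_recording> subject %s, site %s\n", x$subject_id, x$site))
  cat(sprintf("  %d samples at %g Hz (%.1f s from t0 = %.2f s)\n",
              n, x$rate_hz, n / x$rate_hz, x$t0_s))
  cat(sprintf("  channels: gyro [deg/s]%s\n",
              if (is.null(x$accel)) "" else " + accel [g]"))
  invisible(x)
}

#' Labeled time-interval annotations
#'
#' Holds expert (or synthetic) FOG episode intervals and task spans for one
#' subject. On construction the track is normalized: intervals are sorted by
#' start time and overlapping or abutting `fog` intervals are unioned.
#'
#' @param subject_id Subject identifier.
#' @param intervals Data frame with columns `start_s`, `end_s`, `label`.
#'   Labels are `"fog"` for freezing episodes or `"task:<name>"` for task
#'   spans. Intervals are half-open `[start_s, end_s)`.
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(subject_id, intervals) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  intervals <- as.data.frame(intervals)
  required <- c("start_s", "end_s", "label")
  if (!all(required %in% names(intervals))) {
    stop("`intervals` must have columns start_s, end_s, label", call. = FALSE)
  }
  intervals <- intervals[required]
  if (nrow(intervals) > 0) {
    if (anyNA(intervals$start_s) || anyNA(intervals$end_s) ||
        any(!is.finite(intervals$start_s)) || any(!is.finite(intervals$end_s))) {
      stop("interval bounds must be finite", call. = FALSE)
    }
    if (any(intervals$start_s < 0)) {
      stop("interval times must be non-negative", call. = FALSE)
    }
    if (any(intervals$end_s <= intervals$start_s)) {
      stop("each interval must satisfy start_s < end_s", call. = FALSE)
    }
    fog <- intervals$label == "fog"
    if (any(fog)) {
      merged <- merge_interval_runs(intervals$start_s[fog],
                                    intervals$end_s[fog], gap_s = 0)
      intervals <- rbind(
        data.frame(start_s = merged$start_s, end_s = merged$end_s,
                   label = "fog"),
        intervals[!fog, , drop = FALSE]
      )
    }
    intervals <- intervals[order(intervals$start_s, intervals$end_s), ,
                           drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(list(subject_id = subject_id, intervals = intervals),
            class = "annotation_track")
}

#' Extract the FOG intervals of a track
#' @param track An [annotation_track()].
#' @return Data frame with columns `start_s`, `end_s`.
#' @export
fog_intervals <- function(track) {
  stopifnot(inherits(track, "annotation_track"))
  iv <- track$intervals
  iv[iv$label == "fog", c("start_s", "end_s"), drop = FALSE]
}

#' Extract task intervals of a track
#' @param track An [annotation_track()].
#' @param tasks Optional character vector of task names to keep.
#' @return Data frame with columns `start_s`, `end_s`, `task`.
#' @export
task_intervals <- function(track, tasks = NULL) {
  stopifnot(inherits(track, "annotation_track"))
  iv <- track$intervals
  keep <- startsWith(iv$label, "task:")
  iv <- iv[keep, , drop = FALSE]
  iv$task <- sub("^task:", "", iv$label)
  if (!is.null(tasks)) iv <- iv[iv$task %in% tasks, , drop = FALSE]
  rownames(iv) <- NULL
  iv[c("start_s", "end_s", "task")]
}

#' @export
print.annotation_track <- function(x, ...) {
  nf <- sum(x$intervals$label == "fog")
  nt <- sum(startsWith(x$intervals$label, "task:"))
  cat(sprintf("<annotation_track> subject %s: %d fog interval(s), %d task span(s)\n",
              x$subject_id, nf, nt))
  invisible(x)
}

# Union sorted-by-construction intervals: two consecutive intervals are merged
# when the gap between them is < gap_s, or when they overlap/abut (gap <= 0).
merge_interval_runs <- function(start_s, end_s, gap_s = 0) {
  stopifnot(length(start_s) == length(end_s))
  if (length(start_s) == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  o <- order(start_s, end_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  out_s <- start_s[1]; out_e <- end_s[1]
  res_s <- numeric(0); res_e <- numeric(0)
  for (i in seq_along(start_s)[-1]) {
    gap <- start_s[i] - out_e
    if (gap <= 0 || gap < gap_s) {
      out_e <- max(out_e, end_s[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- start_s[i]; out_e <- end_s[i]
    }
  }
  data.frame(start_s = c(res_s, out_s), end_s = c(res_e, out_e))
}
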