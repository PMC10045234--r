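#' Per-sample active/sedentary mask
#'
#' @param rate_hz Sampling rate in samples per second.
#' @param t0_s Session-clock time of the first sample.
#' @param flags Logical vector, `TRUE` = active.
#' @return An object of class `activity_mask`.
#' @export
activity_mask <- function(rate_hz, t0_s, flags) {
  stopifnot(is.logical(flags), length(flags) >= 1L, !anyNA(flags),
            rate_hz > 0)
  structure(list(rate_hz = as.numeric(rate_hz), t0_s = as.numeric(t0_s),
                 flags = flags),
            class = "activity_mask")
}

#' @export
print.activity_mask <- function(x, ...) {
  cat(sprintf("<activity_mask> %d samples at %g Hz: %.1f%% active\n",
              length(x$flags), x$rate_hz, 100 * mean(x$flags)))
  invisible(x)
}

#' Total hip angular speed
#'
#' Sum of the absolute angular velocity of the three gyroscope axes,
#' per sample, in deg/s. This is the quantity thresholded (after smoothing)
#' to separate active from sedentary time.
#'
#' @param rec An [imu_recording()] from the `left_hip` site.
#' @return Numeric vector, one value per sample.
#' @export
total_angular_speed <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$site != "left_hip") {
    stop("usage error: total_angular_speed() requires a left_hip recording",
         call. = FALSE)
  }
  rowSums(abs(rec$gyro))
}

#' Centered moving average
#'
#' Mean over all samples within `window_s / 2` seconds of each sample. At the
#' session edges the window shrinks to the available samples (no padding).
#'
#' @param x Numeric vector.
#' @param window_s Window length in seconds.
#' @param rate_hz Sampling rate of `x` in samples per second.
#' @return Numeric vector of the same length as `x`.
#' @export
centered_moving_average <- function(x, window_s, rate_hz) {
  if (length(x) == 0L) stop("usage error: empty series", call. = FALSE)
  stopifnot(window_s > 0, rate_hz > 0)
  half <- round(window_s / 2 * rate_hz)
  n <- length(x)
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Compute the activity mask from a hip recording
#'
#' Smooths the total hip angular speed with a centered moving average and
#' flags a sample active when the smoothed value is strictly above
#' `threshold_dps`; samples at or below the threshold (including exactly
#' 1 deg/s) are sedentary. With `per_axis = TRUE` each axis's absolute
#' angular velocity is smoothed separately and a sample is active when any
#' axis exceeds the threshold.
#'
#' @param rec An [imu_recording()] from the `left_hip` site.
#' @param threshold_dps Threshold in deg/s.
#' @param window_s Smoothing window in seconds.
#' @param per_axis Use the any-axis variant instead of the summed total.
#' @return An [activity_mask()].
#' @export
compute_activity_mask <- function(rec, threshold_dps = 1.0, window_s = 20,
                                  per_axis = FALSE) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$site != "left_hip") {
    stop("usage error: activity mask requires a left_hip recording",
         call. = FALSE)
  }
  if (per_axis) {
    sm <- apply(abs(rec$gyro), 2L, centered_moving_average,
                window_s = window_s, rate_hz = rec$rate_hz)
    flags <- rowSums(sm > threshold_dps) > 0
  } else {
    sm <- centered_moving_average(total_angular_speed(rec), window_s,
                                  rec$rate_hz)
    flags <- sm > threshold_dps
  }
  activity_mask(rec$rate_hz, rec$t0_s, as.logical(flags))
}
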