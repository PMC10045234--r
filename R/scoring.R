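#' Sample-wise confusion counts over active time
#'
#' Compares the sensor's per-sample FOG calls with the reference (video
#' rater) calls over active samples only. Samples where both methods call FOG
#' are true positives; samples where neither does are true negatives.
#'
#' @param sensor Logical per-sample sensor FOG calls.
#' @param reference Logical per-sample reference FOG calls.
#' @param mask An [activity_mask()] on the same clock, or a logical vector of
#'   the same length (`TRUE` = compare this sample).
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(sensor, reference, mask) {
  flags <- if (inherits(mask, "activity_mask")) mask$flags else mask
  if (length(sensor) != length(reference) ||
      length(sensor) != length(flags)) {
    stop("usage error: series differ in length", call. = FALSE)
  }
  s <- sensor[flags]
  r <- reference[flags]
  structure(list(tp = sum(s & r), tn = sum(!s & !r),
                 fp = sum(s & !r), fn = sum(!s & r)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d  tn %d  fp %d  fn %d (n = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Sample-wise accuracy
#'
#' `100 * (tp + tn) / (tp + tn + fp + fn)`: the share of compared samples on
#' which sensor and reference agree.
#'
#' @param c A [confusion()] result.
#' @return Accuracy in percent.
#' @export
accuracy_pct <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("undefined metric: no compared samples", call. = FALSE)
  100 * (c$tp + c$tn) / total
}

#' Sensitivity (percent)
#' @inheritParams accuracy_pct
#' @return `100 * tp / (tp + fn)`, or `NA` when the reference has no FOG.
#' @export
sensitivity_pct <- function(c) {
  if (c$tp + c$fn == 0) return(NA_real_)
  100 * c$tp / (c$tp + c$fn)
}

#' Specificity (percent)
#' @inheritParams accuracy_pct
#' @return `100 * tn / (tn + fp)`, or `NA` when the reference is all FOG.
#' @export
specificity_pct <- function(c) {
  if (c$tn + c$fp == 0) return(NA_real_)
  100 * c$tn / (c$tn + c$fp)
}

#' Percent of active time spent freezing
#'
#' `100 *` (FOG samples among active samples) `/` (active samples).
#'
#' @param fog_flags Logical per-sample FOG calls.
#' @param mask An [activity_mask()] or logical vector of the same length.
#' @return %ATSF in percent.
#' @export
atsf_pct <- function(fog_flags, mask) {
  flags <- if (inherits(mask, "activity_mask")) mask$flags else mask
  if (length(fog_flags) != length(flags)) {
    stop("usage error: series and mask differ in length", call. = FALSE)
  }
  n_active <- sum(flags)
  if (n_active == 0) {
    stop("undefined metric: no active samples", call. = FALSE)
  }
  100 * sum(fog_flags & flags) / n_active
}

#' Mean FOG episode duration
#' @param ev An [event_list()] with at least one event.
#' @return Mean of `end_s - start_s` in seconds.
#' @export
mean_episode_duration <- function(ev) {
  stopifnot(inherits(ev, "event_list"))
  if (nrow(ev) == 0L) {
    stop("undefined metric: empty event list", call. = FALSE)
  }
  mean(ev$end_s - ev$start_s)
}

#' Per-task agreement and burden scores
#'
#' Computes confusion-based metrics and both %ATSF figures separately on the
#' samples falling inside each task's intervals (intersected with active
#' time). Tasks with no active samples yield `NA` metrics rather than zeros.
#'
#' @param sensor Logical per-sample sensor FOG calls.
#' @param reference Logical per-sample reference FOG calls.
#' @param mask An [activity_mask()] giving the clock and active samples.
#' @param tasks An [annotation_track()] carrying `task:<name>` intervals;
#'   intervals of different tasks must not overlap.
#' @return Data frame with one row per task: `task`, `n_samples`, `n_active`,
#'   `accuracy_pct`, `sensitivity_pct`, `specificity_pct`, `sensor_atsf_pct`,
#'   `video_atsf_pct`.
#' @export
per_task_scores <- function(sensor, reference, mask, tasks) {
  stopifnot(inherits(mask, "activity_mask"))
  iv <- task_intervals(tasks)
  if (nrow(iv) > 1L) {
    o <- order(iv$start_s)
    if (any(iv$start_s[o][-1] < iv$end_s[o][-nrow(iv)])) {
      stop("format error: overlapping task intervals", call. = FALSE)
    }
  }
  n <- length(mask$flags)
  rows <- lapply(split(iv, iv$task), function(ti) {
    in_task <- rasterize(ti, mask$rate_hz, mask$t0_s, n)
    sel <- in_task & mask$flags
    n_active <- sum(sel)
    if (n_active == 0L) {
      return(data.frame(task = ti$task[1], n_samples = sum(in_task),
                        n_active = 0L, accuracy_pct = NA_real_,
                        sensitivity_pct = NA_real_, specificity_pct = NA_real_,
                        sensor_atsf_pct = NA_real_, video_atsf_pct = NA_real_))
    }
    cc <- confusion(sensor, reference, sel)
    data.frame(task = ti$task[1], n_samples = sum(in_task),
               n_active = n_active,
               accuracy_pct = accuracy_pct(cc),
               sensitivity_pct = sensitivity_pct(cc),
               specificity_pct = specificity_pct(cc),
               sensor_atsf_pct = atsf_pct(sensor, sel),
               video_atsf_pct = atsf_pct(reference, sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
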