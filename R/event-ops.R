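#' FOG event list
#'
#' A sorted, non-overlapping set of half-open `[start_s, end_s)` FOG events.
#'
#' @param events Data frame with numeric columns `start_s`, `end_s`.
#' @return An object of class `event_list` (a data frame).
#' @export
event_list <- function(events = data.frame(start_s = numeric(0),
                                           end_s = numeric(0))) {
  events <- as.data.frame(events)[c("start_s", "end_s")]
  if (nrow(events) > 0) {
    if (any(events$end_s <= events$start_s)) {
      stop("each event must satisfy start_s < end_s", call. = FALSE)
    }
    events <- events[order(events$start_s), , drop = FALSE]
    if (any(events$start_s[-1] < events$end_s[-nrow(events)])) {
      stop("events must be non-overlapping", call. = FALSE)
    }
    rownames(events) <- NULL
  }
  class(events) <- c("event_list", "data.frame")
  events
}

#' Convert a per-sample binary series to events
#'
#' Maximal runs of `TRUE` become events; an event starts at the timestamp of
#' its first flagged sample and ends one sample period after its last flagged
#' sample (half-open convention).
#'
#' @param flags Logical vector.
#' @param rate_hz Sampling rate in samples per second.
#' @param t0_s Session-clock time of the first sample.
#' @return An [event_list()].
#' @export
series_to_events <- function(flags, rate_hz, t0_s = 0) {
  stopifnot(is.logical(flags), length(flags) >= 1L, !anyNA(flags))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  event_list(data.frame(
    start_s = t0_s + (starts[keep] - 1L) / rate_hz,
    end_s = t0_s + ends[keep] / rate_hz
  ))
}

#' Merge events separated by short gaps
#'
#' Consecutive events whose gap (`next start - previous end`) is strictly
#' less than `gap_s` are unioned, applied transitively until no gap below
#' `gap_s` remains. The operation is idempotent.
#'
#' @param ev An [event_list()].
#' @param gap_s Merge gap in seconds; a gap of exactly `gap_s` is kept.
#' @return An [event_list()].
#' @export
merge_events <- function(ev, gap_s = 2.0) {
  stopifnot(inherits(ev, "event_list"), gap_s >= 0)
  if (nrow(ev) == 0L) return(ev)
  merged <- merge_interval_runs(ev$start_s, ev$end_s, gap_s = gap_s)
  event_list(merged)
}

#' Rasterize intervals onto a sample grid
#'
#' Marks sample `k` (timestamp `t0_s + k / rate_hz`) `TRUE` when it falls in
#' any interval under the half-open convention `start <= t < end`. Accepts an
#' [event_list()], an [annotation_track()] (its fog intervals are used), or a
#' plain data frame with `start_s`/`end_s` columns.
#'
#' @param x Intervals to rasterize.
#' @param rate_hz Sampling rate in samples per second.
#' @param t0_s Session-clock time of sample 0.
#' @param n Number of samples in the grid.
#' @return Logical vector of length `n`.
#' @export
rasterize <- function(x, rate_hz, t0_s, n) {
  stopifnot(n >= 1L)
  iv <- if (inherits(x, "annotation_track")) fog_intervals(x)
        else as.data.frame(x)[c("start_s", "end_s")]
  out <- logical(n)
  if (nrow(iv) == 0L) return(out)
  # work in sample units with a small tolerance against fp drift of
  # second-valued boundaries: member iff k >= s - eps and k < e - eps
  eps <- 1e-9
  s <- (iv$start_s - t0_s) * rate_hz
  e <- (iv$end_s - t0_s) * rate_hz
  k_lo <- pmax(0, ceiling(s - eps))
  k_hi <- pmin(n - 1, ceiling(e - eps) - 1)
  for (i in seq_len(nrow(iv))) {
    if (k_hi[i] >= k_lo[i]) out[(k_lo[i]:k_hi[i]) + 1L] <- TRUE
  }
  out
}

#' Restrict a per-sample series to active samples
#'
#' Drops sedentary samples, keeping the original sample indices as an
#' attribute so results can be mapped back to the session clock.
#'
#' @param flags Logical (or numeric) per-sample vector.
#' @param mask An [activity_mask()] on the same clock and of the same length.
#' @return The subsequence of `flags` at active samples, with attribute
#'   `index` holding the original (1-based) sample indices.
#' @export
restrict_active <- function(flags, mask) {
  stopifnot(inherits(mask, "activity_mask"))
  if (length(flags) != length(mask$flags)) {
    stop("usage error: series and mask differ in length", call. = FALSE)
  }
  idx <- which(mask$flags)
  out <- flags[idx]
  attr(out, "index") <- idx
  out
}
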