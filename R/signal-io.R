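#' Read an IMU recording from CSV
#'
#' The file dialect is UTF-8 comma-separated with a header
#' `time_s,gyro_x,gyro_y,gyro_z[,accel_x,accel_y,accel_z]`, preceded by
#' sidecar comment lines `#subject=`, `#site=`, `#rate_hz=`. When sidecar
#' metadata is absent, subject and site are parsed from a
#' `<subject>_<site>.csv` file name and the rate is inferred from the median
#' timestamp spacing. Timestamps must be strictly increasing and uniform to
#' within 1% jitter of the median spacing.
#'
#' @param path Path to the CSV file.
#' @return An [imu_recording()].
#' @export
read_imu <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 16L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- parse_sidecar(meta_lines)
  dt <- data.table::fread(path, skip = length(meta_lines), header = TRUE,
                          data.table = FALSE)
  need <- c("time_s", "gyro_x", "gyro_y", "gyro_z")
  if (!all(need %in% names(dt))) {
    stop("format error: missing required column(s): ",
         paste(setdiff(need, names(dt)), collapse = ", "), call. = FALSE)
  }
  tt <- dt$time_s
  if (length(tt) < 1L) stop("format error: no data rows", call. = FALSE)
  if (length(tt) > 1L) {
    d <- diff(tt)
    if (any(d <= 0)) stop("data error: non-monotonic timestamps",
                          call. = FALSE)
    med <- stats::median(d)
    if (any(abs(d - med) > 0.01 * med)) {
      stop("data error: non-uniform timestamps (jitter above 1% of median spacing)",
           call. = FALSE)
    }
  }
  rate <- meta$rate_hz
  if (is.null(rate)) {
    rate <- if (length(tt) > 1L) 1 / stats::median(diff(tt)) else 100
  }
  ids <- meta[c("subject", "site")]
  if (is.null(ids$subject) || is.null(ids$site)) {
    guess <- parse_imu_filename(basename(path))
    if (is.null(ids$subject)) ids$subject <- guess$subject
    if (is.null(ids$site)) ids$site <- guess$site
  }
  has_accel <- all(c("accel_x", "accel_y", "accel_z") %in% names(dt))
  imu_recording(
    subject_id = ids$subject %||% "unknown",
    site = ids$site %||% stop("cannot determine sensor site for ", path,
                              call. = FALSE),
    rate_hz = as.numeric(rate),
    t0_s = tt[1],
    gyro = as.matrix(dt[c("gyro_x", "gyro_y", "gyro_z")]),
    accel = if (has_accel) as.matrix(dt[c("accel_x", "accel_y", "accel_z")])
  )
}

parse_sidecar <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  if (!is.null(out$rate_hz)) out$rate_hz <- as.numeric(out$rate_hz)
  out
}

parse_imu_filename <- function(name) {
  name <- sub("\\.csv$", "", name)
  for (site in imu_sites()) {
    suffix <- paste0("_", site)
    if (endsWith(name, suffix)) {
      return(list(subject = sub(paste0(suffix, "$"), "", name), site = site))
    }
  }
  list(subject = NULL, site = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an IMU recording to CSV
#'
#' Emits the dialect read by [read_imu()]: sidecar comment lines carrying
#' subject, site and rate, then one row per sample. Accelerometer columns are
#' omitted when the stream is absent. Output is deterministic for a fixed
#' recording; values are written with enough digits to round-trip within 1e-9.
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(time_s = sample_times(rec))
  df[c("gyro_x", "gyro_y", "gyro_z")] <- rec$gyro
  if (!is.null(rec$accel)) {
    df[c("accel_x", "accel_y", "accel_z")] <- rec$accel
  }
  con <- file(path, open = "wb")
  ok <- FALSE
  on.exit(if (!ok) close(con))
  writeLines(c(sprintf("#subject=%s", rec$subject_id),
               sprintf("#site=%s", rec$site),
               sprintf("#rate_hz=%.10g", rec$rate_hz)), con)
  close(con); ok <- TRUE
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read an annotation track from CSV
#'
#' Expects a header `start_s,end_s,label`, optionally preceded by a
#' `#subject=` sidecar line. The returned track is normalized (fog intervals
#' sorted and unioned).
#'
#' @param path Path to the CSV file.
#' @param subject_id Subject identifier used when no sidecar line is present.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 4L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- parse_sidecar(meta_lines)
  dt <- data.table::fread(path, skip = length(meta_lines), header = TRUE,
                          data.table = FALSE)
  if (!all(c("start_s", "end_s", "label") %in% names(dt))) {
    stop("format error: annotation file needs columns start_s,end_s,label",
         call. = FALSE)
  }
  if (nrow(dt) > 0 && any(dt$end_s <= dt$start_s)) {
    stop("format error: interval with end_s <= start_s", call. = FALSE)
  }
  annotation_track(meta$subject %||% subject_id %||% "unknown", dt)
}

#' Write an annotation track to CSV
#' @param track An [annotation_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  con <- file(path, open = "wb")
  ok <- FALSE
  on.exit(if (!ok) close(con))
  writeLines(sprintf("#subject=%s", track$subject_id), con)
  close(con); ok <- TRUE
  data.table::fwrite(track$intervals, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Resample a recording with a Hann-windowed sinc kernel
#'
#' Downsamples every channel to `target_rate_hz` by convolution with a
#' Hann-tapered sinc low-pass kernel cut off at the target Nyquist frequency.
#' The kernel half-width is 64 source samples; edges use reflection padding;
#' kernel weights are renormalized to unit sum at every output sample so a
#' constant signal is reproduced exactly. Output timestamps are anchored at
#' `t0_s` and cover the input span (`floor((n-1) * ratio) + 1` samples). A
#' recording already at the target rate is returned unchanged; upsampling is
#' not supported.
#'
#' @param rec An [imu_recording()].
#' @param target_rate_hz Target sampling rate in samples per second.
#' @param half_width Kernel half-width in source samples.
#' @return An [imu_recording()] at `target_rate_hz`.
#' @export
resample_sinc <- function(rec, target_rate_hz, half_width = 64L) {
  stopifnot(inherits(rec, "imu_recording"))
  if (target_rate_hz > rec$rate_hz * (1 + 1e-9)) {
    stop("unsupported: upsampling (target rate above source rate)",
         call. = FALSE)
  }
  if (abs(target_rate_hz - rec$rate_hz) <= 1e-9 * rec$rate_hz) return(rec)
  ratio <- target_rate_hz / rec$rate_hz
  n <- nrow(rec$gyro)
  n_out <- floor((n - 1) * ratio) + 1L
  # fractional source index (0-based) of each output sample
  s <- (seq_len(n_out) - 1) / ratio
  gyro_out <- apply(rec$gyro, 2L, resample_channel, s = s, n = n,
                    ratio = ratio, half_width = half_width)
  accel_out <- if (!is.null(rec$accel)) {
    apply(rec$accel, 2L, resample_channel, s = s, n = n, ratio = ratio,
          half_width = half_width)
  }
  imu_recording(rec$subject_id, rec$site, target_rate_hz, rec$t0_s,
                gyro = gyro_out, accel = accel_out)
}

resample_channel <- function(x, s, n, ratio, half_width) {
  hw <- as.integer(half_width)
  # reflection padding (no edge repeat): x[-k] = x[k], x[n-1+k] = x[n-1-k]
  left <- if (n > 1) x[pmin(n, (hw + 1):2)] else rep(x[1], hw)
  right <- if (n > 1) x[pmax(1, (n - 1):(n - hw))] else rep(x[1], hw)
  xp <- c(left, x, right)           # index i in xp = source index (i - hw - 1)
  j0 <- floor(s) - hw + 1           # first source index (0-based) in window
  acc <- numeric(length(s))
  wsum <- numeric(length(s))
  for (m in 0:(2L * hw - 1L)) {
    j <- j0 + m                     # source index, 0-based
    u <- j - s                      # offset from the output point
    w <- ratio * sinc(ratio * u) * hann_taper(u / hw)
    acc <- acc + w * xp[j + hw + 1L]
    wsum <- wsum + w
  }
  acc / wsum
}

sinc <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u))

hann_taper <- function(v) ifelse(abs(v) <= 1, 0.5 * (1 + cos(pi * v)), 0)
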