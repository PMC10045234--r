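#' Detector configuration
#'
#' Parameters of the two-stage probabilistic FOG detector. The detector first
#' derives two per-sample event flags from a foot gyroscope — a zero-velocity
#' flag (windowed RMS of the gyroscope magnitude below a stance-like floor)
#' and a trembling flag (3–8 Hz band power dominating the 0.5–3 Hz locomotor
#' band) — then fuses them with a causal two-state forward probability filter
#' whose output is the per-sample probability of FOG.
#'
#' @param zv_window_s Centered window for the zero-velocity RMS, seconds.
#' @param zv_rms_dps RMS floor below which a sample is a zero-velocity
#'   candidate, deg/s.
#' @param fi_window_s Centered window for the band-power (freeze-index style)
#'   analysis, seconds.
#' @param freeze_band_hz Two-vector, trembling band in Hz (`[low, high]`,
#'   lower edge inclusive).
#' @param locomotor_band_hz Two-vector, locomotor band in Hz (`[low, high)`).
#' @param fi_ratio_min Minimum freeze/locomotor band-power ratio for the
#'   trembling flag.
#' @param power_floor Minimum total (freeze + locomotor) band power,
#'   (deg/s)^2, below which the trembling flag is suppressed.
#' @param persist Self-transition probability of each hidden state per sample.
#' @param emit 2 x 4 emission matrix, rows `noFOG`/`FOG`, columns the
#'   observation categories (zv, trembling) = (0,0), (1,0), (0,1), (1,1).
#'   Rows must sum to 1.
#' @param pfog_threshold Probability threshold above which a sample is called
#'   FOG.
#' @param prior_fog Initial probability of the FOG state.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(zv_window_s = 0.25,
                            zv_rms_dps = 10,
                            fi_window_s = 2.0,
                            freeze_band_hz = c(3, 8),
                            locomotor_band_hz = c(0.5, 3),
                            fi_ratio_min = 2.0,
                            power_floor = 10,
                            persist = 0.99,
                            emit = default_emission(),
                            pfog_threshold = 0.7,
                            prior_fog = 0.01) {
  emit <- as.matrix(emit)
  stopifnot(zv_window_s > 0, zv_rms_dps > 0, fi_window_s > 0,
            length(freeze_band_hz) == 2L, length(locomotor_band_hz) == 2L,
            freeze_band_hz[1] < freeze_band_hz[2],
            locomotor_band_hz[1] < locomotor_band_hz[2],
            fi_ratio_min > 0, power_floor >= 0,
            persist > 0, persist < 1,
            nrow(emit) == 2L, ncol(emit) == 4L, all(emit >= 0),
            pfog_threshold > 0, pfog_threshold < 1,
            prior_fog > 0, prior_fog < 1)
  if (any(abs(rowSums(emit) - 1) > 1e-8)) {
    stop("emission rows must sum to 1", call. = FALSE)
  }
  rownames(emit) <- c("noFOG", "FOG")
  colnames(emit) <- c("zv0_tr0", "zv1_tr0", "zv0_tr1", "zv1_tr1")
  structure(
    list(zv_window_s = zv_window_s, zv_rms_dps = zv_rms_dps,
         fi_window_s = fi_window_s, freeze_band_hz = freeze_band_hz,
         locomotor_band_hz = locomotor_band_hz, fi_ratio_min = fi_ratio_min,
         power_floor = power_floor, persist = persist, emit = emit,
         pfog_threshold = pfog_threshold, prior_fog = prior_fog),
    class = "detector_config"
  )
}

#' Default emission table of the forward filter
#'
#' Probabilities of the four (zero-velocity, trembling) observation pairs in
#' each hidden state, chosen so that simultaneous zero-velocity and trembling
#' evidence strongly favors FOG while the quiet no-event pair favors normal
#' locomotion.
#'
#' @return A 2 x 4 numeric matrix with rows `noFOG`, `FOG`.
#' @export
default_emission <- function() {
  matrix(c(0.6, 0.25, 0.1, 0.05,
           0.1, 0.2, 0.2, 0.5),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("noFOG", "FOG"),
                         c("zv0_tr0", "zv1_tr0", "zv0_tr1", "zv1_tr1")))
}

#' Per-sample FOG probability trace
#' @param rate_hz Sampling rate, samples per second.
#' @param t0_s Session-clock time of the first sample.
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return An object of class `probability_trace`.
#' @export
probability_trace <- function(rate_hz, t0_s, p) {
  stopifnot(is.numeric(p), length(p) >= 1L, all(is.finite(p)),
            all(p >= 0), all(p <= 1), rate_hz > 0)
  structure(list(rate_hz = as.numeric(rate_hz), t0_s = as.numeric(t0_s),
                 p = as.numeric(p)),
            class = "probability_trace")
}

#' @export
print.probability_trace <- function(x, ...) {
  cat(sprintf("<probability_trace> %d samples at %g Hz; mean p = %.3f, max p = %.3f\n",
              length(x$p), x$rate_hz, mean(x$p), max(x$p)))
  invisible(x)
}

check_foot_100hz <- function(rec, what) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!rec$site %in% c("left_foot", "right_foot")) {
    stop("usage error: ", what, " requires a foot recording", call. = FALSE)
  }
}

#' Zero-velocity event flags
#'
#' Flags a sample when the RMS of the gyroscope magnitude over a centered
#' window is strictly below `cfg$zv_rms_dps`, indicating a stance-like or
#' motionless foot. Edge windows shrink to the available samples.
#'
#' @param rec A foot [imu_recording()].
#' @param cfg A [detector_config()].
#' @return Logical vector, one flag per sample.
#' @export
zero_velocity_flags <- function(rec, cfg = detector_config()) {
  check_foot_100hz(rec, "zero_velocity_flags()")
  n <- nrow(rec$gyro)
  half <- round(cfg$zv_window_s / 2 * rec$rate_hz)
  if (2 * half + 1 > n) {
    stop("usage error: zero-velocity window longer than the recording",
         call. = FALSE)
  }
  mag2 <- rowSums(rec$gyro^2)
  rms <- sqrt(centered_moving_average(mag2, cfg$zv_window_s, rec$rate_hz))
  rms < cfg$zv_rms_dps
}

#' Trembling event flags
#'
#' Over a centered window, computes the periodogram band power of the
#' (window-mean-removed) angular velocity in the trembling band and in the
#' locomotor band, summed over the three gyroscope axes, using the window's
#' own Fourier frequencies. Band power is evaluated on the signed axis
#' components rather than on the vector norm: the norm of a symmetric
#' oscillation is rectified, which would shift a genuine 3–8 Hz tremor to
#' twice its frequency and out of band. A sample is flagged when freeze-band
#' power exceeds `fi_ratio_min` times the locomotor power and the summed
#' power is above `power_floor`. Samples closer than half a window to an
#' edge inherit the nearest full-window decision.
#'
#' @inheritParams zero_velocity_flags
#' @return Logical vector, one flag per sample.
#' @export
trembling_flags <- function(rec, cfg = detector_config()) {
  check_foot_100hz(rec, "trembling_flags()")
  n <- nrow(rec$gyro)
  rate <- rec$rate_hz
  w <- 2L * as.integer(floor(cfg$fi_window_s * rate / 2)) + 1L
  if (w > n) {
    stop("usage error: trembling window longer than the recording",
         call. = FALSE)
  }
  bands <- list(freeze = cfg$freeze_band_hz, loco = cfg$locomotor_band_hz)
  pf <- numeric(n); pl <- numeric(n)
  for (ax in 1:3) {
    bp <- sliding_band_power(rec$gyro[, ax], rate, w, bands = bands)
    pf <- pf + bp$freeze
    pl <- pl + bp$loco
  }
  flags <- (pf > cfg$fi_ratio_min * pl) & (pf + pl > cfg$power_floor)
  h <- (w - 1L) %/% 2L
  # replicate nearest full-window decision into the edges
  flags[seq_len(h)] <- flags[h + 1L]
  flags[(n - h + 1L):n] <- flags[n - h]
  flags
}

# Sliding-window periodogram band power at every full-window center.
# For window length w (odd) and the window's Fourier frequencies
# f_m = m * rate / w, band power at center k is sum over band frequencies of
# 2 |c_m(k)|^2 / w^2 where c_m(k) is the windowed DFT coefficient; this
# equals A^2/2 for a sine of amplitude A at an exact bin frequency. The
# coefficients at m >= 1 are invariant to the window mean, so the signal is
# effectively detrended per window. The locomotor band is [low, high); the
# freeze band is [low, high].
sliding_band_power <- function(x, rate, w, bands) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  freqs <- (seq_len(w - 1L)) * rate / w
  pick <- list(
    freeze = which(freqs >= bands$freeze[1] & freqs <= bands$freeze[2]),
    loco = which(freqs >= bands$loco[1] & freqs < bands$loco[2])
  )
  nfft <- stats::nextn(n + w - 1L, 2L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  out <- list(freeze = numeric(n), loco = numeric(n))
  for (band in names(pick)) {
    total <- numeric(n)
    for (m in pick[[band]]) {
      kern <- exp(-2i * pi * m * (0:(w - 1L)) / w)
      K <- stats::fft(c(rev(kern), rep(0, nfft - w)))
      z <- stats::fft(X * K, inverse = TRUE) / nfft
      # c_m(k) = z[k + h] for full-window centers k in (h+1)..(n-h)
      ctr <- (h + 1L):(n - h)
      total[ctr] <- total[ctr] + 2 * Mod(z[ctr + h])^2 / w^2
    }
    out[[band]] <- total
  }
  out
}

#' Two-state forward probability filter
#'
#' Causal forward (filtering) recursion of a two-state hidden process
#' (`noFOG`, `FOG`) with symmetric transitions of self-probability
#' `cfg$persist`, observing the per-sample (zero-velocity, trembling) flag
#' pair as one of four categories with likelihoods `cfg$emit`. The returned
#' trace is the normalized posterior `P(FOG | observations so far)` at every
#' sample, starting from prior `cfg$prior_fog`.
#'
#' @param zv Logical vector of zero-velocity flags.
#' @param tremble Logical vector of trembling flags, same length.
#' @param cfg A [detector_config()].
#' @param rate_hz,t0_s Clock metadata attached to the returned trace.
#' @return A [probability_trace()].
#' @export
pfog_forward_filter <- function(zv, tremble, cfg = detector_config(),
                                rate_hz = 100, t0_s = 0) {
  if (length(zv) != length(tremble)) {
    stop("usage error: flag vectors differ in length", call. = FALSE)
  }
  n <- length(zv)
  stopifnot(n >= 1L)
  obs <- 1L + as.integer(zv) + 2L * as.integer(tremble)
  e_no <- cfg$emit[1L, ]
  e_fog <- cfg$emit[2L, ]
  a <- cfg$persist
  p <- cfg$prior_fog
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (k > 1L) p <- a * p + (1 - a) * (1 - p)   # predict
    o <- obs[k]
    num <- p * e_fog[o]
    p <- num / (num + (1 - p) * e_no[o])         # update + normalize
    out[k] <- p
  }
  probability_trace(rate_hz, t0_s, out)
}

#' Detect FOG probability on one foot
#'
#' Convenience wrapper running the two event stages and the forward filter on
#' a single foot recording.
#'
#' @inheritParams zero_velocity_flags
#' @return A [probability_trace()] aligned with `rec`.
#' @export
detect_foot <- function(rec, cfg = detector_config()) {
  zv <- zero_velocity_flags(rec, cfg)
  tr <- trembling_flags(rec, cfg)
  pfog_forward_filter(zv, tr, cfg, rate_hz = rec$rate_hz, t0_s = rec$t0_s)
}

#' Combine the two feet's probability traces
#'
#' A sample is called FOG when the probability for either foot is strictly
#' above the threshold.
#'
#' @param left,right [probability_trace()] objects on a common clock.
#' @param threshold Probability threshold.
#' @return Logical vector of per-sample FOG calls.
#' @export
combine_feet <- function(left, right, threshold = 0.7) {
  stopifnot(inherits(left, "probability_trace"),
            inherits(right, "probability_trace"))
  if (length(left$p) != length(right$p)) {
    stop("usage error: traces differ in length", call. = FALSE)
  }
  if (abs(left$rate_hz - right$rate_hz) > 1e-9 ||
      abs(left$t0_s - right$t0_s) > 1e-9) {
    stop("usage error: traces are not on a common clock", call. = FALSE)
  }
  left$p > threshold | right$p > threshold
}
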