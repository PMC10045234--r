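# Brute-force reference implementations used as independent oracles.
# These deliberately use explicit per-sample loops and naive arithmetic,
# independent of the vectorized/cumsum/FFT paths in the package.

oracle_moving_average <- function(x, window_s, rate_hz) {
  half <- round(window_s / 2 * rate_hz)
  n <- length(x)
  out <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1, k - half)
    hi <- min(n, k + half)
    out[k] <- sum(x[lo:hi]) / (hi - lo + 1)
  }
  out
}

oracle_window_rms <- function(mag, window_s, rate_hz) {
  half <- round(window_s / 2 * rate_hz)
  n <- length(mag)
  out <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1, k - half)
    hi <- min(n, k + half)
    out[k] <- sqrt(mean(mag[lo:hi]^2))
  }
  out
}

# Half-open membership with the package's documented sample-unit tolerance.
oracle_rasterize <- function(iv, rate_hz, t0_s, n) {
  out <- logical(n)
  for (k in 0:(n - 1)) {
    for (i in seq_len(nrow(iv))) {
      s <- (iv$start_s[i] - t0_s) * rate_hz
      e <- (iv$end_s[i] - t0_s) * rate_hz
      if (k >= s - 1e-9 && k < e - 1e-9) out[k + 1] <- TRUE
    }
  }
  out
}

oracle_confusion <- function(sensor, reference, active) {
  tp <- tn <- fp <- fn <- 0L
  for (k in seq_along(sensor)) {
    if (!active[k]) next
    if (sensor[k] && reference[k]) tp <- tp + 1L
    else if (!sensor[k] && !reference[k]) tn <- tn + 1L
    else if (sensor[k] && !reference[k]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Repeated pairwise merging until fixpoint.
oracle_merge_fixpoint <- function(ev, gap_s) {
  ev <- ev[order(ev$start_s), , drop = FALSE]
  repeat {
    changed <- FALSE
    i <- 1
    while (i < nrow(ev)) {
      if (ev$start_s[i + 1] - ev$end_s[i] < gap_s) {
        ev$end_s[i] <- max(ev$end_s[i], ev$end_s[i + 1])
        ev <- ev[-(i + 1), , drop = FALSE]
        changed <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!changed) break
  }
  rownames(ev) <- NULL
  ev
}

# Rank-then-Pearson with explicit formulas.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(rx)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exhaustive-enumeration forward posterior of the two-state chain:
# P(S_k = FOG | o_1..k) summed over all state paths.
oracle_hmm_forward <- function(obs, emit, persist, prior_fog) {
  n <- length(obs)
  pi0 <- c(1 - prior_fog, prior_fog)      # (noFOG, FOG)
  A <- matrix(c(persist, 1 - persist,
                1 - persist, persist), 2, 2, byrow = TRUE)
  out <- numeric(n)
  for (k in seq_len(n)) {
    paths <- as.matrix(expand.grid(rep(list(1:2), k)))
    num <- 0; den <- 0
    for (r in seq_len(nrow(paths))) {
      s <- paths[r, ]
      pr <- pi0[s[1]] * emit[s[1], obs[1]]
      if (k > 1) {
        for (t in 2:k) pr <- pr * A[s[t - 1], s[t]] * emit[s[t], obs[t]]
      }
      den <- den + pr
      if (s[k] == 2) num <- num + pr
    }
    out[k] <- num / den
  }
  out
}

# Direct windowed-DFT band power at one full-window center (1-based k).
oracle_band_power <- function(x, k, w, ms) {
  h <- (w - 1) %/% 2
  win <- x[(k - h):(k + h)]
  total <- 0
  for (m in ms) {
    c_m <- sum(win * exp(-2i * pi * m * (0:(w - 1)) / w))
    total <- total + 2 * Mod(c_m)^2 / w^2
  }
  total
}
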