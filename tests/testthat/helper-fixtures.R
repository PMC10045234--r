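# Small recording builders used across test files.

foot_rec <- function(gyro, rate_hz = 100, site = "left_foot", t0_s = 0) {
  imu_recording("T01", site, rate_hz, t0_s, gyro)
}

hip_rec <- function(gyro, rate_hz = 100, t0_s = 0) {
  imu_recording("T01", "left_hip", rate_hz, t0_s, gyro)
}

sine_foot <- function(freq_hz, amp_dps, dur_s, rate_hz = 100) {
  tt <- seq(0, dur_s - 1 / rate_hz, by = 1 / rate_hz)
  foot_rec(cbind(amp_dps * sin(2 * pi * freq_hz * tt), 0, 0), rate_hz)
}

random_events <- function(n_events, span_s = 60) {
  starts <- sort(runif(n_events, 0, span_s))
  ends <- starts + runif(n_events, 0.1, 3)
  # enforce non-overlap so the list is a valid normalized input
  for (i in seq_len(n_events - 1)) {
    ends[i] <- min(ends[i], starts[i + 1])
  }
  keep <- ends > starts
  data.frame(start_s = starts[keep], end_s = ends[keep])
}

# The shared 19-subject visit cohort used by the acceptance suite; built once.
acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- simulate_cohort(n = 19, seed = 7, sessions = "visit")
      result <- run_cohort(cohort)
      cache <<- list(cohort = cohort, result = result)
    }
    cache
  }
})
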