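#' Synthetic subject profile
#'
#' Parameters of one simulated subject. FOG burden is driven by a single
#' `severity` in `[0, 1]`: episodes arrive during movement as a Poisson
#' process with rate `base_fog_rate_per_min * severity` per active minute,
#' with log-normal durations centered on `episode_mean_s`.
#'
#' @param subject_id Subject identifier.
#' @param severity FOG severity in `[0, 1]`; 0 means no freezing.
#' @param cadence_hz Stepping rate during walking, steps per second.
#' @param swing_amp_dps Peak foot swing angular velocity, deg/s.
#' @param base_fog_rate_per_min Episode rate per active minute at severity 1.
#' @param episode_mean_s Mean FOG episode duration, seconds.
#' @param episode_sigma_log Log-normal shape (sdlog) of episode durations.
#' @param trembling_fraction Share of episodes of the trembling phenotype
#'   (3–8 Hz leg oscillation); the rest are akinetic (near-motionless feet).
#' @param noise_sd_dps Additive Gaussian sensor noise per channel, deg/s.
#' @param nfogq Optional questionnaire score in `[0, 28]`; filled in by
#'   [simulate_cohort()].
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, severity,
                            cadence_hz = 1.8,
                            swing_amp_dps = 200,
                            base_fog_rate_per_min = 1.5,
                            episode_mean_s = 5,
                            episode_sigma_log = 0.5,
                            trembling_fraction = 0.7,
                            noise_sd_dps = 0.3,
                            nfogq = NA_real_) {
  stopifnot(severity >= 0, severity <= 1, cadence_hz > 0, swing_amp_dps > 0,
            base_fog_rate_per_min >= 0, episode_mean_s > 0,
            episode_sigma_log >= 0, trembling_fraction >= 0,
            trembling_fraction <= 1, noise_sd_dps >= 0)
  structure(
    list(subject_id = subject_id, severity = severity,
         cadence_hz = cadence_hz, swing_amp_dps = swing_amp_dps,
         fog_rate_per_min = base_fog_rate_per_min * severity,
         episode_mean_s = episode_mean_s,
         episode_sigma_log = episode_sigma_log,
         trembling_fraction = trembling_fraction,
         noise_sd_dps = noise_sd_dps, nfogq = nfogq),
    class = "subject_profile"
  )
}

#' Session plan
#'
#' @param segments Data frame with columns `name` (unique), `kind` (one of
#'   `walk_task`, `iadl_task`, `sitting`, `home_mixed`) and `duration_s`.
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(segments) {
  segments <- as.data.frame(segments)[c("name", "kind", "duration_s")]
  stopifnot(nrow(segments) >= 1L, all(segments$duration_s > 0),
            !anyDuplicated(segments$name),
            all(segments$kind %in% c("walk_task", "iadl_task", "sitting",
                                     "home_mixed")))
  segments$start_s <- cumsum(c(0, segments$duration_s[-nrow(segments)]))
  segments$end_s <- segments$start_s + segments$duration_s
  structure(list(segments = segments), class = "session_plan")
}

#' Default visit and home session plans
#'
#' The visit plan mirrors an in-person assessment: three clinic walking/
#' turning tasks (120 s each), then four simulated instrumental
#' activities-of-daily-living tasks — vacuuming, a dish task, navigating the
#' building (180 s each) and ten minutes of sitting in a recliner. The home
#' plan is a desk-scale stand-in for multi-day wear: three "days" of roughly
#' 30 minutes each alternating mixed household movement with sitting.
#'
#' @param home_day_min Minutes of wear simulated per home day.
#' @return List with elements `visit` and `home`, both [session_plan()]s.
#' @export
default_plans <- function(home_day_min = 30) {
  visit <- session_plan(data.frame(
    name = c("hallway_pivot", "got", "turn_360",
             "vacuum", "dish", "community", "sitting"),
    kind = c("walk_task", "walk_task", "walk_task",
             "iadl_task", "iadl_task", "iadl_task", "sitting"),
    duration_s = c(120, 120, 120, 180, 180, 180, 600)
  ))
  day_s <- home_day_min * 60
  move_s <- round(day_s * 0.35)
  sit_s <- round(day_s * 0.15)
  day <- function(d) data.frame(
    name = sprintf("day%d_%s", d, c("morning", "rest1", "midday", "rest2")),
    kind = c("home_mixed", "sitting", "home_mixed", "sitting"),
    duration_s = c(move_s, sit_s, move_s, sit_s)
  )
  home <- session_plan(do.call(rbind, lapply(1:3, day)))
  list(visit = visit, home = home)
}

#' Names of the simulated IADL tasks in the default visit plan
#' @return Character vector.
#' @export
default_iadl_tasks <- function() c("vacuum", "dish", "community", "sitting")

#' Sample a ground-truth FOG episode schedule
#'
#' Episodes arrive within each movement segment as a homogeneous Poisson
#' process at `profile$fog_rate_per_min` per minute, with log-normal
#' durations whose mean is `profile$episode_mean_s`. Episodes are clipped to
#' their segment and arrivals that begin inside an earlier episode are
#' dropped so truth intervals never overlap; the raw Poisson arrival count is
#' kept in attribute `n_arrivals`. Draws from the current RNG stream.
#'
#' @param profile A [subject_profile()].
#' @param segments Data frame of movement segments with `start_s`, `end_s`.
#' @return Data frame with `start_s`, `end_s`, `type` (`trembling` or
#'   `akinetic`), attribute `n_arrivals`.
#' @export
sample_fog_schedule <- function(profile, segments) {
  rate_per_s <- profile$fog_rate_per_min / 60
  meanlog <- log(profile$episode_mean_s) - profile$episode_sigma_log^2 / 2
  starts <- numeric(0); ends <- numeric(0)
  n_arrivals <- 0L
  if (rate_per_s > 0 && nrow(segments) > 0) {
    for (i in seq_len(nrow(segments))) {
      dur <- segments$end_s[i] - segments$start_s[i]
      n_ep <- stats::rpois(1L, rate_per_s * dur)
      n_arrivals <- n_arrivals + n_ep
      if (n_ep == 0L) next
      s <- sort(segments$start_s[i] + stats::runif(n_ep) * dur)
      d <- stats::rlnorm(n_ep, meanlog = meanlog,
                         sdlog = profile$episode_sigma_log)
      e <- pmin(s + d, segments$end_s[i])
      keep <- e > s
      starts <- c(starts, s[keep]); ends <- c(ends, e[keep])
    }
  }
  # drop arrivals starting inside an earlier episode (keeps truth disjoint)
  if (length(starts) > 1L) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    keep <- logical(length(starts)); keep[1] <- TRUE
    last_end <- ends[1]
    for (i in seq_along(starts)[-1]) {
      if (starts[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- ends[i]
      }
    }
    starts <- starts[keep]; ends <- ends[keep]
  }
  type <- if (length(starts)) {
    ifelse(stats::runif(length(starts)) < profile$trembling_fraction,
           "trembling", "akinetic")
  } else character(0)
  out <- data.frame(start_s = starts, end_s = ends, type = type)
  attr(out, "n_arrivals") <- n_arrivals
  out
}

# Baseline walking-like signals for one segment: alternating half-sine foot
# swing pulses at the stride rate, hip oscillating in a 5-20 deg/s band.
walk_signals <- function(tt, profile, amp_scale = 1) {
  stride_hz <- profile$cadence_hz / 2
  amp <- profile$swing_amp_dps * amp_scale
  swing <- function(phase_offset) {
    phi <- (tt * stride_hz + phase_offset) %% 1
    ifelse(phi < 0.4, amp * sin(pi * phi / 0.4), 0)
  }
  foot <- function(y) cbind(x = 0.15 * y, y = y, z = 0.1 * y)
  hip <- cbind(x = 8 + 5 * sin(2 * pi * stride_hz * tt),
               y = 3 * sin(2 * pi * profile$cadence_hz * tt + 1),
               z = 2 * sin(2 * pi * stride_hz * tt + 2))
  list(lf = foot(swing(0)), rf = foot(swing(0.5)), hip = hip)
}

# Sitting signals: hip at rest; occasional single-foot leg-bounce bursts
# (2 Hz, 20 deg/s) that the hip-based mask must still classify as sedentary.
sitting_signals <- function(tt, bounce_rate_per_min = 0.5) {
  n <- length(tt)
  lf <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  rf <- lf
  hip <- lf
  dur <- tt[n] - tt[1]
  n_bounce <- stats::rpois(1L, bounce_rate_per_min / 60 * dur)
  if (n_bounce > 0) {
    for (b in seq_len(n_bounce)) {
      b_start <- tt[1] + stats::runif(1) * dur
      b_len <- stats::runif(1, 5, 15)
      idx <- which(tt >= b_start & tt < b_start + b_len)
      if (!length(idx)) next
      yy <- 20 * sin(2 * pi * 2 * (tt[idx] - b_start))
      burst <- cbind(x = 0.1 * yy, y = yy, z = 0.05 * yy)
      if (stats::runif(1) < 0.5) lf[idx, ] <- lf[idx, ] + burst
      else rf[idx, ] <- rf[idx, ] + burst
    }
  }
  list(lf = lf, rf = rf, hip = hip)
}

#' Simulate one multi-sensor session
#'
#' Generates 100 Hz tri-axial gyroscope streams for both feet and the left
#' hip following a session plan, overlays ground-truth FOG episodes on
#' movement segments (trembling: 5 Hz, 25 deg/s foot oscillation; akinetic:
#' near-motionless feet; the hip stays active in both), adds Gaussian sensor
#' noise, and records exact truth intervals. Deterministic for a fixed seed.
#'
#' @param profile A [subject_profile()].
#' @param plan A [session_plan()].
#' @param seed Integer seed.
#' @param rate_hz Sampling rate (the common analysis rate).
#' @return List with [imu_recording()]s `left_foot`, `right_foot`,
#'   `left_hip`, and `truth`, an [annotation_track()] holding the fog
#'   intervals plus `task:<name>` spans for every segment. The truth track
#'   carries the episode schedule (with types) as attribute `schedule`.
#' @export
simulate_session <- function(profile, plan, seed, rate_hz = 100) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(plan, "session_plan"))
  set.seed(seed)
  seg <- plan$segments
  movement <- seg[seg$kind != "sitting", , drop = FALSE]
  schedule <- sample_fog_schedule(profile, movement)

  n_total <- sum(round(seg$duration_s * rate_hz))
  lf <- matrix(0, n_total, 3); rf <- matrix(0, n_total, 3)
  hip <- matrix(0, n_total, 3)
  pos <- 0L
  for (i in seq_len(nrow(seg))) {
    n_seg <- round(seg$duration_s[i] * rate_hz)
    tt <- seg$start_s[i] + (0:(n_seg - 1L)) / rate_hz
    sig <- switch(seg$kind[i],
      walk_task = walk_signals(tt, profile, amp_scale = 1),
      iadl_task = walk_signals(tt, profile, amp_scale = 0.8),
      home_mixed = walk_signals(tt, profile, amp_scale = 0.9),
      sitting = sitting_signals(tt)
    )
    idx <- pos + seq_len(n_seg)
    lf[idx, ] <- sig$lf; rf[idx, ] <- sig$rf; hip[idx, ] <- sig$hip
    pos <- pos + n_seg
  }

  all_t <- (0:(n_total - 1L)) / rate_hz
  if (nrow(schedule) > 0) {
    for (i in seq_len(nrow(schedule))) {
      idx <- which(all_t >= schedule$start_s[i] & all_t < schedule$end_s[i])
      if (!length(idx)) next
      if (schedule$type[i] == "trembling") {
        tau <- all_t[idx] - schedule$start_s[i]
        yy <- 25 * sin(2 * pi * 5 * tau)
        ep <- cbind(0.2 * yy, yy, 0.1 * yy)
        lf[idx, ] <- ep
        rf[idx, ] <- ep
      } else {
        lf[idx, ] <- 0
        rf[idx, ] <- 0
      }
    }
  }

  sdn <- profile$noise_sd_dps
  if (sdn > 0) {
    lf <- lf + matrix(stats::rnorm(3 * n_total, sd = sdn), n_total, 3)
    rf <- rf + matrix(stats::rnorm(3 * n_total, sd = sdn), n_total, 3)
    hip <- hip + matrix(stats::rnorm(3 * n_total, sd = sdn), n_total, 3)
  }

  intervals <- rbind(
    if (nrow(schedule) > 0) {
      data.frame(start_s = schedule$start_s, end_s = schedule$end_s,
                 label = "fog")
    },
    data.frame(start_s = seg$start_s, end_s = seg$end_s,
               label = paste0("task:", seg$name))
  )
  truth <- annotation_track(profile$subject_id, intervals)
  attr(truth, "schedule") <- schedule

  list(
    left_foot = imu_recording(profile$subject_id, "left_foot", rate_hz, 0, lf),
    right_foot = imu_recording(profile$subject_id, "right_foot", rate_hz, 0, rf),
    left_hip = imu_recording(profile$subject_id, "left_hip", rate_hz, 0, hip),
    truth = truth
  )
}

#' Emulate an imperfect expert video rater
#'
#' Perturbs every ground-truth FOG boundary with Gaussian jitter (clipped so
#' each episode keeps `start < end` and non-negative times), drops episodes
#' shorter than the rater's minimum perceptible duration, and re-normalizes.
#' Task spans are passed through unchanged.
#'
#' @param truth An [annotation_track()] with ground-truth fog intervals.
#' @param jitter_sd_s Boundary jitter standard deviation, seconds.
#' @param min_episode_s Minimum episode duration the rater reports, seconds.
#' @param seed Integer seed.
#' @return An [annotation_track()].
#' @export
emulate_rater <- function(truth, jitter_sd_s = 0.2, min_episode_s = 0.5,
                          seed) {
  stopifnot(inherits(truth, "annotation_track"))
  set.seed(seed)
  fog <- fog_intervals(truth)
  if (nrow(fog) > 0) {
    s <- pmax(0, fog$start_s + stats::rnorm(nrow(fog), sd = jitter_sd_s))
    e <- fog$end_s + stats::rnorm(nrow(fog), sd = jitter_sd_s)
    e <- pmax(e, s + 1e-3)
    keep <- (e - s) >= min_episode_s
    fog <- data.frame(start_s = s[keep], end_s = e[keep])
  }
  other <- truth$intervals[truth$intervals$label != "fog", , drop = FALSE]
  intervals <- rbind(
    if (nrow(fog) > 0) cbind(fog, label = "fog"),
    other
  )
  if (is.null(intervals)) {
    intervals <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            label = character(0))
  }
  annotation_track(truth$subject_id, intervals)
}

#' Simulate a full synthetic cohort
#'
#' Generates `n` subjects with severities spread over `[0, 1]` — the two
#' lowest at exactly 0, so the cohort contains subjects with no freezing at
#' all — along with a noise-dominated questionnaire score, visit (and
#' optionally home) sessions, and rater-emulated visit annotations. All
#' randomness derives from `seed` plus fixed per-subject/per-stream offsets,
#' so every artifact is replayable in isolation.
#'
#' @param n Number of subjects (at least 3).
#' @param seed Integer seed.
#' @param sessions Which sessions to generate: subset of
#'   `c("visit", "home")`.
#' @param plans List with `visit`/`home` [session_plan()]s.
#' @param out_dir Optional directory; when given, the cohort file tree
#'   (per-subject IMU and annotation CSVs plus `subjects.csv`) is written.
#' @param nfogq_severity_weight Weight of true severity in the questionnaire
#'   score (the remainder is uniform noise).
#' @return An object of class `fog_cohort`: list with `subjects` (data frame
#'   of `subject_id`, `severity`, `nfogq`, `true_atsf_visit`), `sessions`
#'   (per-subject list with `visit`, `rater`, `home`), `plans`, `seed`.
#' @export
simulate_cohort <- function(n = 19, seed = 1,
                            sessions = c("visit", "home"),
                            plans = default_plans(),
                            out_dir = NULL,
                            nfogq_severity_weight = 0.3) {
  stopifnot(n >= 3)
  sessions <- match.arg(sessions, several.ok = TRUE)
  severities <- c(0, 0, seq_len(n - 2) / (n - 2))
  subj_ids <- sprintf("S%02d", seq_len(n))
  move_s <- with(plans$visit$segments,
                 sum(duration_s[kind != "sitting"]))
  rows <- list()
  out_sessions <- list()
  for (i in seq_len(n)) {
    set.seed(seed + 200000 + i)
    u <- stats::runif(1)
    nfogq <- min(28, max(0, round(28 * (nfogq_severity_weight * severities[i] +
                                          (1 - nfogq_severity_weight) * u))))
    prof <- subject_profile(subj_ids[i], severities[i], nfogq = nfogq)
    subj <- list()
    true_atsf <- NA_real_
    if ("visit" %in% sessions) {
      subj$visit <- simulate_session(prof, plans$visit, seed = seed + i)
      subj$rater <- emulate_rater(subj$visit$truth,
                                  seed = seed + 100000 + i)
      fog <- fog_intervals(subj$visit$truth)
      true_atsf <- 100 * sum(fog$end_s - fog$start_s) / move_s
    }
    if ("home" %in% sessions) {
      subj$home <- simulate_session(prof, plans$home, seed = seed + 300000 + i)
    }
    subj$profile <- prof
    out_sessions[[subj_ids[i]]] <- subj
    rows[[i]] <- data.frame(subject_id = subj_ids[i],
                            severity = severities[i], nfogq = nfogq,
                            true_atsf_visit = true_atsf)
  }
  cohort <- structure(
    list(subjects = do.call(rbind, rows), sessions = out_sessions,
         plans = plans, seed = seed),
    class = "fog_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.fog_cohort <- function(x, ...) {
  cat(sprintf("<fog_cohort> %d subjects (seed %g)\n", nrow(x$subjects),
              x$seed))
  cat(sprintf("  severities %.2f-%.2f; sessions: %s\n",
              min(x$subjects$severity), max(x$subjects$severity),
              paste(setdiff(names(x$sessions[[1]]), "profile"),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort file tree
#'
#' Lays out one directory per subject with `visit/` (three sensor CSVs plus
#' `truth.csv` and `rater.csv`) and `home/` (sensor CSVs), plus a top-level
#' `subjects.csv`.
#'
#' @param cohort A `fog_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "fog_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$subjects, file.path(out_dir, "subjects.csv"))
  for (sid in names(cohort$sessions)) {
    subj <- cohort$sessions[[sid]]
    if (!is.null(subj$visit)) {
      vdir <- file.path(out_dir, sid, "visit")
      dir.create(vdir, showWarnings = FALSE, recursive = TRUE)
      for (site in imu_sites()) {
        write_imu(subj$visit[[site]], file.path(vdir, paste0(site, ".csv")))
      }
      write_annotations(subj$visit$truth, file.path(vdir, "truth.csv"))
      write_annotations(subj$rater, file.path(vdir, "rater.csv"))
    }
    if (!is.null(subj$home)) {
      hdir <- file.path(out_dir, sid, "home")
      dir.create(hdir, showWarnings = FALSE, recursive = TRUE)
      for (site in imu_sites()) {
        write_imu(subj$home[[site]], file.path(hdir, paste0(site, ".csv")))
      }
    }
  }
  invisible(out_dir)
}
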