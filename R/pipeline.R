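#' Pipeline configuration
#'
#' Houses every analysis constant of the end-to-end pipeline: the common
#' analysis rate, the FOG probability threshold applied per foot, the event
#' merge gap, the sedentary-exclusion threshold and smoothing window, and the
#' detector configuration.
#'
#' @param target_rate_hz Common analysis sampling rate, samples per second.
#' @param pfog_threshold Per-foot FOG probability threshold.
#' @param merge_gap_s Events separated by less than this many seconds are
#'   merged.
#' @param activity_threshold_dps Sedentary threshold on smoothed total hip
#'   angular speed, deg/s.
#' @param activity_window_s Centered moving-average window for the activity
#'   mask, seconds.
#' @param detector A [detector_config()].
#' @param iadl_tasks Task names treated as the simulated-IADL subset when
#'   reporting IADL-only metrics.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_rate_hz = 100,
                            pfog_threshold = 0.7,
                            merge_gap_s = 2.0,
                            activity_threshold_dps = 1.0,
                            activity_window_s = 20,
                            detector = detector_config(),
                            iadl_tasks = default_iadl_tasks()) {
  stopifnot(target_rate_hz > 0, pfog_threshold > 0, pfog_threshold < 1,
            merge_gap_s >= 0, activity_threshold_dps > 0,
            activity_window_s > 0, inherits(detector, "detector_config"))
  structure(
    list(target_rate_hz = target_rate_hz, pfog_threshold = pfog_threshold,
         merge_gap_s = merge_gap_s,
         activity_threshold_dps = activity_threshold_dps,
         activity_window_s = activity_window_s, detector = detector,
         iadl_tasks = iadl_tasks),
    class = "pipeline_config"
  )
}

read_session_dir <- function(dir) {
  recs <- lapply(imu_sites(), function(site) {
    path <- file.path(dir, paste0(site, ".csv"))
    if (!file.exists(path)) {
      stop("input error: missing recording ", path, call. = FALSE)
    }
    read_imu(path)
  })
  names(recs) <- imu_sites()
  rater_path <- file.path(dir, "rater.csv")
  recs$rater <- if (file.exists(rater_path)) read_annotations(rater_path)
  recs
}

# Shared detection front end: resample to the analysis rate, build the
# activity mask from the hip, run the two-stage detector on both feet,
# threshold, convert to events and merge. Returns everything downstream
# scoring needs.
detect_session <- function(left, right, hip, cfg) {
  left <- resample_sinc(left, cfg$target_rate_hz)
  right <- resample_sinc(right, cfg$target_rate_hz)
  hip <- resample_sinc(hip, cfg$target_rate_hz)
  n <- min(n_samples(left), n_samples(right), n_samples(hip))
  mask <- compute_activity_mask(hip, cfg$activity_threshold_dps,
                                cfg$activity_window_s)
  mask$flags <- mask$flags[seq_len(n)]
  p_left <- detect_foot(left, cfg$detector)
  p_right <- detect_foot(right, cfg$detector)
  p_left$p <- p_left$p[seq_len(n)]
  p_right$p <- p_right$p[seq_len(n)]
  raw_flags <- combine_feet(p_left, p_right, cfg$pfog_threshold)
  events <- merge_events(series_to_events(raw_flags, cfg$target_rate_hz,
                                          left$t0_s),
                         cfg$merge_gap_s)
  sensor <- rasterize(events, cfg$target_rate_hz, left$t0_s, n)
  list(n = n, rate_hz = cfg$target_rate_hz, t0_s = left$t0_s, mask = mask,
       p_left = p_left, p_right = p_right, events = events, sensor = sensor)
}

#' Score one in-person visit
#'
#' Runs the full visit pipeline for one subject: resampling to the analysis
#' rate, hip-based sedentary exclusion, per-foot detection, either-foot
#' thresholding, event merging, and sample-wise scoring against the rater's
#' annotations — restricted to samples inside task intervals, since only task
#' time is analyzed for the visit. Metrics are reported for the whole visit,
#' for the IADL subset, and per task.
#'
#' @param x Either a subject visit directory (containing `left_foot.csv`,
#'   `right_foot.csv`, `left_hip.csv` and `rater.csv`) or an in-memory
#'   session list with those recordings; in the latter case `rater` must be
#'   supplied (or present as `x$rater`).
#' @param cfg A [pipeline_config()].
#' @param rater Optional [annotation_track()] with the video-rated fog
#'   intervals and `task:` spans (overrides any found in `x`).
#' @return An object of class `score_report`.
#' @export
run_visit <- function(x, cfg = pipeline_config(), rater = NULL) {
  if (is.character(x)) x <- read_session_dir(x)
  rater <- rater %||% x$rater
  if (is.null(rater)) {
    stop("input error: no rater annotations provided", call. = FALSE)
  }
  det <- detect_session(x$left_foot, x$right_foot, x$left_hip, cfg)
  n <- det$n
  video <- rasterize(rater, det$rate_hz, det$t0_s, n)
  tasks_iv <- task_intervals(rater)
  if (nrow(tasks_iv) == 0L) {
    stop("input error: rater track carries no task spans", call. = FALSE)
  }
  in_task <- rasterize(tasks_iv, det$rate_hz, det$t0_s, n)
  in_iadl <- rasterize(tasks_iv[tasks_iv$task %in% cfg$iadl_tasks, ,
                                drop = FALSE],
                       det$rate_hz, det$t0_s, n)
  sel_visit <- in_task & det$mask$flags
  sel_iadl <- in_iadl & det$mask$flags
  cc <- confusion(det$sensor, video, sel_visit)
  cc_iadl <- if (sum(sel_iadl) > 0) confusion(det$sensor, video, sel_iadl)
  report <- list(
    subject_id = x$left_foot$subject_id,
    n_samples = sum(in_task),
    n_active = sum(sel_visit),
    confusion = cc,
    accuracy_pct = accuracy_pct(cc),
    sensitivity_pct = sensitivity_pct(cc),
    specificity_pct = specificity_pct(cc),
    sensor_atsf_pct = atsf_pct(det$sensor, sel_visit),
    video_atsf_pct = atsf_pct(video, sel_visit),
    accuracy_iadl_pct = if (!is.null(cc_iadl)) accuracy_pct(cc_iadl)
                        else NA_real_,
    sensor_atsf_iadl_pct = if (sum(sel_iadl) > 0)
      atsf_pct(det$sensor, sel_iadl) else NA_real_,
    video_atsf_iadl_pct = if (sum(sel_iadl) > 0)
      atsf_pct(video, sel_iadl) else NA_real_,
    mean_episode_s = if (nrow(det$events) > 0)
      mean_episode_duration(det$events) else NA_real_,
    n_events = nrow(det$events),
    events = det$events,
    per_task = per_task_scores(det$sensor, video, det$mask, rater),
    config = cfg
  )
  class(report) <- "score_report"
  report
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> subject %s\n", x$subject_id))
  cat(sprintf("  visit accuracy %.2f%% (sens %.1f%%, spec %.1f%%) over %d active samples\n",
              x$accuracy_pct, x$sensitivity_pct, x$specificity_pct,
              x$n_active))
  cat(sprintf("  %%ATSF sensor %.2f / video %.2f (visit); sensor %.2f / video %.2f (IADL)\n",
              x$sensor_atsf_pct, x$video_atsf_pct, x$sensor_atsf_iadl_pct,
              x$video_atsf_iadl_pct))
  cat(sprintf("  %d merged FOG event(s), mean duration %.2f s\n",
              x$n_events, x$mean_episode_s))
  invisible(x)
}

#' Sensor-based %ATSF for unsupervised home wear
#'
#' Runs detection on the home recordings (no annotations exist at home) and
#' pools FOG and active time over the whole recording after sedentary
#' exclusion.
#'
#' @param x A home session directory (three sensor CSVs) or an in-memory
#'   session list.
#' @param cfg A [pipeline_config()].
#' @return List with `sensor_atsf_home_pct`, `active_s`, `fog_s`,
#'   `n_events`.
#' @export
run_home <- function(x, cfg = pipeline_config()) {
  if (is.character(x)) x <- read_session_dir(x)
  det <- detect_session(x$left_foot, x$right_foot, x$left_hip, cfg)
  n_active <- sum(det$mask$flags)
  if (n_active == 0) {
    stop("undefined metric: no active time in home recording", call. = FALSE)
  }
  fog_active <- sum(det$sensor & det$mask$flags)
  list(sensor_atsf_home_pct = 100 * fog_active / n_active,
       active_s = n_active / det$rate_hz,
       fog_s = fog_active / det$rate_hz,
       n_events = nrow(det$events))
}

#' Run the cohort-level analysis
#'
#' Processes every subject's visit (and home session when present), builds
#' the cohort table of questionnaire and %ATSF measures, checks each column
#' for normality, and computes the two Spearman correlation matrices
#' (visit-level and IADL-level). Subjects whose processing fails become
#' missing rows with a warning rather than aborting the cohort.
#'
#' @param x A `fog_cohort` from [simulate_cohort()], or a root directory laid
#'   out as written by [write_cohort()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory for CSV outputs (`cohort_table.csv`,
#'   `accuracy_summary.csv`, `atsf_summary.csv`, `corr_visit.csv`,
#'   `corr_iadl.csv`).
#' @return List with `cohort_table`, `reports`, `corr_visit`, `corr_iadl`,
#'   `normality`, `accuracy_summary`, `atsf_summary`.
#' @export
run_cohort <- function(x, cfg = pipeline_config(), out_dir = NULL) {
  subjects <- if (inherits(x, "fog_cohort")) {
    names(x$sessions)
  } else {
    dirs <- list.dirs(x, recursive = FALSE)
    basename(dirs)[file.exists(file.path(dirs, "visit", "left_foot.csv"))]
  }
  if (length(subjects) < 3L) {
    stop("input error: need at least 3 processed subjects", call. = FALSE)
  }
  nfogq_lookup <- if (inherits(x, "fog_cohort")) {
    stats::setNames(x$subjects$nfogq, x$subjects$subject_id)
  } else {
    sf <- file.path(x, "subjects.csv")
    if (file.exists(sf)) {
      st <- data.table::fread(sf, data.table = FALSE)
      stats::setNames(st$nfogq, st$subject_id)
    }
  }
  reports <- list()
  rows <- list()
  for (sid in subjects) {
    row <- data.frame(subject_id = sid, nfogq = NA_real_,
                      sensor_atsf_visit = NA_real_,
                      video_atsf_visit = NA_real_,
                      sensor_atsf_iadl = NA_real_,
                      video_atsf_iadl = NA_real_,
                      sensor_atsf_home = NA_real_,
                      accuracy_visit = NA_real_, accuracy_iadl = NA_real_)
    res <- tryCatch({
      if (inherits(x, "fog_cohort")) {
        subj <- x$sessions[[sid]]
        rep_v <- run_visit(subj$visit, cfg, rater = subj$rater)
        home <- if (!is.null(subj$home)) run_home(subj$home, cfg)
      } else {
        rep_v <- run_visit(file.path(x, sid, "visit"), cfg)
        hdir <- file.path(x, sid, "home")
        home <- if (file.exists(file.path(hdir, "left_foot.csv")))
          run_home(hdir, cfg)
      }
      list(rep_v = rep_v, home = home)
    }, error = function(e) {
      warning("subject ", sid, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      reports[[sid]] <- res$rep_v
      row$sensor_atsf_visit <- res$rep_v$sensor_atsf_pct
      row$video_atsf_visit <- res$rep_v$video_atsf_pct
      row$sensor_atsf_iadl <- res$rep_v$sensor_atsf_iadl_pct
      row$video_atsf_iadl <- res$rep_v$video_atsf_iadl_pct
      row$accuracy_visit <- res$rep_v$accuracy_pct
      row$accuracy_iadl <- res$rep_v$accuracy_iadl_pct
      if (!is.null(res$home)) {
        row$sensor_atsf_home <- res$home$sensor_atsf_home_pct
      }
    }
    if (!is.null(nfogq_lookup) && sid %in% names(nfogq_lookup)) {
      row$nfogq <- nfogq_lookup[[sid]]
    }
    rows[[sid]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  visit_cols <- c("nfogq", "sensor_atsf_visit", "video_atsf_visit",
                  "sensor_atsf_home")
  iadl_cols <- c("nfogq", "sensor_atsf_iadl", "video_atsf_iadl",
                 "sensor_atsf_home")
  have <- function(cols) cols[colSums(is.finite(as.matrix(tab[cols]))) >= 3]
  corr_visit <- correlation_matrix(tab, have(visit_cols))
  corr_iadl <- correlation_matrix(tab, have(iadl_cols))
  mean_sd <- function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  acc_cols <- c("accuracy_iadl", "accuracy_visit")
  accuracy_summary <- data.frame(
    measure = acc_cols,
    t(vapply(acc_cols, function(cl) mean_sd(tab[[cl]]), numeric(3)))
  )
  atsf_cols <- c("sensor_atsf_visit", "sensor_atsf_iadl", "sensor_atsf_home",
                 "video_atsf_visit", "video_atsf_iadl")
  atsf_summary <- data.frame(
    measure = atsf_cols,
    t(vapply(atsf_cols, function(cl) mean_sd(tab[[cl]]), numeric(3)))
  )
  rownames(accuracy_summary) <- rownames(atsf_summary) <- NULL
  out <- list(cohort_table = tab, reports = reports,
              corr_visit = corr_visit, corr_iadl = corr_iadl,
              normality = normality_report(tab, setdiff(names(tab),
                                                        "subject_id")),
              accuracy_summary = accuracy_summary,
              atsf_summary = atsf_summary, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(tab, file.path(out_dir, "cohort_table.csv"))
    data.table::fwrite(accuracy_summary,
                       file.path(out_dir, "accuracy_summary.csv"))
    data.table::fwrite(atsf_summary, file.path(out_dir, "atsf_summary.csv"))
    utils::write.csv(corr_visit, file.path(out_dir, "corr_visit.csv"))
    utils::write.csv(corr_iadl, file.path(out_dir, "corr_iadl.csv"))
    jsonlite::write_json(
      list(config = unclass(cfg), package_version =
             as.character(utils::packageVersion("fogatsf"))),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE
    )
  }
  out
}
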