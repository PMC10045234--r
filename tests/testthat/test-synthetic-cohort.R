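test_that("default plans match the intended session structure", {
  plans <- default_plans()
  seg <- plans$visit$segments
  expect_equal(nrow(seg), 7L)
  expect_equal(seg$duration_s[seg$name == "sitting"], 600)
  expect_equal(sum(seg$kind == "walk_task"), 3L)
  expect_equal(sum(seg$kind == "iadl_task"), 3L)
  home <- plans$home$segments
  expect_equal(sum(home$duration_s), 3 * sum(home$duration_s[1:4]))
})

test_that("sessions are deterministic and severity 0 yields no freezing", {
  prof0 <- subject_profile("S00", severity = 0)
  plan <- session_plan(data.frame(name = "walk", kind = "walk_task",
                                  duration_s = 60))
  ses <- simulate_session(prof0, plan, seed = 71)
  expect_equal(nrow(fog_intervals(ses$truth)), 0L)

  prof1 <- subject_profile("S01", severity = 0.8)
  a <- simulate_session(prof1, plan, seed = 72)
  b <- simulate_session(prof1, plan, seed = 72)
  expect_identical(a, b)
  c <- simulate_session(prof1, plan, seed = 73)
  expect_false(identical(a$left_foot$gyro, c$left_foot$gyro))
})

test_that("episode arrivals follow the Poisson expectation", {
  prof <- subject_profile("S01", severity = 1)
  seg <- data.frame(start_s = 0, end_s = 600)
  counts <- vapply(1:200, function(r) {
    set.seed(7400 + r)
    attr(sample_fog_schedule(prof, seg), "n_arrivals")
  }, integer(1))
  expected <- 1.5 / 60 * 600
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("generated episode durations center on the 5 s mean", {
  prof <- subject_profile("S01", severity = 1)
  seg <- data.frame(start_s = 0, end_s = 400000)
  set.seed(75)
  sch <- sample_fog_schedule(prof, seg)
  durs <- sch$end_s - sch$start_s
  expect_gt(length(durs), 1000)
  expect_lt(abs(mean(durs) - 5) / 5, 0.05)
})

test_that("truth intervals are disjoint and avoid sitting segments", {
  prof <- subject_profile("S01", severity = 1)
  plans <- default_plans()
  ses <- simulate_session(prof, plans$visit, seed = 76)
  fog <- fog_intervals(ses$truth)
  expect_gt(nrow(fog), 0)
  expect_true(all(fog$start_s[-1] >= fog$end_s[-nrow(fog)]))
  sit <- plans$visit$segments[plans$visit$segments$kind == "sitting", ]
  overlap <- pmin(fog$end_s, sit$end_s) - pmax(fog$start_s, sit$start_s)
  expect_true(all(overlap <= 0))
})

test_that("segment spectra land in the expected bands", {
  prof <- subject_profile("S01", severity = 1, trembling_fraction = 1)
  plan <- session_plan(data.frame(name = "walk", kind = "walk_task",
                                  duration_s = 300))
  ses <- simulate_session(prof, plan, seed = 77)
  tt <- sample_times(ses$left_foot)
  sch <- attr(ses$truth, "schedule")
  in_fog <- oracle_rasterize(sch, 100, 0, length(tt))

  peak_freq <- function(x) {
    sp <- stats::spec.pgram(x - mean(x), taper = 0, plot = FALSE)
    sp$freq[which.max(sp$spec)] * 100
  }
  # a clean contiguous walking stretch: peak in the locomotor band
  r <- rle(!in_fog)
  ends <- cumsum(r$lengths)
  pick <- which(r$values & r$lengths >= 1500)[1]
  run <- (ends[pick] - r$lengths[pick] + 300):(ends[pick] - 200)
  expect_true(peak_freq(ses$left_foot$gyro[run, 2]) >= 0.5 &&
                peak_freq(ses$left_foot$gyro[run, 2]) < 3)
  # interior of a long trembling episode: peak in the freeze band
  long <- sch[sch$end_s - sch$start_s >= 3, ][1, ]
  idx <- which(tt >= long$start_s + 0.5 & tt < long$end_s - 0.5)
  pf <- peak_freq(ses$left_foot$gyro[idx, 2])
  expect_true(pf >= 3 && pf <= 8)
})

test_that("rater emulation jitters, drops short episodes, and replays", {
  truth <- annotation_track("S01", data.frame(
    start_s = c(10, 30, 50), end_s = c(15, 30.3, 58), label = "fog"))

  ident <- emulate_rater(truth, jitter_sd_s = 0, min_episode_s = 0, seed = 81)
  expect_equal(fog_intervals(ident), fog_intervals(truth))

  dropped <- emulate_rater(truth, jitter_sd_s = 0, min_episode_s = 0.5,
                           seed = 81)
  expect_equal(nrow(fog_intervals(dropped)), 2L)

  jit <- emulate_rater(truth, jitter_sd_s = 0.2, min_episode_s = 0.5,
                       seed = 82)
  set.seed(82)
  fog <- fog_intervals(truth)
  s <- pmax(0, fog$start_s + rnorm(3, sd = 0.2))
  e <- pmax(fog$end_s + rnorm(3, sd = 0.2), s + 1e-3)
  keep <- (e - s) >= 0.5
  expect_equal(fog_intervals(jit),
               data.frame(start_s = s[keep], end_s = e[keep]))
})

test_that("cohorts are reproducible with zero-severity subjects included", {
  plans <- list(visit = session_plan(data.frame(
    name = c("walk", "vac", "sit"),
    kind = c("walk_task", "iadl_task", "sitting"),
    duration_s = c(60, 60, 120))))
  co <- simulate_cohort(n = 5, seed = 9, sessions = "visit", plans = plans)
  expect_equal(nrow(co$subjects), 5L)
  expect_equal(co$subjects$severity[1:2], c(0, 0))
  expect_true(all(co$subjects$nfogq >= 0 & co$subjects$nfogq <= 28))
  for (sid in co$subjects$subject_id[1:2]) {
    expect_equal(nrow(fog_intervals(co$sessions[[sid]]$visit$truth)), 0L)
  }
  co2 <- simulate_cohort(n = 5, seed = 9, sessions = "visit", plans = plans)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(co$sessions$S05$visit$left_foot$gyro,
                   co2$sessions$S05$visit$left_foot$gyro)
})

test_that("the written cohort tree feeds the file-based pipeline", {
  plans <- list(
    visit = session_plan(data.frame(
      name = c("walk", "vac", "sit"),
      kind = c("walk_task", "iadl_task", "sitting"),
      duration_s = c(60, 60, 90))),
    home = session_plan(data.frame(
      name = c("move", "rest"), kind = c("home_mixed", "sitting"),
      duration_s = c(90, 60))))
  root <- withr::local_tempdir()
  co <- simulate_cohort(n = 3, seed = 10, plans = plans, out_dir = root)
  expect_true(file.exists(file.path(root, "subjects.csv")))
  expect_true(file.exists(file.path(root, "S03", "visit", "left_foot.csv")))
  expect_true(file.exists(file.path(root, "S03", "home", "left_hip.csv")))
  back <- read_imu(file.path(root, "S03", "visit", "left_foot.csv"))
  expect_lt(max(abs(back$gyro - co$sessions$S03$visit$left_foot$gyro)), 1e-9)
  rater <- read_annotations(file.path(root, "S03", "visit", "rater.csv"))
  expect_equal(fog_intervals(rater), fog_intervals(co$sessions$S03$rater))
})
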