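test_that("zero-velocity flags match a brute-force windowed RMS", {
  cfg <- detector_config()
  still <- foot_rec(matrix(0, 200, 3))
  expect_true(all(zero_velocity_flags(still, cfg)))

  fast <- foot_rec(cbind(rep(100, 200), 0, 0))
  expect_false(any(zero_velocity_flags(fast, cfg)))

  set.seed(31)
  rec <- foot_rec(matrix(rnorm(600, sd = 15), 200, 3))
  mag <- sqrt(rowSums(rec$gyro^2))
  expect_identical(zero_velocity_flags(rec, cfg),
                   oracle_window_rms(mag, cfg$zv_window_s, 100) <
                     cfg$zv_rms_dps)

  expect_error(zero_velocity_flags(foot_rec(matrix(0, 10, 3)), cfg),
               "window longer")
})

test_that("trembling flags fire for 5 Hz tremor but not 1 Hz stepping", {
  cfg <- detector_config()
  tremor <- sine_foot(5, 30, dur_s = 10)
  fl <- trembling_flags(tremor, cfg)
  interior <- 200:800
  expect_true(all(fl[interior]))

  stepping <- sine_foot(1, 30, dur_s = 10)
  expect_false(any(trembling_flags(stepping, cfg)))

  still <- foot_rec(matrix(0, 1000, 3))
  expect_false(any(trembling_flags(still, cfg)))
})

test_that("sliding band power agrees with a direct windowed DFT", {
  set.seed(32)
  rate <- 100
  w <- 2L * floor(2.0 * rate / 2) + 1L
  x <- rnorm(600) + 20 * sin(2 * pi * 5 * (0:599) / rate)
  freqs <- (1:(w - 1)) * rate / w
  freeze_ms <- which(freqs >= 3 & freqs <= 8)
  bp <- fogatsf:::sliding_band_power(x, rate, w,
                                     bands = list(freeze = c(3, 8),
                                                  loco = c(0.5, 3)))
  for (k in c(101, 250, 417, 499)) {
    expect_equal(bp$freeze[k], oracle_band_power(x, k, w, freeze_ms),
                 tolerance = 1e-9)
  }
})

test_that("forward filter reproduces hand-checked and enumerated posteriors", {
  cfg <- detector_config()

  # uninformative emissions: posterior relaxes to the stationary 0.5
  flat <- detector_config(emit = matrix(0.25, 2, 4))
  tr <- pfog_forward_filter(rep(TRUE, 1000), rep(FALSE, 1000), flat)
  expect_lt(abs(tr$p[1000] - 0.5), 1e-6)

  # three-step hand computation with the default emissions,
  # observations (0,0), (1,1), (1,1)
  e <- cfg$emit; a <- cfg$persist; p0 <- cfg$prior_fog
  p1 <- p0 * e[2, 1] / (p0 * e[2, 1] + (1 - p0) * e[1, 1])
  pp <- a * p1 + (1 - a) * (1 - p1)
  p2 <- pp * e[2, 4] / (pp * e[2, 4] + (1 - pp) * e[1, 4])
  pp <- a * p2 + (1 - a) * (1 - p2)
  p3 <- pp * e[2, 4] / (pp * e[2, 4] + (1 - pp) * e[1, 4])
  tr3 <- pfog_forward_filter(c(FALSE, TRUE, TRUE), c(FALSE, TRUE, TRUE), cfg)
  expect_equal(tr3$p, c(p1, p2, p3), tolerance = 1e-12)

  # sustained strongly FOG-likely evidence (likelihood ratio 9:1) saturates
  strong <- detector_config(emit = matrix(
    c(0.1, 0.3, 0.3, 0.3,
      0.9, 1 / 30, 1 / 30, 1 / 30), 2, 4, byrow = TRUE))
  tr9 <- pfog_forward_filter(rep(FALSE, 500), rep(FALSE, 500), strong)
  expect_gt(tr9$p[500], 0.99)

  # random strings against the exhaustive path-enumeration oracle
  set.seed(33)
  for (rep in 1:5) {
    zv <- runif(6) < 0.5; tp <- runif(6) < 0.5
    obs <- 1L + as.integer(zv) + 2L * as.integer(tp)
    expect_equal(pfog_forward_filter(zv, tp, cfg)$p,
                 oracle_hmm_forward(obs, cfg$emit, cfg$persist,
                                    cfg$prior_fog),
                 tolerance = 1e-12)
  }

  expect_error(pfog_forward_filter(c(TRUE, FALSE), TRUE, cfg), "length")
})

test_that("probability traces stay normalized probabilities", {
  cfg <- detector_config()
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    tr <- pfog_forward_filter(runif(n) < 0.5, runif(n) < 0.3, cfg)
    expect_true(all(tr$p >= 0 & tr$p <= 1))
    expect_true(all(is.finite(tr$p)))
  }
})

test_that("either-foot combination is strict, symmetric and clock-checked", {
  l <- probability_trace(100, 0, c(0.8, 0.7, 0.0))
  r <- probability_trace(100, 0, c(0.1, 0.7, 0.0))
  expect_identical(combine_feet(l, r, 0.7), c(TRUE, FALSE, FALSE))
  expect_identical(combine_feet(l, r, 0.7), combine_feet(r, l, 0.7))
  bad <- probability_trace(100, 5, c(0.1, 0.2, 0.3))
  expect_error(combine_feet(l, bad, 0.7), "clock")
})

test_that("supra-threshold pFOG covers injected trembling episodes", {
  prof <- subject_profile("S01", severity = 1, trembling_fraction = 1)
  plan <- session_plan(data.frame(name = "walk", kind = "walk_task",
                                  duration_s = 600))
  ses <- simulate_session(prof, plan, seed = 44)
  cfg <- pipeline_config()
  p_l <- detect_foot(ses$left_foot, cfg$detector)
  p_r <- detect_foot(ses$right_foot, cfg$detector)
  flags <- combine_feet(p_l, p_r, cfg$pfog_threshold)
  tt <- sample_times(ses$left_foot)
  sch <- attr(ses$truth, "schedule")
  long <- sch[sch$end_s - sch$start_s >= 3, ]
  expect_gt(nrow(long), 3)
  covered <- 0; total <- 0
  for (i in seq_len(nrow(long))) {
    idx <- which(tt >= long$start_s[i] & tt < long$end_s[i])
    covered <- covered + sum(flags[idx]); total <- total + length(idx)
  }
  expect_gt(covered / total, 0.8)
})
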