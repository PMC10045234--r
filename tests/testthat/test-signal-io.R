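test_that("IMU CSV round-trips recordings within 1e-9", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(5:80, 1)
    rec <- imu_recording(
      subject_id = sprintf("S%02d", rep), site = sample(c(
        "left_foot", "right_foot", "left_hip"), 1),
      rate_hz = sample(c(100, 128), 1), t0_s = runif(1, 0, 10),
      gyro = matrix(rnorm(3 * n, sd = 200), n, 3),
      accel = if (rep %% 2 == 0) matrix(rnorm(3 * n), n, 3)
    )
    path <- withr::local_tempfile(fileext = ".csv")
    write_imu(rec, path)
    back <- read_imu(path)
    expect_equal(back$subject_id, rec$subject_id)
    expect_equal(back$site, rec$site)
    expect_equal(back$rate_hz, rec$rate_hz, tolerance = 1e-9)
    expect_lt(abs(back$t0_s - rec$t0_s), 1e-9)
    expect_lt(max(abs(back$gyro - rec$gyro)), 1e-9)
    if (is.null(rec$accel)) expect_null(back$accel)
    else expect_lt(max(abs(back$accel - rec$accel)), 1e-9)
  }
})

test_that("read_imu validates structure and timestamps", {
  # no sidecar lines: subject/site from the file name, rate from timestamps
  dir <- withr::local_tempdir()
  path <- file.path(dir, "T9_left_foot.csv")
  writeLines(c("time_s,gyro_x,gyro_y,gyro_z",
               "0,1,2,3", "0.01,4,5,6", "0.02,7,8,9"), path)
  rec <- read_imu(path)
  expect_equal(nrow(rec$gyro), 3L)
  expect_equal(rec$rate_hz, 100, tolerance = 1e-6)
  expect_equal(rec$gyro[2, ], c(x = 4, y = 5, z = 6))
  expect_equal(rec$subject_id, "T9")
  expect_equal(rec$site, "left_foot")

  writeLines(c("time_s,gyro_x,gyro_y", "0,1,2"), path)
  expect_error(read_imu(path), "missing required column")

  writeLines(c("time_s,gyro_x,gyro_y,gyro_z",
               "0,1,1,1", "0.01,1,1,1", "0.05,1,1,1"), path)
  expect_error(read_imu(path), "non-uniform")

  writeLines(c("time_s,gyro_x,gyro_y,gyro_z",
               "0.02,1,1,1", "0.01,1,1,1"), path)
  expect_error(read_imu(path), "non-monotonic")
})

test_that("write_imu omits accel columns when the stream is absent", {
  rec <- foot_rec(matrix(1:3, 1, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu(rec, path)
  lines <- readLines(path)
  header <- grep("^time_s", lines, value = TRUE)
  expect_equal(header, "time_s,gyro_x,gyro_y,gyro_z")
  expect_equal(length(lines) - length(grep("^#", lines)), 2L)
})

test_that("annotation files normalize fog intervals and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start_s,end_s,label", "1.0,2.0,fog", "1.5,3.0,fog"), path)
  track <- read_annotations(path)
  expect_equal(fog_intervals(track),
               data.frame(start_s = 1.0, end_s = 3.0))

  writeLines("start_s,end_s,label", path)
  expect_equal(nrow(read_annotations(path)$intervals), 0L)

  writeLines(c("start_s,end_s,label", "5.0,4.0,fog"), path)
  expect_error(read_annotations(path), "format error")
})

test_that("sinc resampling preserves constants, sines and the length rule", {
  rec <- foot_rec(matrix(5, 256, 3), rate_hz = 128)
  out <- resample_sinc(rec, 100)
  expect_equal(n_samples(out), floor(255 * 100 / 128) + 1)
  expect_lt(max(abs(out$gyro - 5)), 1e-6)

  t_in <- (0:255) / 128
  rec2 <- foot_rec(cbind(sin(2 * pi * 2 * t_in), 0, 0), rate_hz = 128)
  out2 <- resample_sinc(rec2, 100)
  t_out <- sample_times(out2)
  interior <- t_out > 0.5 & t_out < max(t_out) - 0.5
  expect_lt(max(abs(out2$gyro[interior, 1] -
                      sin(2 * pi * 2 * t_out[interior]))), 0.01)

  rec3 <- foot_rec(matrix(rnorm(30), 10, 3), rate_hz = 100)
  expect_identical(resample_sinc(rec3, 100), rec3)
  expect_error(resample_sinc(rec3, 128), "upsampling")
})

test_that("sinc resampling keeps sub-10 Hz sine amplitude within 1%", {
  n <- 1280
  t_in <- (0:(n - 1)) / 128
  for (f in c(1, 5, 9.5)) {
    rec <- foot_rec(cbind(sin(2 * pi * f * t_in), 0, 0), rate_hz = 128)
    out <- resample_sinc(rec, 100)
    t_out <- sample_times(out)
    interior <- t_out > 1 & t_out < max(t_out) - 1
    expect_lt(max(abs(out$gyro[interior, 1] -
                        sin(2 * pi * f * t_out[interior]))), 0.01)
  }
})

test_that("output length follows floor(duration x target rate) convention", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(150:800, 1)
    rec <- foot_rec(matrix(rnorm(3 * n), n, 3), rate_hz = 128)
    out <- resample_sinc(rec, 100)
    expect_equal(n_samples(out), floor((n - 1) * 100 / 128) + 1)
    expect_lte(abs(n_samples(out) - floor(n / 128 * 100)), 1)
  }
})
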