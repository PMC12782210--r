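# Ingestion, deduplication, windowing and min-max normalization.

make_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

base_rows <- function(n, t0 = 100) {
  data.frame(
    accelerometerTimestamp_sinceReboot = t0 + (seq_len(n) - 1) / 100,
    accelX = 0, accelY = 0, accelZ = -1,
    gyroX = 0, gyroY = 0, gyroZ = 0,
    position = "laying"
  )
}

test_that("duplicated since-reboot timestamps keep their first row", {
  df <- base_rows(5)
  df$accelX <- 1:5
  df$accelerometerTimestamp_sinceReboot[2:3] <-
    df$accelerometerTimestamp_sinceReboot[2]
  df <- df[order(df$accelerometerTimestamp_sinceReboot), ]
  path <- make_csv(df, withr::local_tempfile(fileext = ".csv"))
  rec <- read_sensorlog_csv(path, user_id = "u")
  expect_length(rec$timestamps, 4L)        # 3 rows shared a timestamp -> 1 kept
  expect_equal(unname(rec$accel[2, 1]), 2) # first occurrence survives
})

test_that("missing required columns are named in the error", {
  df <- base_rows(3)
  df$gyroZ <- NULL
  path <- make_csv(df, withr::local_tempfile(fileext = ".csv"))
  expect_error(read_sensorlog_csv(path), "gyroZ")
})

test_that("windows tile the stream, drop the partial tail and conserve samples", {
  sig <- sample_cohort(2, seed = 2)[[1]]
  rec <- simulate_recording(sig, protocol_spec(1, 1), seed = 6)
  # truncate to 12.5 s
  keep <- seq_len(1250)
  short <- sensor_recording(rec$user_id, rec$timestamps[keep],
                            rec$accel[keep, ], rec$gyro[keep, ],
                            rec$position[keep], rec$sample_rate_hz)
  wins <- segment_windows(short)
  expect_length(wins, 12L)
  # tiling conservation: windows + dropped tail reconstruct the stream
  recon <- do.call(rbind, lapply(wins, `[[`, "accel"))
  expect_identical(rbind(recon, short$accel[1201:1250, ]), short$accel)
  expect_identical(wins[[3]]$window_index, 2L)
  expect_identical(wins[[3]]$minute, 1L)
})

test_that("a full two-minute recording yields one window per second", {
  rec <- simulate_recording(static_signature(), protocol_spec(1, 1), seed = 1)
  expect_length(segment_windows(rec), 120L)
})

test_that("window position labels use the majority rule with earlier-label ties", {
  n <- 100
  maj <- toy_window(matrix(0, n, 3))
  rec <- sensor_recording("u", (0:(n - 1)) / 100, maj$accel,
                          matrix(0, n, 3),
                          rep(c("laying", "sitting"), c(60, 40)), 100)
  expect_identical(segment_windows(rec)[[1]]$position, "laying")
  rec_min <- sensor_recording("u", (0:(n - 1)) / 100, maj$accel,
                              matrix(0, n, 3),
                              rep(c("laying", "sitting"), c(40, 60)), 100)
  expect_identical(segment_windows(rec_min)[[1]]$position, "sitting")
  rec_tie <- sensor_recording("u", (0:(n - 1)) / 100, maj$accel,
                              matrix(0, n, 3),
                              rep(c("sitting", "laying"), c(50, 50)), 100)
  expect_identical(segment_windows(rec_tie)[[1]]$position, "sitting")
})

test_that("min-max normalization follows the fit-on-train contract", {
  train <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  prm <- fit_minmax(train)
  norm <- apply_minmax(prm, train)
  expect_equal(norm[, "a"], c(0, 0.5, 1))
  expect_equal(norm[, "b"], c(0, 0, 0))          # constant feature -> 0
  test <- cbind(a = 8, b = 9)
  expect_equal(unname(apply_minmax(prm, test)[1, "a"]), 1.5)  # no clipping
  expect_equal(unname(apply_minmax(prm, test)[1, "b"]), 0)
  expect_error(apply_minmax(list(), train), "state error")
  expect_error(fit_minmax(train[1, , drop = FALSE]), "at least 2 rows")
})

test_that("normalization is idempotent on training data and leak-free", {
  set.seed(3)
  train <- matrix(rnorm(200), 40, 5)
  test <- matrix(rnorm(100, mean = 3), 20, 5)
  prm <- fit_minmax(train)
  before <- unclass(prm)
  norm_train <- apply_minmax(prm, train)
  expect_equal(unname(apply(norm_train, 2, min)), rep(0, 5))
  expect_equal(unname(apply(norm_train, 2, max)), rep(1, 5))
  invisible(apply_minmax(prm, test))
  expect_identical(unclass(prm), before)         # params never mutated
})
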