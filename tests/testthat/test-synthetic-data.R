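# Synthetic cohort generator: seeded determinism, separation scaling,
# simulator physics, and the SensorLog CSV round trip.

test_that("sample_cohort is deterministic and validates its inputs", {
  a <- sample_cohort(36, seed = 7, separation = 1.0)
  b <- sample_cohort(36, seed = 7, separation = 1.0)
  expect_length(a, 36)
  expect_identical(a, b)
  expect_error(sample_cohort(1, seed = 1), "n_users")
})

test_that("zero separation collapses all users onto the population mean", {
  sigs <- sample_cohort(2, seed = 1, separation = 0)
  p1 <- signature_parameters(sigs[[1]])
  p2 <- signature_parameters(sigs[[2]])
  expect_identical(p1, p2)
})

test_that("pairwise parameter distance grows with the separation knob", {
  d_wide <- cohort_separation_distance(sample_cohort(10, seed = 3, separation = 2.0))
  d_narrow <- cohort_separation_distance(sample_cohort(10, seed = 3, separation = 0.5))
  expect_gt(d_wide, d_narrow)
})

test_that("simulated streams have the protocol-mandated shape", {
  sig <- sample_cohort(2, seed = 5)[[1]]
  rec <- simulate_recording(sig, protocol_spec(), seed = 9)
  expect_length(rec$timestamps, 15 * 60 * 100)   # 15 min at 100 Hz
  expect_true(all(diff(rec$timestamps) > 0))
  expect_equal(max(abs(diff(rec$timestamps) - 0.01)), 0, tolerance = 1e-9)
  expect_identical(rec$position[1], "laying")
  expect_identical(rec$position[length(rec$position)], "sitting")
  expect_equal(sum(rec$position == "laying"), 10 * 60 * 100)
})

test_that("a static face-up device reads gravity only", {
  rec <- simulate_recording(static_signature(), protocol_spec(1, 1), seed = 4)
  expect_equal(max(abs(rec$accel[, 1])), 0)
  expect_equal(max(abs(rec$accel[, 2])), 0)
  expect_equal(max(abs(rec$accel[, 3] + 1)), 0)
  expect_equal(max(abs(rec$gyro)), 0)
})

test_that("attitude drift separates early and late windows, more so at higher rates", {
  base <- static_signature()
  drift_of <- function(rate) {
    sig <- base
    sig$drift_rate <- rate
    rec <- simulate_recording(sig, protocol_spec(10, 1), seed = 2)
    w <- window_feature_matrix(rec)
    m1 <- colMeans(w$features[w$meta$minute == 1, c("accelX_mean", "accelY_mean")])
    m10 <- colMeans(w$features[w$meta$minute == 10, c("accelX_mean", "accelY_mean")])
    sqrt(sum((m10 - m1)^2))
  }
  d_small <- drift_of(0.01)
  d_large <- drift_of(0.10)
  expect_gt(d_large, d_small)
  expect_gt(d_large, 0)
})

test_that("SensorLog CSV writing round-trips and counts rows", {
  sig <- sample_cohort(2, seed = 8)[[2]]
  rec <- simulate_recording(sig, protocol_spec(1, 1, 100), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensorlog_csv(rec, path)
  expect_identical(length(readLines(path)), length(rec$timestamps) + 1L)
  back <- read_sensorlog_csv(path)
  expect_equal(back$timestamps, rec$timestamps, tolerance = 1e-9)
  expect_equal(back$accel, rec$accel, tolerance = 1e-9)
  expect_equal(back$gyro, rec$gyro, tolerance = 1e-9)
  expect_identical(back$position, rec$position)
  expect_identical(back$user_id, rec$user_id)
})

test_that("degenerate recordings are rejected at construction", {
  expect_error(sensor_recording("u", numeric(0), matrix(0, 0, 3),
                                matrix(0, 0, 3), character(0), 100),
               "at least one sample")
  expect_error(sensor_recording("u", c(1, 1), matrix(0, 2, 3),
                                matrix(0, 2, 3), rep("laying", 2), 100),
               "strictly increasing")
})
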