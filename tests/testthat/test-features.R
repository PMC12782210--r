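# The 56-feature extractor, attitude convention, and raw sequences.

test_that("the attitude convention inverts the simulator's rest poses", {
  flat <- toy_window(matrix(rep(c(0, 0, -1), each = 4), 4, 3), fs = 4)
  att <- attitude_series(flat)
  expect_equal(unname(att), matrix(0, 4, 3))
  nose_down <- toy_window(matrix(rep(c(-1, 0, 0), each = 4), 4, 3), fs = 4)
  expect_equal(attitude_series(nose_down)[, "pitch"], rep(pi / 2, 4))
})

test_that("yaw integrates the gyroscope Z rate from the window start", {
  n <- 100
  w <- toy_window(matrix(rep(c(0, 0, -1), each = n), n, 3),
                  cbind(0, 0, rep(0.1, n)), fs = 100)
  yaw <- attitude_series(w)[, "yaw"]
  expect_equal(yaw[1], 0)
  # constant 0.1 rad/s over the window's 0.99 s span
  expect_equal(yaw[n], 0.1 * (n - 1) / 100, tolerance = 1e-12)
})

test_that("vector magnitude matches an independent norm", {
  expect_equal(vector_magnitude(c(3, 4, 0)), 5)
  expect_equal(vector_magnitude(c(0, 0, -1)), 1)
  set.seed(11)
  V <- matrix(rnorm(60), 20, 3)
  expect_equal(vector_magnitude(V),
               apply(V, 1, function(v) sqrt(sum(v * v))))
})

test_that("every window yields exactly 56 named features", {
  set.seed(21)
  f <- extract_features(random_window())
  expect_length(f, 56L)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
})

test_that("constant windows hit the degenerate-statistics conventions", {
  w <- toy_window(matrix(rep(c(0.3, -0.2, -0.9), each = 50), 50, 3), fs = 50)
  f <- extract_features(w)
  expect_equal(unname(f["accelX_mean"]), 0.3)
  expect_equal(unname(f["accelX_max"]), 0.3)
  expect_equal(unname(f["accelX_min"]), 0.3)
  expect_equal(unname(f["accelX_rms"]), 0.3)
  expect_equal(unname(f["accelX_variance"]), 0)
  expect_equal(unname(f["accelX_sd"]), 0)
  expect_equal(unname(f["accelX_skewness"]), 0)
  expect_equal(unname(f["accelX_kurtosis"]), 0)
  expect_equal(unname(f["accelY_rms"]), 0.2)    # rms of a constant = |value|
  expect_error(extract_features(toy_window(matrix(0, 1, 3))), "at least 2")
})

test_that("features match the brute-force oracle on random windows", {
  set.seed(31)
  for (i in 1:40) {
    w <- random_window(n = sample(20:120, 1), fs = 100)
    expect_equal(unname(extract_features(w)), oracle_features(w),
                 tolerance = 1e-9)
  }
})

test_that("shifting a signal moves location statistics and nothing else", {
  set.seed(41)
  w <- random_window()
  w2 <- w
  w2$accel[, 1] <- w2$accel[, 1] + 2.5
  f1 <- extract_features(w)
  f2 <- extract_features(w2)
  expect_equal(f2["accelX_mean"], f1["accelX_mean"] + 2.5)
  expect_equal(f2["accelX_max"], f1["accelX_max"] + 2.5)
  expect_equal(f2["accelX_min"], f1["accelX_min"] + 2.5)
  for (s in c("variance", "sd", "skewness", "kurtosis")) {
    expect_equal(f2[paste0("accelX_", s)], f1[paste0("accelX_", s)],
                 tolerance = 1e-9)
  }
})

test_that("raw sequences have 6 ordered channels and pad short windows", {
  set.seed(51)
  w <- random_window(100)
  s <- extract_raw_sequence(w)
  expect_identical(dim(s), c(100L, 6L))
  expect_identical(colnames(s),
                   c("yaw", "pitch", "roll", "accelX", "accelY", "accelZ"))
  expect_false(attr(s, "padded"))
  w97 <- random_window(97)
  w97$sample_rate_hz <- 100L
  s97 <- extract_raw_sequence(w97)
  expect_identical(dim(s97), c(100L, 6L))
  expect_true(attr(s97, "padded"))
  expect_equal(s97[98, ], s97[97, ])            # right-padded with last sample
  flat <- toy_window(matrix(rep(c(0, 0, -1), each = 10), 10, 3), fs = 10)
  sf <- extract_raw_sequence(flat)
  expect_equal(unname(sf[, 1:3]), matrix(0, 10, 3))
})

test_that("the vectorized recording path equals per-window extraction", {
  sig <- sample_cohort(3, seed = 6)[[2]]
  rec <- simulate_recording(sig, protocol_spec(1, 1, 50), seed = 7)
  fast <- window_feature_matrix(rec)
  slow <- t(vapply(segment_windows(rec), extract_features, numeric(56)))
  expect_equal(unname(fast$features), unname(slow), tolerance = 1e-9)
  seqs <- window_raw_sequences(rec)
  w5 <- segment_windows(rec)[[5]]
  s5 <- extract_raw_sequence(w5)
  expect_equal(matrix(seqs[5, , ], ncol = 6), matrix(s5, ncol = 6),
               tolerance = 1e-12)
})
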