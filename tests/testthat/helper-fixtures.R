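# Shared fixtures: hand-built windows/recordings and independent
# brute-force oracles used to cross-check the package's computations.

# Construct a sensor_window directly from sample matrices.
toy_window <- function(accel, gyro = NULL, fs = nrow(accel),
                       position = "laying", user_id = "toy") {
  accel <- as.matrix(accel)
  n <- nrow(accel)
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  structure(
    list(user_id = user_id, start_time = 0, position = position,
         window_index = 0L, minute = 1L,
         timestamps = (seq_len(n) - 1) / fs,
         accel = accel, gyro = as.matrix(gyro), sample_rate_hz = as.integer(fs)),
    class = "sensor_window"
  )
}

# A window of i.i.d. Gaussian samples on all six channels.
random_window <- function(n = 100L, fs = 100L, sd = 1) {
  toy_window(matrix(stats::rnorm(3 * n, sd = sd), n, 3),
             matrix(stats::rnorm(3 * n, sd = sd), n, 3), fs = fs)
}

# A signature with every stochastic term switched off and flat orientation:
# the simulator must emit accel (0, 0, -1) and gyro 0.
static_signature <- function(user_id = "static") {
  user_signature(user_id,
                 base_orientation_laying = c(0, 0, 0),
                 base_orientation_sitting = c(0, 0, 0),
                 tremor_amplitudes = c(0, 0, 0),
                 tremor_frequencies = c(1, 1, 1),
                 gyro_noise_scale = c(0, 0, 0),
                 accel_noise_sd = 0, drift_rate = 0)
}

# Independent brute-force statistics oracle: explicit sums, no shared code
# with the package implementation.
oracle_stats8 <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  c(mean = m, max = max(x), min = min(x),
    rms = sqrt(sum(x^2) / n), variance = m2, sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# Oracle 56-vector for a window: recompute the seven signals with
# independent formulas, then apply oracle_stats8 to each.
oracle_features <- function(w) {
  a <- w$accel
  pitch <- atan2(-a[, 1], sqrt(a[, 2]^2 + a[, 3]^2))
  roll <- atan2(a[, 2], -a[, 3])
  n <- nrow(a)
  g <- w$gyro[, 3]
  yaw <- numeric(n)
  for (i in 2:n) {
    yaw[i] <- yaw[i - 1] +
      (g[i] + g[i - 1]) / 2 * (w$timestamps[i] - w$timestamps[i - 1])
  }
  vm <- sqrt(a[, 1]^2 + a[, 2]^2 + a[, 3]^2)
  sig <- list(yaw, pitch, roll, a[, 1], a[, 2], a[, 3], vm)
  unlist(lapply(sig, oracle_stats8), use.names = FALSE)
}

# A quick, well-separated two-cluster dataset for model tests.
separable_clusters <- function(n_pos = 40L, n_neg = 80L, p = 8L, gap = 6,
                               seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_pos * p, mean = gap), n_pos, p),
             matrix(stats::rnorm(n_neg * p, mean = 0), n_neg, p))
  list(X = X, y = c(rep(1L, n_pos), rep(0L, n_neg)))
}

# User-id vector shaped like a default 36-child cohort (no simulation).
cohort_ids <- function(n = 36L) sprintf("user%02d", seq_len(n))
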