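# Stream simulator: turns a user signature plus a protocol into a
# SensorLog-style 6-axis recording.
#
# Device-frame convention (fixed throughout the package): a static face-up
# device reads accelerometer (0, 0, -1) in gravity units. Attitude is the
# triple (yaw, pitch, roll); gravity seen in the device frame depends only on
# pitch (theta) and roll (phi):
#   ax = -sin(theta)
#   ay =  cos(theta) * sin(phi)
#   az = -cos(theta) * cos(phi)
# which is exactly inverted by the tilt formulas in [attitude_series()].
# Gyroscope channels carry the attitude angle rates (X: roll, Y: pitch,
# Z: yaw), a good approximation at the small angular rates of sedentary use.

#' Construct a sensor recording object
#'
#' Usually produced by [simulate_recording()] or [read_sensorlog_csv()];
#' exported so tests and external readers can build recordings directly.
#'
#' @param user_id Identifier.
#' @param timestamps Strictly increasing numeric vector, seconds since
#'   reboot.
#' @param accel,gyro Numeric matrices `n x 3` (columns X, Y, Z) in gravity
#'   units and rad/s respectively.
#' @param position Character vector of per-sample position labels
#'   (`"laying"` / `"sitting"`).
#' @param sample_rate_hz Nominal sampling rate in Hz.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(user_id, timestamps, accel, gyro, position,
                             sample_rate_hz) {
  n <- length(timestamps)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (n < 1L) stopf("a recording must contain at least one sample")
  if (nrow(accel) != n || nrow(gyro) != n || length(position) != n)
    stopf("timestamps, accel, gyro and position must have equal length")
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stopf("accel and gyro must have 3 columns (X, Y, Z)")
  if (anyNA(timestamps) || anyNA(accel) || anyNA(gyro) || anyNA(position))
    stopf("recordings must not contain missing values")
  if (n > 1L && any(diff(timestamps) <= 0))
    stopf("timestamps must be strictly increasing")
  colnames(accel) <- c("accelX", "accelY", "accelZ")
  colnames(gyro) <- c("gyroX", "gyroY", "gyroZ")
  structure(
    list(user_id = as.character(user_id),
         timestamps = as.numeric(timestamps),
         accel = accel, gyro = gyro,
         position = as.character(position),
         sample_rate_hz = as.integer(sample_rate_hz)),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("<sensor_recording>", x$user_id, "-", length(x$timestamps), "samples @",
      x$sample_rate_hz, "Hz;",
      sprintf("%.1f s;", diff(range(x$timestamps))),
      paste(sprintf("%s=%d", names(table(x$position)), table(x$position)),
            collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(rec) length(rec$timestamps)

# Bounded (Ornstein-Uhlenbeck-like) attitude drift: a mean-reverting random
# walk so 15-minute streams stay physically plausible. `rate_per_min` is the
# standard deviation the walk would accumulate over one minute if unbounded;
# the reversion time constant is 5 minutes, long relative to single minutes
# (so nearby-in-time windows stay similar) but short enough to bound drift.
.drift_ou <- function(n, dt, rate_per_min, tau_s = 300) {
  if (rate_per_min <= 0 || n == 0L) return(numeric(n))
  sigma_s <- rate_per_min / sqrt(60)      # rad / sqrt(s)
  eps <- stats::rnorm(n, sd = sigma_s * sqrt(dt))
  as.numeric(stats::filter(eps, 1 - dt / tau_s, method = "recursive"))
}

#' Simulate one user's sedentary-session recording
#'
#' Generates a 6-axis stream of `(laying + sitting) * 60 * rate` samples.
#' The device attitude is the position-specific base orientation plus a
#' bounded random-walk drift (rate set by `sig$drift_rate`); the
#' accelerometer reads the gravity vector in the device frame plus per-axis
#' sinusoidal tremor and white noise; the gyroscope reads the attitude angle
#' rates plus white noise. The position switch is blended over two seconds
#' (the child re-settling the device) rather than an instantaneous jump.
#'
#' @param sig A [user_signature()].
#' @param protocol A [protocol_spec()].
#' @param seed Integer seed; the same `(sig, protocol, seed)` triple always
#'   produces a bit-identical stream.
#' @return A [sensor_recording()] whose per-sample `position` labels follow
#'   the protocol (laying first, then sitting).
#' @export
#' @examples
#' sig <- sample_cohort(2, seed = 1)[[1]]
#' rec <- simulate_recording(sig, protocol_spec(1, 1), seed = 5)
#' n_distinct <- length(unique(rec$position))
simulate_recording <- function(sig, protocol, seed) {
  stopifnot(inherits(sig, "user_signature"), inherits(protocol, "protocol_spec"))
  fs <- protocol$sample_rate_hz
  dt <- 1 / fs
  n_lay <- protocol$laying_minutes * 60L * fs
  n_sit <- protocol$sitting_minutes * 60L * fs
  n <- n_lay + n_sit
  t0 <- 1000  # arbitrary but fixed since-reboot origin
  tim <- t0 + (seq_len(n) - 1L) * dt
  position <- rep(c("laying", "sitting"), c(n_lay, n_sit))

  # base attitude per sample, blended across the position switch (2 s ramp)
  base <- matrix(rep(sig$base_orientation_laying, each = n), n, 3)
  sit <- matrix(rep(sig$base_orientation_sitting, each = n_sit), n_sit, 3)
  base[(n_lay + 1L):n, ] <- sit
  ramp_len <- min(2L * fs, n_lay, n_sit)
  if (ramp_len > 1L) {
    w <- seq(0, 1, length.out = 2L * ramp_len)
    idx <- (n_lay - ramp_len + 1L):(n_lay + ramp_len)
    for (j in 1:3) {
      base[idx, j] <- (1 - w) * sig$base_orientation_laying[j] +
        w * sig$base_orientation_sitting[j]
    }
  }

  with_seed(mix_seed(seed, 202L), {
    drift <- cbind(.drift_ou(n, dt, sig$drift_rate),
                   .drift_ou(n, dt, sig$drift_rate),
                   .drift_ou(n, dt, sig$drift_rate))
    att <- base + drift  # columns: yaw, pitch, roll
    theta <- att[, 2]; phi <- att[, 3]
    grav <- cbind(-sin(theta), cos(theta) * sin(phi), -cos(theta) * cos(phi))

    phase <- stats::runif(3, 0, 2 * pi)
    tt <- tim - t0
    tremor <- vapply(1:3, function(j) {
      sig$tremor_amplitudes[j] * sin(2 * pi * sig$tremor_frequencies[j] * tt +
                                       phase[j])
    }, numeric(n))
    accel <- grav + tremor
    if (sig$accel_noise_sd > 0)
      accel <- accel + matrix(stats::rnorm(3L * n, sd = sig$accel_noise_sd), n, 3)

    # gyro: angle rates (X <- roll, Y <- pitch, Z <- yaw) + white noise
    rate_of <- function(x) c(0, diff(x)) * fs
    gyro <- cbind(rate_of(att[, 3]), rate_of(att[, 2]), rate_of(att[, 1]))
    for (j in 1:3) {
      if (sig$gyro_noise_scale[j] > 0)
        gyro[, j] <- gyro[, j] + stats::rnorm(n, sd = sig$gyro_noise_scale[j])
    }

    sensor_recording(sig$user_id, tim, accel, gyro, position, fs)
  })
}

#' Write a recording as a SensorLog-style CSV
#'
#' Columns: `accelerometerTimestamp_sinceReboot`, `accelX`, `accelY`,
#' `accelZ`, `gyroX`, `gyroY`, `gyroZ`, plus `position` and `user_id`.
#' Values are written with enough digits to round-trip through
#' [read_sensorlog_csv()] within 1e-9.
#'
#' @param rec A [sensor_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensorlog_csv <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (n_samples(rec) == 0L) stopf("refusing to write an empty recording")
  df <- data.table::data.table(
    accelerometerTimestamp_sinceReboot = rec$timestamps,
    accelX = rec$accel[, 1], accelY = rec$accel[, 2], accelZ = rec$accel[, 3],
    gyroX = rec$gyro[, 1], gyroY = rec$gyro[, 2], gyroZ = rec$gyro[, 3],
    position = rec$position,
    user_id = rec$user_id
  )
  data.table::fwrite(df, path)
  invisible(path)
}
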