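# Windowed feature engineering: 8 statistics x 7 signals = 56 features.
#
# Attitude convention (documented here because it is the least-specified
# step of the method): pitch and roll come from accelerometer tilt under the
# face-up (0, 0, -1) rest convention,
#   pitch = atan2(-ax, sqrt(ay^2 + az^2))
#   roll  = atan2(ay, -az)
# and yaw is the cumulative trapezoidal integral of the gyroscope Z channel
# from the window start (yaw at the first sample is 0, i.e. yaw is reset per
# window). This needs no magnetometer and is fully deterministic. Any fixed
# convention serves the classifiers equally because training and testing
# share it.

.STATS <- c("mean", "max", "min", "rms", "variance", "sd", "skewness",
            "kurtosis")
.SIGNALS <- c("yaw", "pitch", "roll", "accelX", "accelY", "accelZ",
              "vector_magnitude")

#' Names of the 56 window features, in stable order
#'
#' Signals vary slowest (yaw, pitch, roll, accelX, accelY, accelZ,
#' vector_magnitude), statistics fastest (mean, max, min, rms, variance, sd,
#' skewness, kurtosis); names are `"<signal>_<statistic>"`.
#'
#' @return Character vector of length 56.
#' @export
feature_names <- function() {
  as.vector(t(outer(.SIGNALS, .STATS, paste, sep = "_")))
}

#' Per-sample attitude angles for one window
#'
#' @param window A `sensor_window` from [segment_windows()].
#' @return A numeric matrix with one row per sample and columns `yaw`,
#'   `pitch`, `roll` (radians), under the convention documented above.
#' @export
attitude_series <- function(window) {
  stopifnot(inherits(window, "sensor_window"))
  a <- window$accel
  pitch <- atan2(-a[, 1], sqrt(a[, 2]^2 + a[, 3]^2))
  roll <- atan2(a[, 2], -a[, 3])
  yaw <- if (nrow(a) > 1L) {
    as.numeric(pracma::cumtrapz(window$timestamps, window$gyro[, 3]))
  } else 0
  cbind(yaw = yaw, pitch = pitch, roll = roll)
}

#' Euclidean vector magnitude of accelerometer samples
#'
#' @param sample A length-3 vector or an `n x 3` matrix of accelerometer
#'   samples.
#' @return `sqrt(x^2 + y^2 + z^2)` per sample.
#' @export
vector_magnitude <- function(sample) {
  if (is.matrix(sample)) sqrt(rowSums(sample^2)) else sqrt(sum(sample^2))
}

# The eight per-signal statistics. Population moments (divide by n);
# skewness m3/m2^1.5 and excess kurtosis m4/m2^2 - 3, both 0 by convention
# when m2 = 0.
.stats8 <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = m, max = max(x), min = min(x), rms = sqrt(mean(x^2)),
    variance = m2, sd = sqrt(m2), skewness = skew, kurtosis = kurt)
}

#' Extract the 56-element feature vector of one window
#'
#' For each of the 7 signals (yaw, pitch, roll, the three accelerometer
#' axes, and accelerometer vector magnitude) computes the 8 statistics
#' mean, max, min, root mean square, population variance, population
#' standard deviation, skewness and excess kurtosis.
#'
#' @param window A `sensor_window` with at least 2 samples.
#' @return Named numeric vector of length 56, ordered as [feature_names()].
#' @export
extract_features <- function(window) {
  stopifnot(inherits(window, "sensor_window"))
  if (nrow(window$accel) < 2L)
    stopf("feature extraction needs a window with at least 2 samples")
  att <- attitude_series(window)
  signals <- cbind(att, window$accel, vector_magnitude(window$accel))
  out <- as.vector(apply(signals, 2, .stats8))
  names(out) <- feature_names()
  out
}

#' Raw 6-channel per-sample sequence of one window
#'
#' Channels are ordered (yaw, pitch, roll, accelX, accelY, accelZ), the
#' input consumed by the dual-stream transformer. Windows shorter than the
#' nominal length are right-padded with their last sample and flagged via
#' the `"padded"` attribute.
#'
#' @param window A non-empty `sensor_window`.
#' @param length Nominal sequence length; defaults to the window's sampling
#'   rate (one second of samples).
#' @return A `length x 6` numeric matrix with a logical `"padded"`
#'   attribute.
#' @export
extract_raw_sequence <- function(window, length = window$sample_rate_hz) {
  stopifnot(inherits(window, "sensor_window"))
  n <- nrow(window$accel)
  if (n < 1L) stopf("cannot extract a raw sequence from an empty window")
  att <- attitude_series(window)
  seqm <- cbind(att, window$accel)
  colnames(seqm) <- c("yaw", "pitch", "roll", "accelX", "accelY", "accelZ")
  padded <- n < length
  if (padded) seqm <- rbind(seqm, seqm[rep(n, length - n), , drop = FALSE])
  if (nrow(seqm) > length) seqm <- seqm[seq_len(length), , drop = FALSE]
  attr(seqm, "padded") <- padded
  seqm
}

# ---- vectorized fast path over a whole recording ---------------------------

# Column-wise versions of .stats8 over a samples x windows matrix.
.stats8_cols <- function(M) {
  m <- colMeans(M)
  D <- sweep(M, 2, m)
  m2 <- colMeans(D^2)
  m3 <- colMeans(D^3)
  m4 <- colMeans(D^4)
  pos <- m2 > 0
  skew <- ifelse(pos, m3 / m2^1.5, 0)
  kurt <- ifelse(pos, m4 / m2^2 - 3, 0)
  rbind(mean = m,
        max = apply(M, 2, max),
        min = apply(M, 2, min),
        rms = sqrt(colMeans(M^2)),
        variance = m2, sd = sqrt(m2), skewness = skew, kurtosis = kurt)
}

#' Feature matrix and window metadata for a full recording
#'
#' Vectorized equivalent of calling [extract_features()] on every window of
#' [segment_windows()]; requires a regular stream whose complete seconds
#' each hold exactly `sample_rate_hz` samples (true of simulated and
#' round-tripped recordings). Returns both the `windows x 56` matrix and a
#' metadata table (user, window index, protocol minute, majority position).
#'
#' @param rec A [sensor_recording()].
#' @return A list with elements `features` (matrix, one row per window,
#'   columns [feature_names()]) and `meta` (data.frame with `user_id`,
#'   `window_index`, `minute`, `position`, `start_time`).
#' @export
window_feature_matrix <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  fs <- rec$sample_rate_hz
  n <- n_samples(rec)
  n_win <- n %/% fs
  if (n_win < 1L) stopf("recording shorter than one window")
  used <- seq_len(n_win * fs)
  tim <- rec$timestamps[used]
  if (max(abs(diff(tim) - 1 / fs)) > 1e-6)
    stopf("fast path requires a regular %d Hz stream; use segment_windows()",
          fs)

  shape <- function(x) matrix(x[used], nrow = fs)  # samples x windows
  ax <- shape(rec$accel[, 1]); ay <- shape(rec$accel[, 2])
  az <- shape(rec$accel[, 3])
  pitch <- atan2(-ax, sqrt(ay^2 + az^2))
  roll <- atan2(ay, -az)
  gz <- shape(rec$gyro[, 3])
  # per-window cumulative trapezoid of the yaw rate, yaw(first sample) = 0
  mids <- (gz[-fs, , drop = FALSE] + gz[-1, , drop = FALSE]) / (2 * fs)
  yaw <- rbind(0, apply(mids, 2, cumsum))
  vm <- sqrt(ax^2 + ay^2 + az^2)

  blocks <- list(yaw = yaw, pitch = pitch, roll = roll,
                 accelX = ax, accelY = ay, accelZ = az,
                 vector_magnitude = vm)
  feats <- do.call(cbind, lapply(blocks, function(M) t(.stats8_cols(M))))
  colnames(feats) <- feature_names()

  w <- seq_len(n_win) - 1L
  pos_m <- matrix(rec$position[used], nrow = fs)
  position <- vapply(seq_len(n_win), function(j) {
    tab <- table(factor(pos_m[, j], levels = unique(pos_m[, j])))
    names(tab)[which.max(tab)]
  }, character(1))
  meta <- data.frame(user_id = rec$user_id, window_index = w,
                     minute = w %/% 60L + 1L, position = position,
                     start_time = tim[w * fs + 1L],
                     stringsAsFactors = FALSE)
  list(features = feats, meta = meta)
}

#' Raw sequences for a full recording
#'
#' Vectorized counterpart of [extract_raw_sequence()] over every complete
#' window of a regular stream.
#'
#' @param rec A [sensor_recording()].
#' @return A 3-d array `windows x sample_rate x 6`.
#' @export
window_raw_sequences <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  fs <- rec$sample_rate_hz
  n_win <- n_samples(rec) %/% fs
  if (n_win < 1L) stopf("recording shorter than one window")
  used <- seq_len(n_win * fs)
  shape <- function(x) matrix(x[used], nrow = fs)
  ax <- shape(rec$accel[, 1]); ay <- shape(rec$accel[, 2])
  az <- shape(rec$accel[, 3])
  pitch <- atan2(-ax, sqrt(ay^2 + az^2))
  roll <- atan2(ay, -az)
  gz <- shape(rec$gyro[, 3])
  mids <- (gz[-fs, , drop = FALSE] + gz[-1, , drop = FALSE]) / (2 * fs)
  yaw <- rbind(0, apply(mids, 2, cumsum))
  out <- array(0, dim = c(n_win, fs, 6L),
               dimnames = list(NULL, NULL,
                               c("yaw", "pitch", "roll",
                                 "accelX", "accelY", "accelZ")))
  out[, , 1] <- t(yaw); out[, , 2] <- t(pitch); out[, , 3] <- t(roll)
  out[, , 4] <- t(ax); out[, , 5] <- t(ay); out[, , 6] <- t(az)
  out
}
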