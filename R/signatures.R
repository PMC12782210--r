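# Cohort signatures: the per-user parameters that make one child's
# micro-movement stream distinguishable from another's.

#' Construct a user movement signature
#'
#' A signature collects the per-user physical parameters the simulator needs:
#' the resting device attitude in each protocol position, the amplitude and
#' dominant frequency of micro-movement ("tremor") on each accelerometer
#' axis, sensor noise scales, and the rate of slow within-session attitude
#' drift. Downstream classifiers see users as separable exactly insofar as
#' these parameters differ between users.
#'
#' @param user_id Opaque identifier (character scalar).
#' @param base_orientation_laying,base_orientation_sitting Numeric length-3
#'   `(yaw, pitch, roll)` resting attitude in radians for each position.
#' @param tremor_amplitudes Numeric length-3, per-accelerometer-axis
#'   micro-movement amplitude in gravity units. Non-negative.
#' @param tremor_frequencies Numeric length-3, per-axis dominant oscillation
#'   frequency in Hz; must lie in `[0.5, 8]` (well below the 50 Hz Nyquist
#'   limit at 100 Hz sampling).
#' @param gyro_noise_scale Numeric length-3, per-axis gyroscope white-noise
#'   standard deviation in rad/s. Non-negative.
#' @param accel_noise_sd Scalar accelerometer white-noise standard deviation
#'   in gravity units. Non-negative.
#' @param drift_rate Scalar, radians per minute of slow random-walk attitude
#'   drift (standard deviation of drift accumulated over one minute in the
#'   unbounded-walk limit). Non-negative.
#' @param separation_scale Non-negative multiplier recording how far this
#'   user's parameters sit from the population mean.
#' @return An object of class `user_signature`.
#' @seealso [sample_cohort()], [simulate_recording()]
#' @export
user_signature <- function(user_id,
                           base_orientation_laying,
                           base_orientation_sitting,
                           tremor_amplitudes,
                           tremor_frequencies,
                           gyro_noise_scale,
                           accel_noise_sd,
                           drift_rate,
                           separation_scale = 1) {
  stopifnot(length(user_id) == 1L)
  chk3 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
      stopf("'%s' must be a finite numeric vector of length 3", nm)
  }
  chk3(base_orientation_laying, "base_orientation_laying")
  chk3(base_orientation_sitting, "base_orientation_sitting")
  chk3(tremor_amplitudes, "tremor_amplitudes")
  chk3(tremor_frequencies, "tremor_frequencies")
  chk3(gyro_noise_scale, "gyro_noise_scale")
  if (any(tremor_amplitudes < 0)) stopf("tremor amplitudes must be non-negative")
  if (any(gyro_noise_scale < 0)) stopf("gyro noise scales must be non-negative")
  if (any(tremor_frequencies < 0.5 - 1e-12) || any(tremor_frequencies > 8 + 1e-12))
    stopf("tremor frequencies must lie in [0.5, 8] Hz")
  if (!is.numeric(accel_noise_sd) || length(accel_noise_sd) != 1L ||
      !is.finite(accel_noise_sd) || accel_noise_sd < 0)
    stopf("'accel_noise_sd' must be a non-negative scalar")
  if (!is.numeric(drift_rate) || length(drift_rate) != 1L ||
      !is.finite(drift_rate) || drift_rate < 0)
    stopf("'drift_rate' must be a non-negative scalar")
  if (!is.numeric(separation_scale) || length(separation_scale) != 1L ||
      !is.finite(separation_scale) || separation_scale < 0)
    stopf("'separation_scale' must be a non-negative scalar")

  structure(
    list(
      user_id = as.character(user_id),
      base_orientation_laying = as.numeric(base_orientation_laying),
      base_orientation_sitting = as.numeric(base_orientation_sitting),
      tremor_amplitudes = as.numeric(tremor_amplitudes),
      tremor_frequencies = as.numeric(tremor_frequencies),
      gyro_noise_scale = as.numeric(gyro_noise_scale),
      accel_noise_sd = as.numeric(accel_noise_sd),
      drift_rate = as.numeric(drift_rate),
      separation_scale = as.numeric(separation_scale)
    ),
    class = "user_signature"
  )
}

#' @export
print.user_signature <- function(x, ...) {
  cat("<user_signature>", x$user_id, "\n")
  cat("  orientation laying/sitting (yaw,pitch,roll rad): ",
      paste(signif(x$base_orientation_laying, 3), collapse = ", "), " / ",
      paste(signif(x$base_orientation_sitting, 3), collapse = ", "), "\n",
      sep = "")
  cat("  tremor amp (g):", paste(signif(x$tremor_amplitudes, 3), collapse = ", "),
      " freq (Hz):", paste(signif(x$tremor_frequencies, 3), collapse = ", "), "\n")
  cat("  drift:", signif(x$drift_rate, 3), "rad/min; separation:",
      x$separation_scale, "\n")
  invisible(x)
}

#' Flatten a signature to its numeric parameter vector
#'
#' Used for distance computations between users (e.g. checking that cohort
#' separation scales as requested).
#'
#' @param sig A [user_signature()].
#' @return A named numeric vector of all numeric parameters.
#' @export
signature_parameters <- function(sig) {
  stopifnot(inherits(sig, "user_signature"))
  c(
    ol = sig$base_orientation_laying,
    os = sig$base_orientation_sitting,
    ta = sig$tremor_amplitudes,
    tf = sig$tremor_frequencies,
    gn = sig$gyro_noise_scale,
    an = sig$accel_noise_sd,
    dr = sig$drift_rate
  )
}

#' Describe the sedentary recording protocol
#'
#' The default mirrors a two-part sedentary tablet protocol: 10 minutes
#' laying followed by 5 minutes sitting, sampled at 100 Hz on both the
#' accelerometer and the gyroscope.
#'
#' @param laying_minutes,sitting_minutes Whole minutes spent in each
#'   position (each at least 1).
#' @param sample_rate_hz Sampling rate in Hz; must be at least twice the
#'   largest admissible tremor frequency (16 Hz).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(laying_minutes = 10L, sitting_minutes = 5L,
                          sample_rate_hz = 100L) {
  if (!is_count(laying_minutes) || !is_count(sitting_minutes))
    stopf("protocol minutes must be whole numbers >= 1")
  if (!is_count(sample_rate_hz, min = 16L))
    stopf("sample_rate_hz must be an integer >= 16 (2 x max tremor frequency)")
  structure(
    list(
      laying_minutes = as.integer(laying_minutes),
      sitting_minutes = as.integer(sitting_minutes),
      sample_rate_hz = as.integer(sample_rate_hz)
    ),
    class = "protocol_spec"
  )
}

total_minutes <- function(protocol) protocol$laying_minutes + protocol$sitting_minutes

# Population-level parameter centres for the synthetic cohort. Chosen once to
# represent a plausible tablet-holding child: near-flat device while laying
# (screen above the face), a steeper pitch while sitting (device propped on
# the lap), millinewton-scale micro-movement and slow attitude drift.
.POP <- list(
  orient_laying  = c(yaw = 0.00, pitch = 0.12, roll = 0.05),
  orient_sitting = c(yaw = 0.00, pitch = 0.55, roll = 0.10),
  orient_sd      = 0.12,   # rad, per angle, at separation 1
  tremor_amp     = c(0.020, 0.020, 0.015),  # g
  tremor_amp_cv  = 0.6,    # log-scale spread at separation 1
  tremor_freq    = c(2.5, 3.5, 4.5),        # Hz
  tremor_freq_sd = 1.2,    # Hz at separation 1
  gyro_noise     = 0.020,  # rad/s
  gyro_noise_cv  = 0.5,
  accel_noise    = 0.008,  # g
  accel_noise_cv = 0.3,
  drift_rate     = 0.030,  # rad/min
  drift_rate_cv  = 0.3
)

#' Sample a synthetic cohort of user signatures
#'
#' Draws `n_users` signatures around a fixed population mean. Every
#' user-level deviation from the mean is multiplied by `separation`, so
#' `separation = 0` yields identical users (an unidentifiable cohort) and
#' larger values yield cohorts that are easier to tell apart; pairwise
#' parameter distance grows monotonically with `separation`. Each user's
#' draws come from a sub-seed derived from `seed` and the user index, so the
#' same user index maps to the same deviations across `separation` values.
#'
#' @param n_users Number of users (at least 2; one-vs-rest evaluation needs
#'   negatives).
#' @param seed Master integer seed.
#' @param separation Non-negative spread multiplier (default 1).
#' @return A list of [user_signature()] objects with ids `"user01"`,
#'   `"user02"`, ...
#' @export
#' @examples
#' cohort <- sample_cohort(6, seed = 7)
#' length(cohort)
sample_cohort <- function(n_users, seed, separation = 1) {
  if (!is_count(n_users, min = 2L))
    stopf("n_users must be an integer >= 2 (authentication needs negatives)")
  if (!is.numeric(separation) || length(separation) != 1L || separation < 0)
    stopf("'separation' must be a non-negative scalar")
  n_users <- as.integer(n_users)
  width <- max(2L, nchar(as.character(n_users)))
  lapply(seq_len(n_users), function(i) {
    with_seed(mix_seed(seed, 101L, i), {
      z_ol <- stats::rnorm(3)
      z_os <- stats::rnorm(3)
      z_ta <- stats::rnorm(3)
      z_tf <- stats::rnorm(3)
      z_gn <- stats::rnorm(1)
      z_an <- stats::rnorm(1)
      z_dr <- stats::rnorm(1)
      user_signature(
        user_id = sprintf(paste0("user%0", width, "d"), i),
        base_orientation_laying = .POP$orient_laying +
          separation * .POP$orient_sd * z_ol,
        base_orientation_sitting = .POP$orient_sitting +
          separation * .POP$orient_sd * z_os,
        tremor_amplitudes = .POP$tremor_amp *
          exp(separation * .POP$tremor_amp_cv * z_ta),
        tremor_frequencies = pmin(8, pmax(0.5, .POP$tremor_freq +
          separation * .POP$tremor_freq_sd * z_tf)),
        gyro_noise_scale = rep(.POP$gyro_noise, 3) *
          exp(separation * .POP$gyro_noise_cv * z_gn),
        accel_noise_sd = .POP$accel_noise *
          exp(separation * .POP$accel_noise_cv * z_an),
        drift_rate = .POP$drift_rate *
          exp(separation * .POP$drift_rate_cv * z_dr),
        separation_scale = separation
      )
    })
  })
}

#' Mean pairwise parameter distance within a cohort
#'
#' @param cohort A list of [user_signature()]s.
#' @return Mean Euclidean distance between all pairs of
#'   [signature_parameters()] vectors.
#' @export
cohort_separation_distance <- function(cohort) {
  P <- t(vapply(cohort, signature_parameters,
                numeric(length(signature_parameters(cohort[[1]])))))
  mean(stats::dist(P))
}
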