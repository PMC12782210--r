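# Ingestion and windowing of SensorLog-style CSV streams.

.REQUIRED_COLS <- c("accelerometerTimestamp_sinceReboot",
                    "accelX", "accelY", "accelZ",
                    "gyroX", "gyroY", "gyroZ")

#' Read a SensorLog-style CSV into a sensor recording
#'
#' The since-reboot accelerometer timestamp is used as the time base;
#' logging-layer buffering can emit duplicate rows for one sensor read, so
#' rows sharing a since-reboot timestamp are deduplicated keeping the first
#' occurrence. After deduplication timestamps must be strictly increasing.
#'
#' @param path CSV file path.
#' @param user_id Identifier to attach; defaults to a `user_id` column if
#'   present, else the file name.
#' @return A [sensor_recording()]. If the file has no `position` column the
#'   labels are set to `"unlabeled"`.
#' @export
read_sensorlog_csv <- function(path, user_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- data.table::fread(path, showProgress = FALSE)
  missing_cols <- setdiff(.REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0L)
    stopf("format error: missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  tim <- df[["accelerometerTimestamp_sinceReboot"]]
  keep <- !duplicated(tim)
  df <- df[keep, ]
  tim <- tim[keep]
  if (length(tim) > 1L && any(diff(tim) <= 0))
    stopf("data error: timestamps not strictly increasing after deduplication")
  if (is.null(user_id)) {
    user_id <- if ("user_id" %in% names(df)) as.character(df[["user_id"]][1])
               else basename(path)
  }
  position <- if ("position" %in% names(df)) as.character(df[["position"]])
              else rep("unlabeled", nrow(df))
  dt <- stats::median(diff(tim))
  sensor_recording(
    user_id = user_id,
    timestamps = tim,
    accel = as.matrix(df[, c("accelX", "accelY", "accelZ")]),
    gyro = as.matrix(df[, c("gyroX", "gyroY", "gyroZ")]),
    position = position,
    sample_rate_hz = as.integer(round(1 / dt))
  )
}

#' Cut a recording into non-overlapping 1-second windows
#'
#' Windows are anchored to the recording's first timestamp (not wall-clock
#' second boundaries) and tile it in whole seconds; a trailing partial second
#' is dropped, so the window count is `floor(duration in seconds)`. Each
#' window's position label is the majority label over its samples, with an
#' exact tie going to the earlier-in-time label.
#'
#' @param rec A [sensor_recording()].
#' @return A list of `sensor_window` objects, each holding its sample
#'   sub-stream, `start_time`, majority `position`, 0-based `window_index`
#'   and 1-based protocol `minute`. A recording shorter than 1 s yields an
#'   empty list.
#' @export
segment_windows <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  tim <- rec$timestamps
  n <- length(tim)
  dtn <- if (n > 1L) stats::median(diff(tim)) else 1 / rec$sample_rate_hz
  duration <- (tim[n] - tim[1]) + dtn
  n_win <- floor(duration + 1e-9)
  if (n_win < 1L) return(list())
  idx <- floor(tim - tim[1] + 1e-9)  # window index per sample
  lapply(seq_len(n_win) - 1L, function(w) {
    rows <- which(idx == w)
    pos_tab <- table(factor(rec$position[rows],
                            levels = unique(rec$position[rows])))
    # which.max on a table keeps the first level on ties; levels are ordered
    # by first appearance, so an exact tie resolves to the earlier label
    position <- names(pos_tab)[which.max(pos_tab)]
    structure(
      list(user_id = rec$user_id,
           start_time = tim[rows[1]],
           position = position,
           window_index = w,
           minute = w %/% 60L + 1L,
           timestamps = tim[rows],
           accel = rec$accel[rows, , drop = FALSE],
           gyro = rec$gyro[rows, , drop = FALSE],
           sample_rate_hz = rec$sample_rate_hz),
      class = "sensor_window"
    )
  })
}

#' Fit min-max normalization parameters
#'
#' Stores the per-feature minimum and maximum of the training matrix only;
#' [apply_minmax()] maps `x` to `(x - min) / (max - min)`. Constant training
#' features map to 0, and test values outside the training range are not
#' clipped (values > 1 or < 0 are legitimate).
#'
#' @param train_matrix Numeric matrix (rows = windows, columns = features)
#'   with at least 2 rows.
#' @return An object of class `minmax_params`.
#' @export
fit_minmax <- function(train_matrix) {
  train_matrix <- as.matrix(train_matrix)
  if (nrow(train_matrix) < 2L)
    stopf("min-max fitting requires at least 2 rows")
  if (anyNA(train_matrix)) stopf("training matrix contains missing values")
  structure(
    list(min = apply(train_matrix, 2, min),
         max = apply(train_matrix, 2, max),
         n_features = ncol(train_matrix),
         feature_names = colnames(train_matrix)),
    class = "minmax_params"
  )
}

#' Apply fitted min-max normalization
#'
#' @param params A `minmax_params` object from [fit_minmax()].
#' @param matrix Numeric matrix with the same number of columns as the
#'   training matrix.
#' @return The normalized matrix (no clipping; constant training features
#'   yield 0).
#' @export
apply_minmax <- function(params, matrix) {
  if (!inherits(params, "minmax_params"))
    stopf("state error: apply_minmax called before fit_minmax")
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != params$n_features)
    stopf("matrix has %d columns but normalization was fit on %d",
          ncol(matrix), params$n_features)
  rng <- params$max - params$min
  denom <- ifelse(rng > 0, rng, 1)           # constant features -> 0
  out <- sweep(matrix, 2, params$min, "-")
  out <- sweep(out, 2, denom, "/")
  out[, rng == 0] <- 0
  out
}
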