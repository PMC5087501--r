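# Motion-sensor features over one six-second window: per-channel mean,
# variance, range and spectral energy, plus one absolute-change value for
# the accelerometer triple and one for the gyroscope triple (26 in all).

MOTION_FEATURE_NAMES <- c(
  paste0("mean_", SENSOR_CHANNELS),
  paste0("var_", SENSOR_CHANNELS),
  paste0("range_", SENSOR_CHANNELS),
  paste0("se_", SENSOR_CHANNELS),
  "ac_accel", "ac_gyro"
)

#' Spectral energy of a channel
#'
#' Periodogram energy excluding the DC bin, normalized so that a pure
#' cosine of amplitude A occupying an integer number of cycles scores
#' A^2/2 (unitary-transform convention): `sum(|X_k|^2, k != 0) / N^2` with
#' the usual unnormalized DFT `X = fft(x)`. A constant channel scores 0.
#'
#' @param x Numeric vector of at least 2 samples.
#' @return Non-negative scalar.
#' @examples
#' spectral_energy(cos(2 * pi * 3 * (0:99) / 100))  # 0.5
#' @export
spectral_energy <- function(x) {
  n <- length(x)
  if (n < 2) abort("spectral energy needs at least 2 samples")
  mags <- Mod(fft(x))^2
  sum(mags[-1]) / n^2
}

#' Absolute change of a three-axis window
#'
#' Mean absolute first difference accumulated over the three axes of one
#' sensor: `AC = (sum_i |x_i - x_{i-1}| + |y_i - y_{i-1}| + |z_i - z_{i-1}|) / N`.
#' The sum runs over the N-1 consecutive-sample differences of each axis
#' while the normalizer is the window length N.
#'
#' @param x,y,z Equal-length numeric vectors (N >= 2 samples).
#' @return Non-negative scalar.
#' @examples
#' absolute_change(c(0, 1, 3), c(0, 0, 0), c(0, 0, 0))  # 1
#' @export
absolute_change <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    abort("`x`, `y`, `z` must have equal length")
  }
  if (n < 2) abort("absolute change needs at least 2 samples")
  (sum(abs(diff(x))) + sum(abs(diff(y))) + sum(abs(diff(z)))) / n
}

channel_matrix <- function(window) {
  if (is.matrix(window)) {
    if (!all(SENSOR_CHANNELS %in% colnames(window))) {
      abort("window matrix must have columns ax, ay, az, gx, gy, gz")
    }
    return(window[, SENSOR_CHANNELS, drop = FALSE])
  }
  missing <- setdiff(SENSOR_CHANNELS, names(window))
  if (length(missing)) {
    abort(sprintf("window is missing channel(s): %s",
                  paste(missing, collapse = ", ")))
  }
  as.matrix(as.data.frame(window)[SENSOR_CHANNELS])
}

#' Motion features of a single window
#'
#' Assembles the fixed-order 26-element feature vector of one six-second
#' inertial window: per-channel mean, population variance (divide by N),
#' range (max minus min) and spectral energy for the six channels
#' `ax, ay, az, gx, gy, gz`, followed by the absolute change of the
#' accelerometer triple and of the gyroscope triple.
#'
#' @param window A data frame or matrix with the six channel columns and
#'   at least 2 rows.
#' @return A named numeric vector of length 26 (names
#'   `mean_ax .. se_gz, ac_accel, ac_gyro`).
#' @export
motion_feature_vector <- function(window) {
  m <- channel_matrix(window)
  n <- nrow(m)
  if (n < 2) abort("motion features need a window of at least 2 samples")
  mu <- colMeans(m)
  va <- colMeans(sweep(m, 2, mu)^2)          # population variance
  rg <- apply(m, 2, function(col) max(col) - min(col))
  se <- apply(m, 2, spectral_energy)
  out <- c(mu, va, rg, se,
           absolute_change(m[, "ax"], m[, "ay"], m[, "az"]),
           absolute_change(m[, "gx"], m[, "gy"], m[, "gz"]))
  names(out) <- MOTION_FEATURE_NAMES
  out
}

#' Per-window motion feature matrix
#'
#' Slices a sensor stream into the configured six-second windows and
#' extracts the 26 motion features of each, one row per window.
#'
#' @param stream A `sensor_stream` (or any data frame with `time` and the
#'   six channel columns).
#' @param windows Optional output of [segment_windows()]; defaults to
#'   windows covering the stream.
#' @param config A [har_config()].
#' @return Tibble with `window_index`, `start_time` and the 26 feature
#'   columns.
#' @export
motion_features <- function(stream, windows = NULL, config = har_config()) {
  config <- as_har_config(config)
  windows <- windows %||% segment_windows(stream, config)
  tagged <- assign_windows(stream, windows, config)
  feats <- tagged |>
    dplyr::group_by(.data$window_index) |>
    dplyr::group_modify(function(df, key) {
      as_tibble(as.list(motion_feature_vector(df)))
    }) |>
    dplyr::ungroup()
  dplyr::left_join(windows[c("window_index", "start_time")], feats,
                   by = "window_index")
}
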