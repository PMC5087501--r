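#' Run configuration
#'
#' A single flat configuration object holding every numeric setting of the
#' pipeline. Every constant used anywhere in the package is a named key here
#' so that experiments are fully described by one document; nothing is
#' hard-coded in the stage functions.
#'
#' The shipped defaults reproduce the published operating point of the
#' method: 6-second windows, 50 Hz inertial sampling, 30 Hz skeleton
#' sampling, activity thresholds `t_gyro = 1.3` rad/s and
#' `t_image = 0.023` (hand displacement per frame), and a linear
#' support-vector classifier with probability output.
#'
#' @param window_seconds Segment length in seconds. Default 6.
#' @param sensor_rate_hz Nominal inertial sampling rate. Default 50.
#' @param skeleton_rate_hz Nominal skeleton frame rate. Default 30.
#' @param accel_range_g Accelerometer full scale; samples are clipped to
#'   `[-accel_range_g, accel_range_g]` g. Default 2.
#' @param gyro_range_rad Gyroscope full scale in rad/s; clipped likewise.
#'   Default 4.
#' @param t_gyro Gyroscope activity threshold in rad/s used to binarize the
#'   wrist angular-velocity magnitude. Default 1.3.
#' @param t_image Image activity threshold (hand displacement per frame, in
#'   the skeleton coordinate unit) used to binarize hand velocity.
#'   Default 0.023.
#' @param t_gyro_grid,t_image_grid Numeric grids searched by
#'   [fit_thresholds()]. Defaults span the sensor ranges: 0..4 rad/s in
#'   steps of 0.05, and 0..0.1 in steps of 0.001.
#' @param median_filter_len Odd length of the median filter applied to
#'   velocity series on the comparison clock. Default 5.
#' @param comparison_rate_hz Common clock both modalities are aggregated to
#'   (per-second maximum) before binarization. Default 1.
#' @param invalid_epsilon Windows where every candidate's normalized cross
#'   correlation lies within this distance of 0 are dropped as invalid for
#'   mapping. Default 0.05.
#' @param watch_hand Which hand wears the watch, `"left"` or `"right"`.
#'   Default `"left"`.
#' @param svm_cost Regularization constant of the linear SVM. Default 1.
#' @param cv_folds Internal stratified cross-validation folds used when
#'   scoring candidate groupings. Default 5.
#' @param ehd_threshold Minimum oriented-edge filter response for a 2x2
#'   block to count as an edge in the edge-histogram descriptor, on a 0-255
#'   intensity scale. Default 11.
#' @param zenith_bins,azimuth_bins Bin counts of the skeleton shape
#'   histogram. Defaults 7 and 10.
#' @param motion_only_labels The activity labels recognisable from the
#'   wrist sensor alone, used when the subject is outside the camera view.
#' @param classifier Optional classifier contract as returned by
#'   [svm_classifier()]; any list with the same `fit`/`predict`/
#'   `predict_prob` signature can be injected (e.g. a deterministic oracle
#'   in tests). `NULL` means the default linear SVM.
#' @param seed Integer seed controlling fold assignment and any other
#'   randomised internals.
#' @param ... Additional named overrides stored verbatim.
#'
#' @return A named list with class `"har_config"`.
#' @examples
#' cfg <- har_config()
#' cfg$t_gyro
#' @export
har_config <- function(window_seconds = 6,
                       sensor_rate_hz = 50,
                       skeleton_rate_hz = 30,
                       accel_range_g = 2,
                       gyro_range_rad = 4,
                       t_gyro = 1.3,
                       t_image = 0.023,
                       t_gyro_grid = seq(0, 4, by = 0.05),
                       t_image_grid = seq(0, 0.1, by = 0.001),
                       median_filter_len = 5,
                       comparison_rate_hz = 1,
                       invalid_epsilon = 0.05,
                       watch_hand = c("left", "right"),
                       svm_cost = 1,
                       cv_folds = 5,
                       ehd_threshold = 11,
                       zenith_bins = 7,
                       azimuth_bins = 10,
                       motion_only_labels = c("running", "sitting",
                                              "standing", "walking"),
                       classifier = NULL,
                       seed = 1L,
                       ...) {
  watch_hand <- match.arg(watch_hand)
  cfg <- list(
    window_seconds = window_seconds,
    sensor_rate_hz = sensor_rate_hz,
    skeleton_rate_hz = skeleton_rate_hz,
    accel_range_g = accel_range_g,
    gyro_range_rad = gyro_range_rad,
    t_gyro = t_gyro,
    t_image = t_image,
    t_gyro_grid = t_gyro_grid,
    t_image_grid = t_image_grid,
    median_filter_len = median_filter_len,
    comparison_rate_hz = comparison_rate_hz,
    invalid_epsilon = invalid_epsilon,
    watch_hand = watch_hand,
    svm_cost = svm_cost,
    cv_folds = cv_folds,
    ehd_threshold = ehd_threshold,
    zenith_bins = zenith_bins,
    azimuth_bins = azimuth_bins,
    motion_only_labels = sort(motion_only_labels),
    classifier = classifier,
    seed = as.integer(seed)
  )
  extra <- list(...)
  if (length(extra)) cfg <- modifyList(cfg, extra)
  numeric_keys <- c(
    "window_seconds", "sensor_rate_hz", "skeleton_rate_hz", "accel_range_g",
    "gyro_range_rad", "median_filter_len", "comparison_rate_hz", "svm_cost",
    "cv_folds", "ehd_threshold", "zenith_bins", "azimuth_bins"
  )
  for (key in numeric_keys) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 || cfg[[key]] <= 0) {
      abort(sprintf("config key `%s` must be a single positive number", key))
    }
  }
  if (cfg$t_gyro < 0 || cfg$t_image < 0) {
    abort("thresholds `t_gyro` and `t_image` must be non-negative")
  }
  if (cfg$median_filter_len %% 2 != 1) {
    abort("`median_filter_len` must be odd")
  }
  structure(cfg, class = "har_config")
}

#' @export
print.har_config <- function(x, ...) {
  cat("<har_config>\n")
  for (key in names(x)) {
    val <- x[[key]]
    if (is.function(val) || is.list(val) && !is.null(val)) {
      if (key == "classifier") {
        cat(sprintf("  %s: %s\n", key,
                    if (is.null(val)) "default linear SVM" else "injected"))
        next
      }
    }
    if (is.numeric(val) && length(val) > 4) {
      cat(sprintf("  %s: [%g .. %g] (%d values)\n", key, min(val), max(val),
                  length(val)))
    } else {
      cat(sprintf("  %s: %s\n", key, paste(format(val), collapse = ", ")))
    }
  }
  invisible(x)
}

as_har_config <- function(config) {
  if (inherits(config, "har_config")) return(config)
  if (is.null(config)) return(har_config())
  if (is.list(config)) return(do.call(har_config, config))
  abort("`config` must be a har_config or a named list")
}

#' Read / write a flat YAML-style configuration file
#'
#' The on-disk format is one `key: value` pair per line; vector values are
#' comma-separated. Round-trips through [har_config()].
#'
#' @param path File path.
#' @return For `read_config()`, a `har_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  parsed <- lapply(vals, function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(parsed) <- trimws(keys)
  do.call(har_config, parsed)
}

#' @param config A `har_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  config <- as_har_config(config)
  keep <- vapply(config, function(v) is.numeric(v) || is.character(v),
                 logical(1))
  lines <- vapply(names(config)[keep], function(key) {
    sprintf("%s: %s", key, paste(format(config[[key]], digits = 12),
                                 collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
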