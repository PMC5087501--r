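#' Read a wrist-sensor CSV stream
#'
#' Expects the columns `time,ax,ay,az,gx,gy,gz`: time in seconds, the
#' accelerometer triple in g and the gyroscope triple in rad/s. Rows are
#' sorted by time; samples outside the configured full-scale ranges are
#' clipped with a warning (transient saturation is expected from wrist-worn
#' devices and should not invalidate a recording).
#'
#' @param path Path to the CSV file.
#' @param subject_id Identifier attached to the stream; defaults to the
#'   file name without extension.
#' @param config A [har_config()].
#' @return A `sensor_stream`: a tibble with columns
#'   `time, ax, ay, az, gx, gy, gz` and attributes `subject_id`, `rate_hz`.
#' @export
read_sensor_csv <- function(path, subject_id = NULL, config = har_config()) {
  config <- as_har_config(config)
  df <- read.csv(path, check.names = TRUE)
  required <- c("time", SENSOR_CHANNELS)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("sensor CSV `%s` is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  sensor_stream(as_tibble(df[required]),
                subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                config = config)
}

#' Construct and validate a sensor stream
#'
#' @param data Data frame with columns `time, ax, ay, az, gx, gy, gz`.
#' @inheritParams read_sensor_csv
#' @return A validated `sensor_stream` tibble, sorted by time.
#' @export
sensor_stream <- function(data, subject_id = "S1", config = har_config()) {
  config <- as_har_config(config)
  data <- as_tibble(data)[, c("time", SENSOR_CHANNELS)]
  if (nrow(data) == 0) abort("sensor stream is empty")
  data <- dplyr::arrange(data, .data$time)
  if (anyNA(data)) abort("sensor stream contains missing values")
  if (any(diff(data$time) <= 0)) {
    abort("sensor timestamps must be strictly increasing after sorting")
  }
  acc <- as.matrix(data[c("ax", "ay", "az")])
  gyr <- as.matrix(data[c("gx", "gy", "gz")])
  n_clip <- sum(abs(acc) > config$accel_range_g) +
    sum(abs(gyr) > config$gyro_range_rad)
  if (n_clip > 0) {
    warn(sprintf("clipped %d out-of-range sensor sample(s) to full scale",
                 n_clip))
    data[c("ax", "ay", "az")] <- as_tibble(
      pmin(pmax(acc, -config$accel_range_g), config$accel_range_g))
    data[c("gx", "gy", "gz")] <- as_tibble(
      pmin(pmax(gyr, -config$gyro_range_rad), config$gyro_range_rad))
  }
  structure(data,
            subject_id = subject_id,
            rate_hz = config$sensor_rate_hz,
            class = c("sensor_stream", class(tibble())))
}

#' @param stream A `sensor_stream`.
#' @rdname read_sensor_csv
#' @export
write_sensor_csv <- function(stream, path) {
  write.csv(as.data.frame(stream)[c("time", SENSOR_CHANNELS)], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a skeleton track (JSON-lines or long CSV)
#'
#' `read_skeleton_jsonl()` expects one frame per line:
#' `{"t": <seconds>, "joints": {"left_hand": [x, y, z], ...}}` with the 12
#' canonical joint names (head, left/right elbow, left/right hand,
#' left/right knee, left/right foot, hip center, left/right hip).
#' `read_skeleton_csv()` reads the long form `time,joint,x,y,z`. Joints
#' absent from a frame are kept as rows with `NA` coordinates so that
#' downstream stages can honour the missing-data mask; an unknown joint
#' name is a format error.
#'
#' @param path Path to the file.
#' @param track_id Identifier attached to the track; defaults to the file
#'   name without extension.
#' @return A `skeleton_stream`: a long tibble with columns
#'   `time, joint, x, y, z` (12 rows per frame) and attribute `track_id`.
#' @export
read_skeleton_jsonl <- function(path, track_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("skeleton file `%s` is empty", path))
  frames <- purrr::map(lines, function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    if (is.null(rec$t) || is.null(rec$joints)) {
      abort("each skeleton JSONL line needs fields `t` and `joints`")
    }
    joints <- rec$joints
    unknown <- setdiff(names(joints), JOINT_NAMES)
    if (length(unknown)) {
      abort(sprintf("unknown joint name(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    coords <- matrix(NA_real_, nrow = length(JOINT_NAMES), ncol = 3,
                     dimnames = list(JOINT_NAMES, c("x", "y", "z")))
    for (joint in names(joints)) coords[joint, ] <- as.numeric(joints[[joint]])
    tibble(time = as.numeric(rec$t), joint = JOINT_NAMES,
           x = unname(coords[, "x"]), y = unname(coords[, "y"]),
           z = unname(coords[, "z"]))
  })
  skeleton_stream(dplyr::bind_rows(frames),
                  track_id = track_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_skeleton_jsonl
#' @export
read_skeleton_csv <- function(path, track_id = NULL) {
  df <- read.csv(path)
  required <- c("time", "joint", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("skeleton CSV `%s` is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  skeleton_stream(as_tibble(df[required]),
                  track_id = track_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct and validate a skeleton stream
#'
#' @param data Long data frame `time, joint, x, y, z`; frames missing some
#'   of the 12 joints are completed with `NA` coordinate rows.
#' @param track_id Track identifier.
#' @return A validated `skeleton_stream` tibble sorted by time.
#' @export
skeleton_stream <- function(data, track_id = "T1") {
  data <- as_tibble(data)[, c("time", "joint", "x", "y", "z")]
  if (nrow(data) == 0) abort("skeleton stream is empty")
  unknown <- setdiff(unique(data$joint), JOINT_NAMES)
  if (length(unknown)) {
    abort(sprintf("unknown joint name(s): %s", paste(unknown, collapse = ", ")))
  }
  data <- tidyr::complete(data, time = unique(data$time),
                          joint = JOINT_NAMES,
                          fill = list(x = NA_real_, y = NA_real_, z = NA_real_))
  data <- dplyr::arrange(data, .data$time,
                         match(.data$joint, JOINT_NAMES))
  times <- unique(data$time)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("skeleton frame times must be strictly increasing")
  }
  structure(data,
            track_id = track_id,
            class = c("skeleton_stream", class(tibble())))
}

#' @param stream A `skeleton_stream`.
#' @rdname read_skeleton_jsonl
#' @export
write_skeleton_jsonl <- function(stream, path) {
  frames <- split(as.data.frame(stream), stream$time)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (frame in frames) {
    present <- frame[!is.na(frame$x), , drop = FALSE]
    joints <- setNames(
      lapply(seq_len(nrow(present)),
             function(i) c(present$x[i], present$y[i], present$z[i])),
      present$joint)
    writeLines(jsonlite::toJSON(list(t = frame$time[[1]], joints = joints),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Cut a recording into consecutive six-second windows
#'
#' Windows are non-overlapping, assigned by the half-open interval
#' `[start, start + window_seconds)`; a trailing partial window is dropped.
#' A four-minute recording therefore yields 40 labelled segments at the
#' default six-second window.
#'
#' @param duration Recording duration in seconds (scalar) or a
#'   `sensor_stream`/`skeleton_stream` whose time span is used.
#' @param config A [har_config()].
#' @param origin Start time of the first window; defaults to 0 for a
#'   scalar duration and to the stream's first timestamp otherwise.
#' @return Tibble with columns `window_index` (1-based), `start_time`,
#'   `end_time`; zero rows when the duration is shorter than one window.
#' @examples
#' segment_windows(240)  # 40 windows
#' @export
segment_windows <- function(duration, config = har_config(), origin = NULL) {
  config <- as_har_config(config)
  if (is.data.frame(duration)) {
    origin <- origin %||% min(duration$time)
    # span up to the end of the last sample period, not just the last stamp
    times <- sort(unique(duration$time))
    period <- if (!is.null(attr(duration, "rate_hz"))) {
      1 / attr(duration, "rate_hz")
    } else if (length(times) > 1) {
      median(diff(times))
    } else {
      0
    }
    duration <- max(times) - min(times) + period
  }
  origin <- origin %||% 0
  if (!is.numeric(duration) || duration < 0) {
    abort("`duration` must be a non-negative number of seconds")
  }
  n <- floor(duration / config$window_seconds)
  if (n == 0) {
    return(tibble(window_index = integer(), start_time = numeric(),
                  end_time = numeric()))
  }
  start <- origin + (seq_len(n) - 1) * config$window_seconds
  tibble(window_index = seq_len(n), start_time = start,
         end_time = start + config$window_seconds)
}

#' Slice a stream into per-window sample sets
#'
#' @param stream A `sensor_stream` or `skeleton_stream`.
#' @param windows Output of [segment_windows()]; defaults to windows
#'   covering the stream.
#' @inheritParams segment_windows
#' @return The stream with an added `window_index` column; samples falling
#'   outside every window are dropped.
#' @export
assign_windows <- function(stream, windows = NULL, config = har_config()) {
  config <- as_har_config(config)
  windows <- windows %||% segment_windows(stream, config)
  idx <- findInterval(stream$time, c(windows$start_time,
                                     max(windows$end_time)))
  idx[stream$time >= max(windows$end_time)] <- NA_integer_
  idx[idx == 0] <- NA_integer_
  out <- dplyr::mutate(stream, window_index = windows$window_index[idx])
  dplyr::filter(out, !is.na(.data$window_index))
}
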