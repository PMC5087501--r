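# Visual features: a 7x10 spherical shape histogram of the 12 tracked
# joints in hip-centred coordinates accumulated over a six-second window,
# plus an MPEG-7-style edge histogram descriptor (16 sub-images x 5 edge
# types) of the hand-region crop.

#' Per-frame hand velocity from a skeleton track
#'
#' First differences of the joint position between consecutive frames,
#' combined as the Euclidean norm of the per-axis differences. Units are
#' displacement per frame, matching the image activity threshold
#' `t_image`; translating the whole skeleton leaves the series unchanged.
#'
#' @param stream A `skeleton_stream`.
#' @param joint Joint name; defaults to the watch hand (`left_hand` for
#'   the default configuration).
#' @param config A [har_config()].
#' @return Tibble `time, velocity` with one row per consecutive frame pair
#'   (the time stamp of the later frame); frames where the joint is
#'   missing break the chain and contribute no rows.
#' @export
hand_velocity <- function(stream, joint = NULL, config = har_config()) {
  config <- as_har_config(config)
  joint <- joint %||% paste0(config$watch_hand, "_hand")
  if (!joint %in% JOINT_NAMES) {
    abort(sprintf("unknown joint `%s`", joint))
  }
  pos <- dplyr::filter(stream, .data$joint == !!joint, !is.na(.data$x))
  if (nrow(pos) < 2) {
    abort(sprintf("joint `%s` is tracked for fewer than 2 frames", joint))
  }
  pos <- dplyr::arrange(pos, .data$time)
  tibble(
    time = pos$time[-1],
    velocity = sqrt(diff(pos$x)^2 + diff(pos$y)^2 + diff(pos$z)^2)
  )
}

#' Spherical shape histogram of a skeleton window
#'
#' Each tracked joint of each frame is expressed in spherical coordinates
#' about the hip centre and binned by zenith angle (7 equal bins over
#' `[0, pi]`, measured from the vertical `+y` axis of the camera frame)
#' and azimuth angle (10 equal bins over `[0, 2*pi)`, measured in the
#' horizontal x-z plane from `+x`). Counts over the window are normalized
#' to sum to 1. The hip centre itself sits at radius 0 and is skipped, as
#' is any joint coincident with it; frames without a hip centre are
#' excluded entirely.
#'
#' @param window A `skeleton_stream` (or its subset covering one
#'   six-second window).
#' @param config A [har_config()].
#' @return Named numeric vector `sh_00 .. sh_69` summing to 1; bin
#'   `sh_{10*zenith + azimuth}`.
#' @export
shape_histogram <- function(window, config = har_config()) {
  config <- as_har_config(config)
  nz <- config$zenith_bins
  na <- config$azimuth_bins
  df <- as_tibble(window)
  hips <- dplyr::filter(df, .data$joint == "hip_center", !is.na(.data$x))
  if (nrow(hips) == 0) {
    abort("shape histogram needs at least one frame with a hip centre")
  }
  joints <- dplyr::filter(df, .data$joint != "hip_center", !is.na(.data$x))
  joints <- dplyr::inner_join(joints, hips, by = "time",
                              suffix = c("", "_hip"))
  counts <- matrix(0, nrow = nz, ncol = na)
  if (nrow(joints) > 0) {
    dx <- joints$x - joints$x_hip
    dy <- joints$y - joints$y_hip
    dz <- joints$z - joints$z_hip
    r <- sqrt(dx^2 + dy^2 + dz^2)
    keep <- r > 0
    if (any(keep)) {
      theta <- acos(pmin(pmax(dy[keep] / r[keep], -1), 1))
      phi <- atan2(dz[keep], dx[keep]) %% (2 * pi)
      zi <- pmin(floor(theta / (pi / nz)), nz - 1)
      ai <- pmin(floor(phi / (2 * pi / na)), na - 1)
      tab <- table(factor(zi, levels = 0:(nz - 1)),
                   factor(ai, levels = 0:(na - 1)))
      counts <- counts + unclass(tab)
    }
  }
  total <- sum(counts)
  h <- if (total > 0) as.vector(t(counts)) / total else as.vector(t(counts))
  names(h) <- sprintf("sh_%02d", seq_along(h) - 1)
  h
}

ehd_filters <- list(
  vertical        = matrix(c(1, 1, -1, -1), 2, 2),   # column-major: a,c,b,d
  horizontal      = matrix(c(1, -1, 1, -1), 2, 2),
  diag45          = matrix(c(sqrt(2), 0, 0, -sqrt(2)), 2, 2),
  diag135         = matrix(c(0, -sqrt(2), sqrt(2), 0), 2, 2),
  non_directional = matrix(c(2, -2, -2, 2), 2, 2)
)

#' Edge histogram descriptor of a grayscale crop
#'
#' MPEG-7-style descriptor of the hand-region crop: the crop is divided
#' into 4x4 sub-images, each sub-image into non-overlapping 2x2-pixel
#' blocks, and each block is classified by the strongest of five oriented
#' edge operators (vertical, horizontal, 45 degrees, 135 degrees,
#' non-directional) provided that response exceeds `ehd_threshold`
#' (default 11 on a 0-255 intensity scale). Per-sub-image 5-bin counts are
#' normalized by the number of blocks in the sub-image.
#'
#' @param crop Numeric matrix of grayscale intensities (0-255 scale), at
#'   least 16 x 16 pixels.
#' @param config A [har_config()].
#' @return Named numeric vector `ehd_00 .. ehd_79`, each entry in
#'   `[0, 1]`: sub-images in row-major order, five edge types
#'   (vertical, horizontal, 45, 135, non-directional) within each.
#' @export
edge_histogram <- function(crop, config = har_config()) {
  config <- as_har_config(config)
  if (!is.matrix(crop) || !is.numeric(crop)) {
    abort("`crop` must be a numeric matrix")
  }
  if (nrow(crop) < 16 || ncol(crop) < 16) {
    abort("`crop` must be at least 16x16 pixels")
  }
  sub_rows <- floor(nrow(crop) / 4)
  sub_cols <- floor(ncol(crop) / 4)
  out <- numeric(0)
  for (si in 0:3) {
    for (sj in 0:3) {
      sub <- crop[si * sub_rows + seq_len(sub_rows),
                  sj * sub_cols + seq_len(sub_cols), drop = FALSE]
      nbr <- floor(nrow(sub) / 2)
      nbc <- floor(ncol(sub) / 2)
      bins <- numeric(5)
      n_blocks <- nbr * nbc
      if (n_blocks > 0) {
        a <- sub[2 * seq_len(nbr) - 1, 2 * seq_len(nbc) - 1, drop = FALSE]
        b <- sub[2 * seq_len(nbr) - 1, 2 * seq_len(nbc), drop = FALSE]
        cc <- sub[2 * seq_len(nbr), 2 * seq_len(nbc) - 1, drop = FALSE]
        d <- sub[2 * seq_len(nbr), 2 * seq_len(nbc), drop = FALSE]
        resp <- vapply(ehd_filters, function(f) {
          as.vector(abs(f[1, 1] * a + f[1, 2] * b + f[2, 1] * cc + f[2, 2] * d))
        }, numeric(n_blocks))
        resp <- matrix(resp, nrow = n_blocks)
        best <- max.col(resp, ties.method = "first")
        strong <- resp[cbind(seq_len(n_blocks), best)] > config$ehd_threshold
        bins <- tabulate(best[strong], nbins = 5) / n_blocks
      }
      out <- c(out, bins)
    }
  }
  names(out) <- sprintf("ehd_%02d", seq_along(out) - 1)
  out
}

#' Visual feature vector of one window
#'
#' Concatenation of the 70-bin skeleton shape histogram and the 80-bin
#' edge histogram descriptor of the hand-region crop, in that fixed order
#' (length 150). The crop may be supplied as a grayscale matrix or as a
#' precomputed 80-value descriptor; with `crop = NULL` the 70-bin
#' shape-only variant is returned and flagged via the `"ehd"` attribute.
#'
#' @param window A `skeleton_stream` window.
#' @param crop Grayscale matrix, precomputed length-80 descriptor, or
#'   `NULL` to omit the edge histogram.
#' @param config A [har_config()].
#' @return Named numeric vector of length 150 (or 70 when `crop` is
#'   `NULL`) with attribute `ehd` indicating whether the edge part is
#'   present.
#' @export
visual_feature_vector <- function(window, crop = NULL, config = har_config()) {
  config <- as_har_config(config)
  sh <- shape_histogram(window, config)
  if (is.null(crop)) {
    return(structure(sh, ehd = FALSE))
  }
  ehd <- if (is.matrix(crop)) {
    edge_histogram(crop, config)
  } else {
    crop <- as.numeric(crop)
    if (length(crop) != 80) {
      abort("a precomputed edge descriptor must have length 80")
    }
    setNames(crop, sprintf("ehd_%02d", 0:79))
  }
  structure(c(sh, ehd), ehd = TRUE)
}

#' Per-window visual feature matrix
#'
#' @param stream A `skeleton_stream`.
#' @param crops Optional list (one element per window) of grayscale crops
#'   or precomputed 80-value edge descriptors; `NULL` entries omit the
#'   edge part for that window.
#' @param windows Optional [segment_windows()] output.
#' @param config A [har_config()].
#' @return Tibble with `window_index`, `start_time` and feature columns
#'   `sh_00..sh_69` (plus `ehd_00..ehd_79` when crops are supplied).
#' @export
visual_features <- function(stream, crops = NULL, windows = NULL,
                            config = har_config()) {
  config <- as_har_config(config)
  windows <- windows %||% segment_windows(stream, config)
  tagged <- assign_windows(stream, windows, config)
  rows <- purrr::map(windows$window_index, function(wi) {
    win <- dplyr::filter(tagged, .data$window_index == wi)
    crop <- if (is.null(crops)) NULL else crops[[wi]]
    as_tibble(as.list(visual_feature_vector(win, crop, config)))
  })
  dplyr::bind_cols(windows[c("window_index", "start_time")],
                   dplyr::bind_rows(rows))
}
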