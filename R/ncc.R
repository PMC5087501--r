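# Watch-to-skeleton binding. The wrist angular-velocity magnitude and the
# image-side hand velocity are aggregated to a common 1 Hz clock
# (per-second maximum), median filtered, binarized at the activity
# thresholds, and compared window-by-window with a normalized cross
# correlation on the binary series; per-window argmax votes accumulate
# into the final track-to-stream assignment.

#' Wrist angular-velocity magnitude
#'
#' Per-sample Euclidean norm of the three gyroscope channels; the overall
#' motion level of the watch-wearing hand.
#'
#' @param stream A `sensor_stream`.
#' @return Tibble `time, velocity` (rad/s).
#' @export
gyro_velocity <- function(stream) {
  tibble(time = stream$time,
         velocity = sqrt(stream$gx^2 + stream$gy^2 + stream$gz^2))
}

#' Median-filter a velocity series
#'
#' Sliding-window median with edge replication; length preserved.
#' `filter_len = 1` is the identity.
#'
#' @param series Tibble `time, velocity` or a plain numeric vector.
#' @param filter_len Odd window length (default from `config`).
#' @param config A [har_config()].
#' @return Same shape as the input.
#' @export
median_smooth <- function(series, filter_len = NULL, config = har_config()) {
  config <- as_har_config(config)
  k <- filter_len %||% config$median_filter_len
  if (k %% 2 != 1 || k < 1) abort("`filter_len` must be odd and >= 1")
  x <- if (is.data.frame(series)) series$velocity else series
  if (k > 1 && length(x) > 1) {
    h <- (k - 1) / 2
    padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
    sm <- runmed(padded, k, endrule = "keep")
    x <- sm[h + seq_along(x)]
  }
  if (is.data.frame(series)) {
    series$velocity <- as.numeric(x)
    series
  } else {
    as.numeric(x)
  }
}

#' Aggregate a velocity series to the comparison clock
#'
#' Both modalities run on different native clocks (50 Hz inertial, 30 Hz
#' skeleton); before binarization each is reduced to a common 1 Hz clock
#' by taking the per-second maximum, which preserves brief hand motions at
#' either native rate.
#'
#' @param series Tibble `time, velocity`.
#' @param config A [har_config()].
#' @return Tibble `time, velocity` with one row per comparison-clock tick
#'   (tick start time).
#' @export
aggregate_velocity <- function(series, config = har_config()) {
  config <- as_har_config(config)
  step <- 1 / config$comparison_rate_hz
  series |>
    dplyr::mutate(tick = floor(.data$time / step) * step) |>
    dplyr::group_by(.data$tick) |>
    dplyr::summarise(velocity = max(.data$velocity), .groups = "drop") |>
    dplyr::rename(time = "tick")
}

#' Binarize a velocity series at an activity threshold
#'
#' Strictly-greater comparison: a tick is active (1) when the velocity
#' exceeds the threshold, else 0.
#'
#' @param series Tibble `time, velocity` or numeric vector.
#' @param threshold Non-negative scalar.
#' @return Tibble `time, active` (or an integer vector), with the
#'   threshold stored in attribute `threshold`.
#' @export
binarize_activity <- function(series, threshold) {
  if (!is.numeric(threshold) || threshold < 0) {
    abort("`threshold` must be a non-negative scalar")
  }
  x <- if (is.data.frame(series)) series$velocity else series
  active <- as.integer(x > threshold)
  if (is.data.frame(series)) {
    structure(tibble(time = series$time, active = active),
              threshold = threshold)
  } else {
    active
  }
}

#' Normalized cross correlation of two binary activity series
#'
#' `sum(gt * it) / sqrt(sum(gt^2) * sum(it^2))`. For 0/1 series this lies
#' in `[0, 1]`; when either series is all zero the value is undefined and
#' `NA` is returned.
#'
#' @param gt,it Equal-length 0/1 vectors (or tibbles with an `active`
#'   column on a shared clock).
#' @return Scalar in `[0, 1]`, or `NA` when undefined.
#' @examples
#' ncc_score(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
#' @export
ncc_score <- function(gt, it) {
  if (is.data.frame(gt)) gt <- gt$active
  if (is.data.frame(it)) it <- it$active
  if (length(gt) != length(it)) {
    abort("binary series must have equal length on a shared clock")
  }
  denom <- sqrt(sum(gt^2) * sum(it^2))
  if (denom == 0) return(NA_real_)
  sum(gt * it) / denom
}

# Threshold-fit objective for one (t_gyro, t_image) cell:
# matches / max(#gyro-active, #image-active) - matches / D.
threshold_objective_scalar <- function(gv, iv, t_gyro, t_image) {
  gt <- as.integer(gv > t_gyro)
  it <- as.integer(iv > t_image)
  matches <- sum(gt * it)
  top <- max(sum(gt), sum(it))
  first <- if (top == 0) 0 else matches / top
  first - matches / length(gv)
}

#' Fit the activity thresholds by grid search
#'
#' Given paired gyroscope/image velocity series recorded from the same
#' subject, searches the configured threshold grids for the pair
#' `(t_gyro, t_image)` maximizing
#' `matches / max(n_gyro_active, n_image_active) - matches / D`, where
#' `matches` counts ticks active in both modalities and `D` is the total
#' number of aligned ticks pooled over all pairs. The first term rewards
#' agreement between the two binary indicators, the second penalizes
#' thresholds so low that everything is labelled active. Ties break to the
#' smallest `t_gyro`, then smallest `t_image`.
#'
#' @param pairs List of pairs, each a list with elements `gyro` and
#'   `image`: velocity tibbles (`time, velocity`) from one subject. Series
#'   are aggregated to the comparison clock, optionally median filtered,
#'   and aligned on shared ticks.
#' @param config A [har_config()] providing `t_gyro_grid`, `t_image_grid`,
#'   `median_filter_len` and the comparison clock.
#' @param smooth Apply the median filter before binarization? Default TRUE.
#' @return One-row tibble `t_gyro, t_image, objective, n_points`, with the
#'   full objective surface in attribute `surface` (tibble
#'   `t_gyro, t_image, objective`).
#' @export
fit_thresholds <- function(pairs, config = har_config(), smooth = TRUE) {
  config <- as_har_config(config)
  tg_grid <- config$t_gyro_grid
  ti_grid <- config$t_image_grid
  if (length(tg_grid) == 0 || length(ti_grid) == 0) {
    abort("threshold grids must be non-empty")
  }
  aligned <- purrr::map(pairs, function(pair) {
    g <- aggregate_velocity(as_tibble(pair$gyro), config)
    i <- aggregate_velocity(as_tibble(pair$image), config)
    if (smooth) {
      g <- median_smooth(g, config = config)
      i <- median_smooth(i, config = config)
    }
    shared <- intersect(g$time, i$time)
    tibble(gv = g$velocity[match(shared, g$time)],
           iv = i$velocity[match(shared, i$time)])
  })
  aligned <- dplyr::bind_rows(aligned)
  d <- nrow(aligned)
  if (d < 1) abort("no aligned ticks; pairs do not overlap in time")
  # Vectorized objective over the full grid: binary indicator matrices per
  # grid value, match counts via one matrix product.
  gt <- outer(tg_grid, aligned$gv, FUN = function(t, v) as.numeric(v > t))
  it <- outer(ti_grid, aligned$iv, FUN = function(t, v) as.numeric(v > t))
  matches <- gt %*% t(it)                       # n_tg x n_ti
  top <- outer(rowSums(gt), rowSums(it), pmax)
  first <- ifelse(top == 0, 0, matches / top)
  objective <- first - matches / d
  best <- which(objective == max(objective), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  surface <- tibble(
    t_gyro = rep(tg_grid, times = length(ti_grid)),
    t_image = rep(ti_grid, each = length(tg_grid)),
    objective = as.vector(objective)
  )
  structure(
    tibble(t_gyro = tg_grid[best[[1]]], t_image = ti_grid[best[[2]]],
           objective = max(objective), n_points = d),
    surface = surface
  )
}

binarized_on_clock <- function(velocity, threshold, config, smooth = TRUE) {
  v <- aggregate_velocity(velocity, config)
  if (smooth) v <- median_smooth(v, config = config)
  binarize_activity(v, threshold)
}

#' Bind skeleton tracks to wrist-sensor streams
#'
#' For every (skeleton track, candidate sensor stream) pair, the hand
#' velocity of the track and the angular-velocity magnitude of the stream
#' are binarized on a common clock and compared with [ncc_score()] over
#' consecutive six-second sub-segments. Sub-segments where every
#' candidate's correlation is within `invalid_epsilon` of zero (everyone
#' inactive or equally ambiguous) are dropped as invalid; each remaining
#' sub-segment votes for the candidate with the highest correlation
#' (undefined correlations count as 0), and each track is assigned the
#' sensor with the most votes. A tied vote leaves the track unresolved.
#'
#' @param skeletons Named list of `skeleton_stream`s (names default to
#'   their `track_id` attributes).
#' @param sensors Named list of `sensor_stream`s (names default to their
#'   `subject_id` attributes).
#' @param config A [har_config()].
#' @param exclusive Enforce a one-to-one assignment by maximizing the
#'   total votes over all track-to-stream bijections (searched
#'   exhaustively; intended for the handful of subjects a camera can
#'   track). Default FALSE: independent per-track argmax.
#' @param smooth Median-filter the velocity series first. Default TRUE.
#' @return A `stream_mapping` object: list with tibbles `scores`
#'   (per window x pair correlations and validity), `votes` (per pair),
#'   and `assignment` (per track: chosen sensor, votes, vote share,
#'   `resolved` flag), plus counts of valid/invalid windows.
#' @export
match_streams <- function(skeletons, sensors, config = har_config(),
                          exclusive = FALSE, smooth = TRUE) {
  config <- as_har_config(config)
  if (length(skeletons) < 1 || length(sensors) < 1) {
    abort("need at least one skeleton track and one sensor stream")
  }
  skel_names <- names(skeletons) %||% purrr::map_chr(
    skeletons, function(s) attr(s, "track_id") %||% "track")
  sens_names <- names(sensors) %||% purrr::map_chr(
    sensors, function(s) attr(s, "subject_id") %||% "sensor")
  names(skeletons) <- skel_names
  names(sensors) <- sens_names

  gt <- purrr::map(sensors, function(s) {
    binarized_on_clock(gyro_velocity(s), config$t_gyro, config, smooth)
  })
  it <- purrr::map(skeletons, function(s) {
    binarized_on_clock(hand_velocity(s, config = config), config$t_image,
                       config, smooth)
  })

  all_times <- c(purrr::map(gt, "time"), purrr::map(it, "time"))
  t0 <- max(purrr::map_dbl(all_times, min))
  t1 <- min(purrr::map_dbl(all_times, max))
  if (t1 <= t0) abort("streams do not overlap in time")
  step <- 1 / config$comparison_rate_hz
  clock <- seq(t0, t1, by = step)
  per_window <- round(config$window_seconds * config$comparison_rate_hz)
  n_windows <- floor(length(clock) / per_window)
  if (n_windows < 1) abort("overlap is shorter than one comparison window")
  clock <- clock[seq_len(n_windows * per_window)]
  window_of <- rep(seq_len(n_windows), each = per_window)

  on_clock <- function(series) {
    out <- series$active[match(clock, series$time)]
    out[is.na(out)] <- 0L
    out
  }
  gtm <- purrr::map(gt, on_clock)
  itm <- purrr::map(it, on_clock)

  scores <- tidyr::expand_grid(window_index = seq_len(n_windows),
                               skeleton = skel_names, sensor = sens_names)
  scores$ncc <- purrr::pmap_dbl(scores, function(window_index, skeleton, sensor) {
    sel <- window_of == window_index
    ncc_score(gtm[[sensor]][sel], itm[[skeleton]][sel])
  })

  scores <- scores |>
    dplyr::group_by(.data$window_index, .data$skeleton) |>
    dplyr::mutate(
      ncc_eff = dplyr::coalesce(.data$ncc, 0),
      invalid = all(abs(.data$ncc_eff) <= config$invalid_epsilon)
    ) |>
    dplyr::ungroup()

  valid <- dplyr::filter(scores, !.data$invalid)
  votes <- if (nrow(valid) > 0) {
    valid |>
      dplyr::group_by(.data$window_index, .data$skeleton) |>
      dplyr::filter(sum(.data$ncc_eff == max(.data$ncc_eff)) == 1,
                    .data$ncc_eff == max(.data$ncc_eff)) |>
      dplyr::ungroup() |>
      dplyr::count(.data$skeleton, .data$sensor, name = "votes")
  } else {
    tibble(skeleton = character(), sensor = character(), votes = integer())
  }
  votes <- tidyr::expand_grid(skeleton = skel_names, sensor = sens_names) |>
    dplyr::left_join(votes, by = c("skeleton", "sensor")) |>
    dplyr::mutate(votes = dplyr::coalesce(.data$votes, 0L))

  assignment <- if (exclusive && length(skel_names) <= length(sens_names)) {
    exclusive_assignment(votes, skel_names, sens_names)
  } else {
    votes |>
      dplyr::group_by(.data$skeleton) |>
      dplyr::summarise(
        sensor = if (sum(.data$votes) == 0 ||
                     sum(.data$votes == max(.data$votes)) > 1) {
          NA_character_
        } else {
          .data$sensor[which.max(.data$votes)]
        },
        votes = if (sum(.data$votes) == 0) 0L else max(.data$votes),
        total_votes = sum(.data$votes),
        .groups = "drop"
      )
  }
  assignment <- assignment |>
    dplyr::mutate(
      vote_share = ifelse(.data$total_votes > 0,
                          .data$votes / .data$total_votes, NA_real_),
      resolved = !is.na(.data$sensor)
    )

  structure(
    list(scores = scores, votes = votes, assignment = assignment,
         n_windows = n_windows,
         n_invalid = scores |>
           dplyr::distinct(.data$window_index, .data$skeleton, .data$invalid) |>
           dplyr::filter(.data$invalid) |> nrow(),
         config = config),
    class = "stream_mapping"
  )
}

# One-to-one resolution: exhaustive search over injections of tracks into
# sensors maximizing total votes (small-n by construction).
exclusive_assignment <- function(votes, skel_names, sens_names) {
  vote_mat <- tidyr::pivot_wider(votes, names_from = "sensor",
                                 values_from = "votes")
  vm <- as.matrix(vote_mat[, sens_names, drop = FALSE])
  rownames(vm) <- vote_mat$skeleton
  vm <- vm[skel_names, , drop = FALSE]
  perms <- all_injections(length(skel_names), length(sens_names))
  totals <- vapply(perms, function(p) {
    sum(vm[cbind(seq_along(p), p)])
  }, numeric(1))
  best <- perms[[which.max(totals)]]
  tibble(
    skeleton = skel_names,
    sensor = sens_names[best],
    votes = vm[cbind(seq_along(best), best)],
    total_votes = rowSums(vm)
  )
}

all_injections <- function(k, n) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (cand in remaining) rec(c(prefix, cand), setdiff(remaining, cand))
  }
  rec(integer(0), seq_len(n))
  out
}

#' @export
print.stream_mapping <- function(x, ...) {
  cat(sprintf("<stream_mapping> %d window(s), %d invalid\n",
              x$n_windows, x$n_invalid))
  print(x$assignment)
  invisible(x)
}

#' @export
tidy.stream_mapping <- function(x, ...) x$assignment

#' @export
glance.stream_mapping <- function(x, ...) {
  tibble(n_tracks = nrow(x$assignment),
         n_resolved = sum(x$assignment$resolved),
         n_windows = x$n_windows,
         n_invalid = x$n_invalid)
}

#' Vote-bar diagnostic plot for a mapping result
#'
#' Per skeleton track, the number of six-second sub-segments won by each
#' candidate sensor stream.
#'
#' @param object A `stream_mapping`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stream_mapping <- function(object, ...) {
  ggplot2::ggplot(object$votes,
                  ggplot2::aes(x = .data$sensor, y = .data$votes,
                               fill = .data$sensor)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~skeleton) +
    ggplot2::labs(x = "candidate sensor stream", y = "sub-segment votes",
                  title = "Watch-to-skeleton vote accumulation")
}
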