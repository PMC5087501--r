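# Synthetic multimodal sessions with known ground truth. The generator
# emulates the signal structure the method relies on: activity-conditioned
# accelerometer statistics (standing holds one axis at +1 g), bursty
# on/off wrist motion with exponential dwell times driving both the
# gyroscope magnitude and the image-side hand velocity of the same
# subject, per-activity skeleton poses, and planted group structure for
# the partition search. All generators are pure functions of their
# arguments and a seed.

#' Activity signal profiles
#'
#' One row per supported activity: accelerometer mean orientation (g),
#' noise scale and periodic component, gyroscope noise, burst level
#' (rad/s) and exponential on/off dwell times (s) of the two-state hand
#' motion process, hand-trajectory amplitude (m) and frequency (Hz),
#' posture and hand rest position, and the planted group id used by the
#' grouped-feature generator. The eight camera activities are brushing
#' (BR), calling (CL), computer working (CW), drinking (DK), eating (ET),
#' reading (RD), sitting (ST) and standing (SD); walking, running,
#' sitting and standing profiles support the motion-only fallback.
#'
#' @return A tibble, one row per activity.
#' @export
activity_profiles <- function() {
  tibble::tribble(
    ~activity,  ~group, ~ax, ~ay, ~az, ~accel_sd, ~accel_amp, ~accel_freq,
      ~gyro_sd, ~burst_level, ~on_s, ~off_s, ~hand_amp, ~hand_freq,
      ~posture, ~hand_x, ~hand_y, ~hand_z,
    "BR", "g5", 0.30, 0.80, 0.40, 0.10, 0,    0,   0.15, 2.6, 2.0, 0.5,
      0.10, 3.0, "stand", 0.15, 0.55, -0.10,
    "CL", "g4", 0.10, 0.95, 0.10, 0.03, 0,    0,   0.08, 0.4, 0.5, 4.0,
      0.01, 0.5, "stand", 0.10, 0.60, 0.05,
    "CW", "g2", 0.60, 0.75, 0.20, 0.04, 0,    0,   0.12, 0.9, 1.0, 1.0,
      0.02, 2.5, "sit", 0.20, 0.10, 0.35,
    "DK", "g5", 0.35, 0.80, 0.30, 0.09, 0,    0,   0.14, 2.0, 1.2, 2.0,
      0.12, 0.7, "sit", 0.10, 0.40, 0.10,
    "ET", "g5", 0.30, 0.85, 0.25, 0.08, 0,    0,   0.13, 2.0, 1.0, 1.0,
      0.12, 1.2, "sit", 0.08, 0.45, 0.12,
    "RD", "g3", 0.50, 0.80, 0.10, 0.03, 0,    0,   0.10, 1.8, 0.6, 2.5,
      0.05, 0.8, "sit", 0.12, 0.15, 0.30,
    "ST", "g2", 0.62, 0.74, 0.22, 0.02, 0,    0,   0.05, 0.3, 0.5, 5.0,
      0.01, 0.5, "sit", 0.15, 0.05, 0.25,
    "SD", "g1", 0.00, 1.00, 0.00, 0.015, 0,   0,   0.05, 0.3, 0.5, 5.0,
      0.01, 0.5, "stand", 0.18, -0.15, 0.02,
    "walking", NA, 0.10, 0.95, 0.05, 0.08, 0.40, 1.8, 0.30, 1.5, 2.0, 0.5,
      0.10, 1.8, "stand", 0.18, -0.10, 0.05,
    "running", NA, 0.10, 0.90, 0.10, 0.15, 0.80, 2.6, 0.50, 2.6, 3.0, 0.3,
      0.15, 2.6, "stand", 0.18, -0.05, 0.05,
    "sitting", NA, 0.62, 0.74, 0.22, 0.02, 0,  0,   0.05, 0.3, 0.5, 5.0,
      0.01, 0.5, "sit", 0.15, 0.05, 0.25,
    "standing", NA, 0.00, 1.00, 0.00, 0.015, 0, 0,  0.05, 0.3, 0.5, 5.0,
      0.01, 0.5, "stand", 0.18, -0.15, 0.02
  )
}

#' Planted activity grouping
#'
#' The group structure encoded in [activity_profiles()] for the eight
#' camera activities: standing alone, computer working with sitting,
#' reading alone, calling alone, and the three hand-to-mouth activities
#' (brushing, drinking, eating) together.
#'
#' @return A 5-group partition of the eight activity labels.
#' @export
planted_partition <- function() {
  profiles <- dplyr::filter(activity_profiles(), !is.na(.data$group))
  as_partition(unname(split(profiles$activity, profiles$group)))
}

# Two-state on/off process with exponential dwell times, evaluated at
# arbitrary times. Returns a function of time (0/1).
gen_telegraph <- function(duration, on_s, off_s, start_on = FALSE) {
  if (on_s <= 0) return(function(t) rep(0L, length(t)))
  if (off_s <= 0) return(function(t) rep(1L, length(t)))
  switches <- numeric(0)
  state <- start_on
  t <- 0
  while (t < duration) {
    dwell <- rexp(1, rate = 1 / (if (state) on_s else off_s))
    t <- t + dwell
    switches <- c(switches, t)
    state <- !state
  }
  function(t) {
    k <- findInterval(t, switches)
    as.integer(xor(start_on, k %% 2 == 1L))
  }
}

# Standing / sitting joint offsets relative to the hip centre (camera
# frame: x lateral, y vertical, z depth).
pose_offsets <- function(posture) {
  base <- list(
    head = c(0, 0.75, 0),
    left_elbow = c(0.22, 0.30, 0.05), right_elbow = c(-0.22, 0.30, 0.05),
    right_hand = c(-0.25, 0.05, 0.10),
    left_knee = c(0.10, -0.45, 0.05), right_knee = c(-0.10, -0.45, 0.05),
    left_foot = c(0.12, -0.85, 0.05), right_foot = c(-0.12, -0.85, 0.05),
    hip_center = c(0, 0, 0),
    left_hip = c(0.12, -0.05, 0), right_hip = c(-0.12, -0.05, 0)
  )
  if (posture == "sit") {
    base$left_knee <- c(0.10, -0.35, 0.35)
    base$right_knee <- c(-0.10, -0.35, 0.35)
    base$left_foot <- c(0.12, -0.75, 0.40)
    base$right_foot <- c(-0.12, -0.75, 0.40)
  }
  base
}

#' Generate one subject's multimodal session
#'
#' Produces a 50 Hz inertial stream and a 30 Hz skeleton track whose
#' per-window statistics follow the activity profiles of the schedule:
#' per-activity accelerometer mean/noise (plus a gait oscillation for
#' walking/running), gyroscope bursts from an exponential-dwell on/off
#' hand-motion process, and a skeleton whose watch hand oscillates during
#' the same bursts around an activity-specific rest pose. Deterministic
#' given `seed`.
#'
#' @param schedule Character vector of activity labels, one per
#'   six-second segment (or a tibble `activity, segments`).
#' @param config A [har_config()].
#' @param seed Integer seed.
#' @param subject_id Stream identifier.
#' @param x_offset Lateral position of the subject in the camera frame
#'   (m), so that multi-person scenes do not overlap in space.
#' @return List with `sensor` (a `sensor_stream`), `skeleton` (a
#'   `skeleton_stream`) and `segments` (windows plus `label`).
#' @export
gen_session <- function(schedule, config = har_config(), seed = 1L,
                        subject_id = "S1", x_offset = 0) {
  config <- as_har_config(config)
  if (is.data.frame(schedule)) {
    schedule <- rep(schedule$activity, schedule$segments)
  }
  schedule <- as.character(schedule)
  if (length(schedule) == 0) abort("`schedule` must contain at least one segment")
  profiles <- activity_profiles()
  unknown <- setdiff(schedule, profiles$activity)
  if (length(unknown)) {
    abort(sprintf("no activity profile for: %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  rng <- local_rng(seed)
  rng({
    win <- config$window_seconds
    duration <- length(schedule) * win
    fs <- config$sensor_rate_hz
    fk <- config$skeleton_rate_hz
    ts <- seq(0, duration - 1 / fs, by = 1 / fs)
    tk <- seq(0, duration - 1 / fk, by = 1 / fk)
    seg_s <- pmin(floor(ts / win) + 1, length(schedule))
    seg_k <- pmin(floor(tk / win) + 1, length(schedule))
    prof <- profiles[match(schedule, profiles$activity), ]

    # Per-segment hand-motion burst process shared by both modalities.
    bursts <- purrr::map(seq_along(schedule), function(i) {
      gen_telegraph(win, prof$on_s[i], prof$off_s[i],
                    start_on = runif(1) < prof$on_s[i] /
                      (prof$on_s[i] + prof$off_s[i]))
    })
    eval_burst <- function(times, seg) {
      out <- integer(length(times))
      for (i in unique(seg)) {
        sel <- seg == i
        out[sel] <- bursts[[i]](times[sel] - (i - 1) * win)
      }
      out
    }
    on_s <- eval_burst(ts, seg_s)
    on_k <- eval_burst(tk, seg_k)

    p <- function(col) prof[[col]][seg_s]
    gait <- function(phase) {
      p("accel_amp") * sin(2 * pi * p("accel_freq") * ts + phase)
    }
    accel <- cbind(
      ax = p("ax") + gait(0) + rnorm(length(ts), 0, p("accel_sd")),
      ay = p("ay") + gait(pi / 2) + rnorm(length(ts), 0, p("accel_sd")),
      az = p("az") + gait(pi) + rnorm(length(ts), 0, p("accel_sd"))
    )
    burst_axis <- function(phase) {
      on_s * p("burst_level") / sqrt(3) *
        sin(2 * pi * p("hand_freq") * ts + phase) +
        rnorm(length(ts), 0, p("gyro_sd"))
    }
    gyro <- cbind(gx = burst_axis(0), gy = burst_axis(2 * pi / 3),
                  gz = burst_axis(4 * pi / 3))
    sensor <- sensor_stream(
      tibble(time = ts,
             ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
             gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3]),
      subject_id = subject_id, config = config)

    # Skeleton: activity-specific posture and hand rest position; the
    # watch hand oscillates during bursts.
    pk <- function(col) prof[[col]][seg_k]
    hip_y <- ifelse(pk("posture") == "sit", 0.55, 0.90)
    hip <- cbind(x = x_offset + rnorm(length(tk), 0, 0.002),
                 y = hip_y + rnorm(length(tk), 0, 0.002),
                 z = 2.5 + rnorm(length(tk), 0, 0.002))
    watch_joint <- paste0(config$watch_hand, "_hand")
    frames <- purrr::map(JOINT_NAMES, function(joint) {
      if (joint == watch_joint) {
        ph <- 2 * pi * pk("hand_freq") * tk
        amp <- on_k * pk("hand_amp")
        x <- hip[, "x"] + pk("hand_x") + amp * sin(ph) +
          rnorm(length(tk), 0, 0.003)
        y <- hip[, "y"] + pk("hand_y") + 0.6 * amp * cos(ph) +
          rnorm(length(tk), 0, 0.003)
        z <- hip[, "z"] + pk("hand_z") + 0.3 * amp * sin(ph + 1) +
          rnorm(length(tk), 0, 0.003)
      } else {
        off <- t(vapply(pk("posture"), function(pos) pose_offsets(pos)[[joint]],
                        numeric(3), USE.NAMES = FALSE))
        x <- hip[, "x"] + off[, 1] + rnorm(length(tk), 0, 0.002)
        y <- hip[, "y"] + off[, 2] + rnorm(length(tk), 0, 0.002)
        z <- hip[, "z"] + off[, 3] + rnorm(length(tk), 0, 0.002)
      }
      tibble(time = tk, joint = joint, x = x, y = y, z = z)
    })
    skeleton <- skeleton_stream(dplyr::bind_rows(frames),
                                track_id = subject_id)
    segments <- dplyr::mutate(segment_windows(duration, config),
                              label = schedule)
    list(sensor = sensor, skeleton = skeleton, segments = segments)
  })
}

#' Generate a multi-person mapping scene
#'
#' Builds paired wrist-sensor and skeleton streams for several subjects
#' sharing one camera view, with a known watch-to-track correspondence.
#' Time is tiled into six-second slots; each subject is either active
#' (hand-motion bursts driving both its gyroscope and its skeleton hand)
#' or still in each slot. Subject 1's slots are Bernoulli(`active_frac`);
#' every other subject copies subject 1's slot state with probability
#' `overlap` and takes the opposite state otherwise, so `overlap = 0`
#' gives disjoint schedules and `overlap = 1` identical ones (the
#' unmappable worst case).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param duration Scene length in seconds. Default 900 (15 minutes).
#' @param overlap Schedule-overlap fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param config A [har_config()].
#' @param noise Add sensor noise and within-slot burst structure
#'   (default); `FALSE` produces idealized noise-free streams that are
#'   exactly zero when still.
#' @param active_frac Fraction of slots in which subject 1 is active.
#' @return List with named lists `sensors` and `skeletons`, the
#'   ground-truth `truth` tibble (`skeleton`, `sensor`), and the
#'   per-slot schedule.
#' @export
gen_scene <- function(n_subjects = 2, duration = 900, overlap = 0.3,
                      seed = 1L, config = har_config(), noise = TRUE,
                      active_frac = 0.5) {
  config <- as_har_config(config)
  if (n_subjects < 2) abort("a mapping scene needs at least 2 subjects")
  if (overlap < 0 || overlap > 1) abort("`overlap` must be in [0, 1]")
  rng <- local_rng(seed)
  rng({
    win <- config$window_seconds
    n_slots <- floor(duration / win)
    if (n_slots < 1) abort("`duration` must cover at least one slot")
    duration <- n_slots * win
    slots <- matrix(0L, nrow = n_slots, ncol = n_subjects)
    slots[, 1] <- as.integer(runif(n_slots) < active_frac)
    for (j in seq_len(n_subjects)[-1]) {
      copy <- runif(n_slots) < overlap
      slots[, j] <- ifelse(copy, slots[, 1], 1L - slots[, 1])
    }

    fs <- config$sensor_rate_hz
    fk <- config$skeleton_rate_hz
    ts <- seq(0, duration - 1 / fs, by = 1 / fs)
    tk <- seq(0, duration - 1 / fk, by = 1 / fk)
    slot_s <- pmin(floor(ts / win) + 1, n_slots)
    slot_k <- pmin(floor(tk / win) + 1, n_slots)
    burst_level <- 2.5
    hand_amp <- 0.12
    hand_freq <- 1.5
    gyro_sd <- if (noise) 0.12 else 0
    hand_sd <- if (noise) 0.004 else 0
    ids <- paste0("S", seq_len(n_subjects))

    subjects <- purrr::map(seq_len(n_subjects), function(j) {
      active_slot_s <- slots[slot_s, j]
      active_slot_k <- slots[slot_k, j]
      # Within-slot burst substructure distinguishes co-active subjects.
      tele <- if (noise) {
        gen_telegraph(duration, 2.5, 0.8, start_on = runif(1) < 0.75)
      } else {
        function(t) rep(1L, length(t))
      }
      on_s <- active_slot_s * tele(ts)
      on_k <- active_slot_k * tele(tk)
      ph0 <- runif(1, 0, 2 * pi)
      axis <- function(phase) {
        on_s * burst_level / sqrt(3) *
          sin(2 * pi * hand_freq * ts + ph0 + phase) +
          rnorm(length(ts), 0, gyro_sd)
      }
      sensor <- sensor_stream(
        tibble(time = ts,
               ax = rnorm(length(ts), 0, gyro_sd / 4),
               ay = 1 + rnorm(length(ts), 0, gyro_sd / 4),
               az = rnorm(length(ts), 0, gyro_sd / 4),
               gx = axis(0), gy = axis(2 * pi / 3), gz = axis(4 * pi / 3)),
        subject_id = ids[j], config = config)

      x_off <- (j - (n_subjects + 1) / 2) * 1.2
      hipx <- x_off + rnorm(length(tk), 0, hand_sd / 2)
      hipy <- 0.9 + rnorm(length(tk), 0, hand_sd / 2)
      hipz <- 2.5 + rnorm(length(tk), 0, hand_sd / 2)
      ph <- 2 * pi * hand_freq * tk + ph0
      amp <- on_k * hand_amp
      frames <- purrr::map(JOINT_NAMES, function(joint) {
        off <- pose_offsets("stand")[[joint]] %||% c(0.18, 0.05, 0.05)
        if (joint == paste0(config$watch_hand, "_hand")) {
          tibble(time = tk, joint = joint,
                 x = hipx + 0.18 + amp * sin(ph) + rnorm(length(tk), 0, hand_sd),
                 y = hipy + 0.05 + 0.6 * amp * cos(ph) + rnorm(length(tk), 0, hand_sd),
                 z = hipz + 0.05 + 0.3 * amp * sin(ph + 1) + rnorm(length(tk), 0, hand_sd))
        } else {
          tibble(time = tk, joint = joint,
                 x = hipx + off[1] + rnorm(length(tk), 0, hand_sd / 2),
                 y = hipy + off[2] + rnorm(length(tk), 0, hand_sd / 2),
                 z = hipz + off[3] + rnorm(length(tk), 0, hand_sd / 2))
        }
      })
      skeleton <- skeleton_stream(dplyr::bind_rows(frames), track_id = ids[j])
      list(sensor = sensor, skeleton = skeleton)
    })

    list(
      sensors = setNames(purrr::map(subjects, "sensor"), ids),
      skeletons = setNames(purrr::map(subjects, "skeleton"), ids),
      truth = tibble(skeleton = ids, sensor = ids),
      slots = as_tibble(slots, .name_repair = ~ids) |>
        dplyr::mutate(slot = dplyr::row_number(), .before = 1)
    )
  })
}

#' Generate planted-group feature matrices
#'
#' Gaussian feature matrices with a planted partition: the motion-like
#' matrix separates groups strongly (`group_sep`) but labels within a
#' group only weakly (`within_sep`), while the visual-like matrix
#' separates the positions within each group strongly (`visual_sep`) but
#' reuses the same position prototypes across groups, so activities in
#' different groups can be visually confusable and only the motion-borne
#' group information resolves them.
#'
#' @param n_per_class Samples per activity label (>= 2).
#' @param partition Planted partition; defaults to a 5-group partition of
#'   8 labels shaped like the planted activity grouping.
#' @param group_sep,within_sep Motion-space separation of group means and
#'   of label means within one group, in units of the noise standard
#'   deviation.
#' @param visual_sep Visual-space separation of within-group position
#'   prototypes.
#' @param noise_sd Isotropic noise standard deviation.
#' @param n_motion,n_visual Feature dimensionalities (defaults 26, 150).
#' @param seed Integer seed.
#' @return List with tibbles `motion` and `visual`, the `labels` vector
#'   and the planted `partition`.
#' @export
gen_grouped_features <- function(n_per_class = 50, partition = NULL,
                                 group_sep = 6, within_sep = 0.6,
                                 visual_sep = 4, noise_sd = 1,
                                 n_motion = 26, n_visual = 150, seed = 1L) {
  if (n_per_class < 2) abort("`n_per_class` must be at least 2")
  partition <- as_partition(
    partition %||% list("a1", c("a2", "a3"), "a4", "a5", c("a6", "a7", "a8")))
  rng <- local_rng(seed)
  rng({
    unit <- function(d) {
      v <- rnorm(d)
      v / sqrt(sum(v^2))
    }
    max_size <- max(purrr::map_int(partition, length))
    visual_proto <- purrr::map(seq_len(max_size), ~unit(n_visual))
    rows <- purrr::imap(partition, function(group, gi) {
      g_dir <- unit(n_motion)
      purrr::imap(group, function(label, li) {
        m_mean <- group_sep * g_dir + within_sep * unit(n_motion)
        v_mean <- visual_sep * visual_proto[[li]]
        list(label = label, m = m_mean, v = v_mean)
      })
    })
    rows <- unlist(rows, recursive = FALSE)
    labels <- rep(purrr::map_chr(rows, "label"), each = n_per_class)
    motion <- do.call(rbind, purrr::map(rows, function(r) {
      matrix(rep(r$m, each = n_per_class), nrow = n_per_class) +
        matrix(rnorm(n_per_class * n_motion, 0, noise_sd), n_per_class)
    }))
    visual <- do.call(rbind, purrr::map(rows, function(r) {
      matrix(rep(r$v, each = n_per_class), nrow = n_per_class) +
        matrix(rnorm(n_per_class * n_visual, 0, noise_sd), n_per_class)
    }))
    colnames(motion) <- sprintf("m%02d", seq_len(n_motion))
    colnames(visual) <- sprintf("v%03d", seq_len(n_visual))
    list(motion = as_tibble(motion), visual = as_tibble(visual),
         labels = labels, partition = partition)
  })
}
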