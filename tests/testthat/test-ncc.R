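test_that("gyro velocity is the channel norm and permutation invariant", {
  df <- tibble::tibble(time = 0:2 / 50, ax = 0, ay = 0, az = 0,
                       gx = c(0, 3, 1), gy = c(0, 4, 2), gz = c(0, 0, 2))
  s <- sensor_stream(df)
  v <- gyro_velocity(s)
  expect_equal(v$velocity, c(0, 5, 3))

  permuted <- sensor_stream(dplyr::mutate(df, gx = df$gz, gz = df$gx))
  expect_equal(gyro_velocity(permuted)$velocity, v$velocity)
})

test_that("median smoothing removes spikes, keeps monotone series, keeps length", {
  expect_equal(median_smooth(c(0, 10, 0), 3), c(0, 0, 0))
  expect_equal(median_smooth(c(5, 1, 7, 2), 1), c(5, 1, 7, 2))
  mono <- c(1, 2, 3, 5, 8, 9)
  expect_equal(median_smooth(mono, 3), mono)
  expect_length(median_smooth(rnorm(101), 5), 101)
  expect_error(median_smooth(1:5, 2), "odd")
})

test_that("binarization is a strict comparison on the aggregated clock", {
  expect_equal(binarize_activity(c(1.0, 1.4), 1.3), c(0L, 1L))
  expect_equal(binarize_activity(c(1.3, 1.3), 1.3), c(0L, 0L))  # strict >
  expect_equal(binarize_activity(c(0.2, 0.9), 0), c(1L, 1L))
  expect_true(all(binarize_activity(runif(50), 2) == 0))
  expect_error(binarize_activity(1:3, -1), "non-negative")

  fast <- tibble::tibble(time = seq(0, 2.98, by = 0.02),
                         velocity = rep(c(0.1, 2), 75))
  agg <- aggregate_velocity(fast)
  expect_equal(nrow(agg), 3)               # 1 Hz clock
  expect_equal(agg$velocity, rep(2, 3))    # per-second max survives bursts
})

test_that("ncc matches the worked value and stays within [0, 1]", {
  expect_equal(ncc_score(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(ncc_score(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(ncc_score(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_true(is.na(ncc_score(c(0, 0), c(1, 0))))
  expect_error(ncc_score(c(1, 0), c(1, 0, 1)), "equal length")

  withr::with_seed(9, {
    for (i in 1:50) {
      a <- rbinom(24, 1, runif(1))
      b <- rbinom(24, 1, runif(1))
      n <- ncc_score(a, b)
      if (!is.na(n)) expect_true(n >= 0 && n <= 1)
    }
  })
})

test_that("threshold objective matches the worked value and a brute-force grid", {
  # GT=[1,1,0,0], IT=[1,0,1,0], D=4 -> 1/2 - 1/4
  expect_equal(brute_threshold_objective(c(2, 2, 0, 0), c(1, 0, 1, 0), 1, 0.5),
               0.25)

  withr::with_seed(31, {
    gv <- rexp(200, 1)
    iv <- rexp(200, 10)
    cfg <- har_config(t_gyro_grid = seq(0, 3, by = 0.25),
                      t_image_grid = seq(0, 0.3, by = 0.025))
    pair <- list(list(
      gyro = tibble::tibble(time = seq_along(gv) - 1, velocity = gv),
      image = tibble::tibble(time = seq_along(iv) - 1, velocity = iv)))
    fit <- fit_thresholds(pair, cfg, smooth = FALSE)
    surface <- attr(fit, "surface")
    # independent double loop over the same grid
    best <- -Inf; best_tg <- NA; best_ti <- NA
    for (tg in cfg$t_gyro_grid) {
      for (ti in cfg$t_image_grid) {
        val <- brute_threshold_objective(gv, iv, tg, ti)
        row <- surface[surface$t_gyro == tg & surface$t_image == ti, ]
        expect_equal(row$objective, val, tolerance = 1e-12)
        if (val > best + 1e-12) {
          best <- val; best_tg <- tg; best_ti <- ti
        }
      }
    }
    expect_equal(fit$objective, best, tolerance = 1e-12)
    expect_equal(fit$t_gyro, best_tg)
    expect_equal(fit$t_image, best_ti)
  })
})

test_that("planted thresholds are recovered within one grid step", {
  # Noise-free two-level series: idle gyro 0.2 / active 2.0, idle hand
  # 0.005 / active 0.05, co-active by construction.
  state <- rep(rep(c(0, 1), 10), each = 30)
  t <- seq_along(state) - 1
  pair <- list(list(
    gyro = tibble::tibble(time = t, velocity = ifelse(state == 1, 2, 0.2)),
    image = tibble::tibble(time = t, velocity = ifelse(state == 1, 0.05, 0.005))))
  fit <- fit_thresholds(pair, har_config(), smooth = FALSE)
  expect_gte(fit$t_gyro, 0.2 - 1e-9)
  expect_lt(fit$t_gyro, 0.2 + 0.05 + 1e-9)    # first grid point above idle
  expect_gte(fit$t_image, 0.005 - 1e-9)
  expect_lt(fit$t_image, 0.005 + 0.001 + 1e-9)
  expect_equal(fit$objective, 0.5)             # half the ticks active
})

test_that("default configuration is used when fitting is skipped", {
  cfg <- har_config()
  expect_equal(c(cfg$t_gyro, cfg$t_image), c(1.3, 0.023))
})

test_that("matching binds single and multi-subject scenes to the right sensor", {
  sess <- gen_scene(2, 300, overlap = 0, seed = 5, noise = FALSE)
  single <- match_streams(sess$skeletons["S1"], sess$sensors["S1"])
  expect_equal(tidy(single)$sensor, "S1")
  expect_equal(tidy(single)$vote_share, 1)

  both <- match_streams(sess$skeletons, sess$sensors)
  expect_equal(tidy(both)$sensor, c("S1", "S2"))
  expect_true(all(tidy(both)$resolved))
})

test_that("matching is equivariant under sensor reordering and flags still scenes", {
  scene <- gen_scene(2, 240, overlap = 0.3, seed = 17)
  a <- match_streams(scene$skeletons, scene$sensors)
  b <- match_streams(scene$skeletons, rev(scene$sensors))
  expect_equal(dplyr::arrange(tidy(a), skeleton)$sensor,
               dplyr::arrange(tidy(b), skeleton)$sensor)

  still <- gen_scene(2, 120, overlap = 1, seed = 3, noise = FALSE,
                     active_frac = 0)
  m <- match_streams(still$skeletons, still$sensors)
  expect_false(any(tidy(m)$resolved))
  expect_equal(m$n_invalid, 2 * m$n_windows)

  off <- gen_session("SD", seed = 1)
  late <- dplyr::mutate(off$sensor, time = time + 1000)
  expect_error(
    match_streams(list(S1 = off$skeleton),
                  list(S1 = sensor_stream(late))),
    "overlap")
})

test_that("mapping accuracy degrades on average as schedules converge", {
  acc <- vapply(c(0.2, 1), function(ov) {
    hits <- 0
    for (s in 1:4) {
      sc <- gen_scene(2, 300, overlap = ov, seed = 100 + s)
      res <- tidy(match_streams(sc$skeletons, sc$sensors))
      hits <- hits + sum(!is.na(res$sensor) & res$sensor == res$skeleton)
    }
    hits / 8
  }, numeric(1))
  expect_gte(acc[1], acc[2])
  expect_equal(acc[1], 1)
})
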