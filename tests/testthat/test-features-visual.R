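test_that("hand velocity differences positions and ignores translation", {
  frames <- tibble::tibble(
    time = rep(0:4 / 30, each = 2),
    joint = rep(c("left_hand", "hip_center"), 5),
    x = c(rbind(0:4 * 1.0, rep(0, 5))),     # hand moves +1 per frame in x
    y = 0, z = 0
  )
  sk <- skeleton_stream(frames)
  v <- hand_velocity(sk, "left_hand")
  expect_equal(nrow(v), 4)
  expect_equal(v$velocity, rep(1, 4))

  static <- dplyr::mutate(frames, x = 2)
  expect_equal(hand_velocity(skeleton_stream(static), "left_hand")$velocity,
               rep(0, 4))

  translated <- dplyr::mutate(frames, x = x + 10, y = y - 3, z = z + 1)
  expect_equal(hand_velocity(skeleton_stream(translated), "left_hand")$velocity,
               v$velocity)

  expect_error(hand_velocity(sk, "left_foot"), "fewer than 2 frames")
  expect_error(hand_velocity(sk, "wrist"), "unknown joint")
})

test_that("shape histogram puts a vertical joint in zenith bin 0 and normalizes", {
  sk <- toy_skeleton_frame("head", at = c(0, 1, 0))  # straight up from hip
  h <- shape_histogram(sk)
  expect_length(h, 70)
  expect_equal(h[["sh_00"]], 1)
  expect_equal(sum(h), 1)

  below <- toy_skeleton_frame("left_foot", at = c(0, -1, 0))
  hb <- shape_histogram(below)
  expect_equal(sum(hb[61:70]), 1)          # last zenith band

  sess <- gen_session(c("DK", "SD"), seed = 8)
  h1 <- shape_histogram(sess$skeleton)
  expect_equal(sum(h1), 1)
  expect_true(all(h1 >= 0))
  translated <- dplyr::mutate(sess$skeleton, x = x + 3, y = y - 1, z = z + 2)
  expect_equal(shape_histogram(skeleton_stream(translated)), h1,
               tolerance = 1e-12)
})

test_that("shape histogram is frame-order invariant and skips degenerate radii", {
  sess <- gen_session("BR", seed = 3)
  sk <- sess$skeleton
  reversed <- dplyr::arrange(sk, dplyr::desc(time))
  expect_equal(shape_histogram(skeleton_stream(reversed)),
               shape_histogram(sk))

  collapsed <- toy_skeleton_frame("head", at = c(0, 0, 0))  # on the hip
  expect_equal(sum(shape_histogram(collapsed)), 0)

  no_hip <- tibble::tibble(time = 0, joint = "head", x = 0, y = 1, z = 0)
  expect_error(shape_histogram(skeleton_stream(no_hip)), "hip centre")
})

test_that("bin indices agree with per-angle classification on random joints", {
  withr::with_seed(21, {
    pts <- matrix(rnorm(3000), ncol = 3)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      sk <- toy_skeleton_frame("right_hand", at = p)
      h <- shape_histogram(sk)
      r <- sqrt(sum(p^2))
      theta <- acos(p[2] / r)
      phi <- atan2(p[3], p[1]) %% (2 * pi)
      zi <- min(floor(theta / (pi / 7)), 6)
      ai <- min(floor(phi / (2 * pi / 10)), 9)
      expect_equal(unname(which(h == 1) - 1), zi * 10 + ai)
    }
  })
})

test_that("edge histogram classifies oriented stripes and respects its contracts", {
  flat <- matrix(128, 32, 32)
  expect_true(all(edge_histogram(flat) == 0))

  vertical <- matrix(0, 32, 32); vertical[, seq(2, 32, 2)] <- 255
  ev <- edge_histogram(vertical)
  expect_length(ev, 80)
  expect_equal(sum(ev[seq(1, 80, 5)]), 16)      # every sub-image vertical
  expect_equal(sum(ev[-seq(1, 80, 5)]), 0)

  horizontal <- t(vertical)
  eh <- edge_histogram(horizontal)
  expect_equal(sum(eh[seq(2, 80, 5)]), 16)

  shifted <- edge_histogram(vertical + 17)       # constant intensity offset
  expect_equal(shifted, ev)

  expect_error(edge_histogram(matrix(0, 8, 8)), "16x16")
  withr::with_seed(5, {
    noisy <- matrix(runif(48 * 40, 0, 255), 48, 40)
    en <- edge_histogram(noisy)
    expect_true(all(en >= 0 & en <= 1))
  })
})

test_that("visual vector concatenates 70 + 80 entries in fixed order", {
  sess <- gen_session("CL", seed = 12)
  crop <- matrix(0, 32, 32); crop[seq(2, 32, 2), ] <- 200
  v <- visual_feature_vector(sess$skeleton, crop)
  expect_length(v, 150)
  expect_true(attr(v, "ehd"))
  expect_named(v[1:70], sprintf("sh_%02d", 0:69))
  expect_named(v[71:150], sprintf("ehd_%02d", 0:79))
  expect_identical(v, visual_feature_vector(sess$skeleton, crop))

  pre <- visual_feature_vector(sess$skeleton, rep(1 / 80, 80))
  expect_equal(unname(pre[71:150]), rep(1 / 80, 80))

  bare <- visual_feature_vector(sess$skeleton, NULL)
  expect_length(bare, 70)
  expect_false(attr(bare, "ehd"))
  expect_error(visual_feature_vector(sess$skeleton, rep(0.1, 10)), "length 80")
})
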