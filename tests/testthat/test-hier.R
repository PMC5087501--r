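oracle_table_model <- function(p_group, p_act, partition) {
  # hand-assembled hier_model around fixed probability tables
  structure(list(
    partition = as_partition(partition),
    layer1 = "l1", layer2 = "l2",
    group_of = hiermotion:::group_lookup(as_partition(partition)),
    activity_levels = sort(colnames(p_act)),
    group_levels = sort(colnames(p_group)),
    classifier = list(predict_prob = function(model, x) {
      if (identical(model, "l1")) p_group else p_act
    }),
    config = har_config()
  ), class = "hier_model")
}

test_that("fusion multiplies the activity and containing-group probabilities", {
  p_group <- matrix(c(0.9, 0.1), 1, dimnames = list(NULL, c("a1+a2", "a3")))
  p_act <- matrix(c(0.2, 0.3, 0.5), 1, dimnames = list(NULL, c("a1", "a2", "a3")))
  model <- oracle_table_model(p_group, p_act, list(c("a1", "a2"), "a3"))
  pred <- fuse_predict(model, matrix(0, 1, 1), matrix(0, 1, 1))
  expect_equal(pred$activity, "a2")
  expect_equal(pred$score_a1, 0.18)
  expect_equal(pred$score_a2, 0.27)
  expect_equal(pred$score_a3, 0.05)

  uniform <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("a1+a2", "a3")))
  mu <- oracle_table_model(uniform, p_act, list(c("a1", "a2"), "a3"))
  expect_equal(fuse_predict(mu, matrix(0, 1, 1), matrix(0, 1, 1))$activity,
               "a3")                        # visual-only argmax

  onehot <- matrix(c(1, 0), 1, dimnames = list(NULL, c("a1+a2", "a3")))
  mo <- oracle_table_model(onehot, p_act, list(c("a1", "a2"), "a3"))
  po <- fuse_predict(mo, matrix(0, 1, 1), matrix(0, 1, 1))
  expect_equal(po$activity, "a2")
  expect_equal(po$score_a3, 0)              # restricted to the hot group
})

test_that("fusion equals a brute-force loop over (activity, group) pairs", {
  withr::with_seed(23, {
    partition <- list(c("a1", "a4"), c("a2", "a5"), "a3")
    acts <- paste0("a", 1:5)
    groups <- c("a1+a4", "a2+a5", "a3")
    for (rep in 1:20) {
      pg <- matrix(runif(3), 1, dimnames = list(NULL, groups))
      pg <- pg / sum(pg)
      pa <- matrix(runif(5), 1, dimnames = list(NULL, acts))
      pa <- pa / sum(pa)
      model <- oracle_table_model(pg, pa, partition)
      pred <- fuse_predict(model, matrix(0, 1, 1), matrix(0, 1, 1))
      # oracle: explicit loop
      lookup <- c(a1 = "a1+a4", a4 = "a1+a4", a2 = "a2+a5",
                  a5 = "a2+a5", a3 = "a3")
      scores <- vapply(acts, function(a) pa[1, a] * pg[1, lookup[[a]]],
                       numeric(1))
      expect_equal(unlist(pred[paste0("score_", acts)]),
                   setNames(scores, paste0("score_", acts)))
      expect_equal(pred$activity, acts[which.max(scores)])
      expect_true(sum(scores) <= 1 + 1e-9)
      expect_true(all(scores >= 0))
    }
  })
})

test_that("training on separable synthetic data gives accurate calibrated layers", {
  gd <- gen_grouped_features(n_per_class = 40, group_sep = 7,
                             visual_sep = 5, seed = 31)
  idx <- rep(rep(c(TRUE, FALSE), each = 20), times = 8)
  cfg <- har_config(seed = 31)
  model <- train_hierarchical(gd$motion[idx, ], gd$visual[idx, ],
                              gd$labels[idx], gd$partition, cfg)
  pred <- fuse_predict(model, gd$motion[!idx, ], gd$visual[!idx, ])
  expect_gte(mean(pred$activity == gd$labels[!idx]), 0.9)
  scores <- as.matrix(pred[grep("^score_", names(pred))])
  expect_true(all(scores >= 0))
  expect_true(all(rowSums(scores) <= 1 + 1e-6))
  expect_equal(pred$path, rep("hierarchical", sum(!idx)))
})

test_that("degenerate partitions and misaligned rows are handled", {
  gd <- gen_grouped_features(n_per_class = 10, seed = 3,
                             partition = list(c("a1", "a2")))
  cfg <- har_config(seed = 3)
  one_group <- train_hierarchical(gd$motion, gd$visual, gd$labels,
                                  list(c("a1", "a2")), cfg)
  pred <- fuse_predict(one_group, gd$motion[1, ], gd$visual[1, ])
  expect_true(pred$activity %in% c("a1", "a2"))

  expect_error(train_hierarchical(gd$motion[1:5, ], gd$visual, gd$labels,
                                  list(c("a1", "a2")), cfg),
               "same number of rows")
  expect_error(train_hierarchical(gd$motion, gd$visual, gd$labels,
                                  list("a1"), cfg),
               "belong to a group")
})

test_that("motion-only model enforces its four-activity label set", {
  sessions <- purrr::map(1:2, function(i) {
    # running saturates the +-2 g accelerometer by design; clipping warns
    suppressWarnings(
      gen_session(rep(c("walking", "running", "sitting", "standing"), each = 4),
                  seed = 40 + i, subject_id = paste0("S", i)))
  })
  dat <- purrr::map_dfr(sessions, function(s) {
    dplyr::bind_cols(suppressWarnings(motion_features(s$sensor)),
                     label = s$segments$label)
  })
  feats <- dat[, 3:28]
  cfg <- har_config(seed = 1)
  idx <- seq_len(nrow(dat)) %% 2 == 0
  model <- train_motion_only(feats[idx, ], dat$label[idx], cfg)
  pred <- predict(model, feats[!idx, ])
  expect_gte(mean(pred$activity == dat$label[!idx]), 0.9)
  expect_equal(unique(pred$path), "motion_only")

  # duplicate of a training row predicts its own label
  dup <- predict(model, feats[which(idx)[1], ])
  expect_equal(dup$activity, dat$label[which(idx)[1]])

  three <- dat$label != "running"
  expect_error(train_motion_only(feats[three, ], dat$label[three], cfg),
               "exactly")
})

test_that("dispatch takes the hierarchical path only when visual data exist", {
  gd <- gen_grouped_features(n_per_class = 12, seed = 8)
  cfg <- har_config(seed = 8)
  hier <- train_hierarchical(gd$motion, gd$visual, gd$labels,
                             gd$partition, cfg)
  labels4 <- rep(c("running", "sitting", "standing", "walking"), each = 12)
  motion4 <- withr::with_seed(2, {
    centers <- matrix(rnorm(4 * 26, sd = 6), 4)
    as.data.frame(centers[rep(1:4, each = 12), ] + rnorm(48 * 26, sd = 0.5))
  })
  names(motion4) <- names(gd$motion)
  fallback <- train_motion_only(motion4, labels4, cfg)
  models <- list(hier = hier, motion_only = fallback)

  seen <- predict_dispatch(models, gd$motion[1:3, ], gd$visual[1:3, ])
  expect_equal(seen$path, rep("hierarchical", 3))
  expect_true(all(seen$activity %in% paste0("a", 1:8)))

  unseen <- predict_dispatch(models, motion4[1:3, ])
  expect_equal(unseen$path, rep("motion_only", 3))
  expect_true(all(unseen$activity %in% cfg$motion_only_labels))

  mixed_visual <- gd$visual[1:2, ]
  mixed_visual[2, ] <- NA_real_
  mixed <- predict_dispatch(models, gd$motion[1:2, ], mixed_visual)
  expect_equal(mixed$path, c("hierarchical", "motion_only"))

  expect_error(predict_dispatch(models, NULL), "required")
})

test_that("flat and single-source baselines share the prediction contract", {
  gd <- gen_grouped_features(n_per_class = 20, seed = 14)
  cfg <- har_config(seed = 14)
  for (mode in c("flat", "sensor-only", "image-only")) {
    model <- train_flat(gd$motion, gd$visual, gd$labels, mode, cfg)
    pred <- predict(model, gd$motion[1:4, ], gd$visual[1:4, ])
    expect_equal(nrow(pred), 4)
    expect_equal(unique(pred$path), mode)
    expect_true(all(pred$activity %in% paste0("a", 1:8)))
  }
})
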