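test_that("partitions validate disjointness, coverage and canonical order", {
  p <- as_partition(list(c("b", "a"), "c"))
  expect_equal(unclass(p), list(c("a", "b"), "c"))
  expect_error(as_partition(list(c("a", "b"), "b")), "disjoint")
  expect_error(as_partition(list("a"), labels = c("a", "b")), "cover")
  expect_error(as_partition(list()), "non-empty")
})

test_that("refinement splits exactly one group and never regroups", {
  cands <- refine_candidates(list(c("a", "b"), "c"))
  expect_length(cands, 1)
  expect_equal(unclass(cands[[1]]), list("a", "b", "c"))

  expect_length(refine_candidates(list(letters[1:4])), 7)   # 2^(4-1) - 1
  expect_length(refine_candidates(list("a", "b", "c")), 0)

  # brute force: every candidate is a strict refinement with M + 1 groups
  base <- as_partition(list(c("a", "d"), c("b", "e", "f"), "c"))
  for (cand in refine_candidates(base)) {
    expect_length(cand, length(base) + 1)
    for (group in cand) {
      containers <- purrr::map_lgl(base, function(g) all(group %in% g))
      expect_equal(sum(containers), 1)
    }
  }
})

test_that("bipartition enumeration counts 2^(N-1) - 1 distinct candidates", {
  for (n in 2:8) {
    labels <- paste0("a", seq_len(n))
    cands <- all_bipartitions(labels)
    expect_length(cands, 2^(n - 1) - 1)
    keys <- purrr::map_chr(cands, function(p) {
      paste(purrr::map_chr(p, paste, collapse = "+"), collapse = "|")
    })
    expect_false(anyDuplicated(keys) > 0)
    for (p in cands) expect_length(p, 2)
  }
})

test_that("partition invariants hold along random refinement chains", {
  withr::with_seed(13, {
    labels <- paste0("a", 1:6)
    for (rep in 1:5) {
      current <- as_partition(list(labels))
      repeat {
        cands <- refine_candidates(current)
        if (length(cands) == 0) break
        current <- cands[[sample(length(cands), 1)]]
        members <- sort(unlist(current))
        expect_equal(members, labels)                  # covering, disjoint
        expect_true(all(purrr::map_int(current, length) > 0))
      }
      expect_length(current, length(labels))           # ends at singletons
    }
  })
})

test_that("q_score is mean group accuracy penalized by 1/M", {
  expect_equal(q_score(c(1, 1)), 0.5)
  expect_equal(q_score(rep(1, 5)), 0.8)
  expect_equal(q_score(rep(0, 4)), -0.25)
  expect_error(q_score(numeric(0)), "non-empty")
})

test_that("group accuracy is CV recall: perfect, chance, and trivial cases", {
  cfg <- har_config(seed = 2)
  gd <- gen_grouped_features(n_per_class = 20, group_sep = 8,
                             within_sep = 0.3, seed = 2)
  t_planted <- group_accuracy(gd$motion, gd$labels, gd$partition, cfg)
  expect_true(all(t_planted$t > 0.95))      # well-separated planted groups

  single <- group_accuracy(gd$motion, gd$labels,
                           list(sort(unique(gd$labels))), cfg)
  expect_equal(single$t, 1)

  withr::with_seed(3, {
    x <- matrix(rnorm(400 * 4), 400, 4)
    y <- rep(c("u", "v"), each = 200)      # labels independent of features
    t_chance <- group_accuracy(x, y, list("u", "v"), cfg)
    expect_true(all(abs(t_chance$t - 0.5) < 0.12))
  })

  expect_error(group_accuracy(x[1:6, ], y[c(1:3, 201:203)],
                              list("u", "v"), cfg),
               "at least k")
})

test_that("the greedy search recovers a planted grouping and stops after the peak", {
  gd <- gen_grouped_features(n_per_class = 50, seed = 11)
  gs <- select_groups(gd$motion, gd$labels, har_config(seed = 11))
  expect_length(gs$partition, 5)
  expect_equal(unclass(gs$partition), unclass(gd$partition))
  expect_equal(which.max(gs$trace$e_max), nrow(gs$trace) - 1)
  expect_false(gs$trace$improved[nrow(gs$trace)])
  expect_equal(gs$trace$n_candidates[1], 127)      # all 2-group partitions
  expect_equal(gs$trace$m, seq(2, max(gs$trace$m)))
})

test_that("two labels give a single round; separable data runs to M = N", {
  clf <- centroid_classifier()
  cfg <- har_config(classifier = clf, seed = 1)
  gd2 <- gen_grouped_features(n_per_class = 15, partition = list("a", "b"),
                              group_sep = 8, seed = 4)
  gs2 <- select_groups(gd2$motion, gd2$labels, cfg)
  expect_equal(nrow(gs2$trace), 1)
  expect_length(gs2$partition, 2)

  sep <- gen_grouped_features(n_per_class = 15,
                              partition = list("a", "b", "c", "d"),
                              group_sep = 10, seed = 5)
  gss <- select_groups(sep$motion, sep$labels, cfg)
  expect_length(gss$partition, 4)                  # stopped by M < N guard
  expect_true(all(gss$trace$improved))
})

test_that("with an injected deterministic oracle the search is reproducible", {
  gd <- gen_grouped_features(n_per_class = 12, seed = 19, group_sep = 4)
  cfg <- har_config(classifier = centroid_classifier(), seed = 7)
  a <- select_groups(gd$motion, gd$labels, cfg)
  b <- select_groups(gd$motion, gd$labels, cfg)
  expect_identical(tidy(a), tidy(b))
  expect_identical(unclass(a$partition), unclass(b$partition))
})
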