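# Automatic group selection: a greedy, refinement-only search over
# partitions of the activity label set. Round M = 2 scores every 2-group
# partition; each later round may only split one group of the incumbent
# best partition, and the search stops as soon as the partition score
# Q = mean(per-group recall) - 1/M stops improving.

canonical_partition <- function(partition) {
  groups <- purrr::map(partition, function(g) sort(as.character(g)))
  groups[order(purrr::map_chr(groups, 1))]
}

partition_key <- function(partition) {
  paste(purrr::map_chr(canonical_partition(partition), paste, collapse = "+"),
        collapse = " | ")
}

#' Validate a partition of the activity label set
#'
#' A valid partition is a list of non-empty, pairwise-disjoint groups of
#' labels that together cover `labels` exactly.
#'
#' @param partition List of character vectors.
#' @param labels Character vector of activity labels the partition must
#'   cover (defaults to the union of the groups).
#' @return The partition in canonical order (groups sorted internally and
#'   by smallest member), invisibly classed `"har_partition"`.
#' @export
as_partition <- function(partition, labels = NULL) {
  if (!is.list(partition) || length(partition) == 0) {
    abort("a partition must be a non-empty list of label groups")
  }
  partition <- canonical_partition(partition)
  members <- unlist(partition)
  if (any(purrr::map_int(partition, length) == 0)) {
    abort("partition groups must be non-empty")
  }
  if (anyDuplicated(members)) {
    abort("partition groups must be disjoint")
  }
  labels <- sort(as.character(labels %||% members))
  if (!setequal(members, labels)) {
    abort("partition must cover the label set exactly")
  }
  structure(partition, class = "har_partition")
}

#' @export
print.har_partition <- function(x, ...) {
  cat(sprintf("<partition> M = %d: %s\n", length(x), partition_key(x)))
  invisible(x)
}

group_lookup <- function(partition) {
  keys <- purrr::map_chr(partition, paste, collapse = "+")
  setNames(rep(keys, purrr::map_int(partition, length)), unlist(partition))
}

# All 2-way splits of one group (set of 2^(k-1)-1 unordered bipartitions).
two_way_splits <- function(group) {
  k <- length(group)
  if (k < 2) return(list())
  purrr::map(seq_len(2^(k - 1) - 1), function(mask) {
    # first member pinned to part one; mask bits send the rest to part two
    sel <- c(TRUE, bitwAnd(mask, 2^(seq_len(k - 1) - 1)) == 0)
    list(group[sel], group[!sel])
  })
}

#' All partitions of a label set into two groups
#'
#' Enumerates the `2^(N-1) - 1` unordered bipartitions of `labels`.
#'
#' @param labels Character vector of N >= 2 labels.
#' @return List of canonical partitions.
#' @export
all_bipartitions <- function(labels) {
  labels <- sort(as.character(labels))
  purrr::map(two_way_splits(labels), as_partition, labels = labels)
}

#' Refinement candidates of a partition
#'
#' All partitions obtained by splitting exactly one group of `partition`
#' into two non-empty subsets; labels placed in different groups by the
#' incumbent can never be regrouped, which is what keeps the search cheap.
#' Deduplicated, in canonical order.
#'
#' @param partition A partition (list of label groups).
#' @return List of canonical partitions with one group more; empty when
#'   every group is a singleton.
#' @export
refine_candidates <- function(partition) {
  partition <- as_partition(partition)
  labels <- unlist(partition)
  out <- list()
  for (gi in seq_along(partition)) {
    for (split in two_way_splits(partition[[gi]])) {
      cand <- c(partition[-gi], split)
      out[[length(out) + 1]] <- as_partition(cand, labels = labels)
    }
  }
  out[!duplicated(purrr::map_chr(out, partition_key))]
}

#' Partition score Q
#'
#' `Q = mean(T) - 1/M` for per-group accuracies `T` of an M-group
#' partition: the average group recall penalized by `1/M` so that finer
#' partitions must earn their extra groups.
#'
#' @param t_values Numeric vector of per-group accuracies in `[0, 1]`.
#' @return Scalar.
#' @examples
#' q_score(c(1, 1))  # 0.5
#' @export
q_score <- function(t_values) {
  if (length(t_values) == 0) abort("`t_values` must be non-empty")
  mean(t_values) - 1 / length(t_values)
}

make_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  counts <- table(labels)
  if (any(counts < k)) {
    abort(sprintf(
      "every activity needs at least k = %d samples for %d-fold CV; smallest has %d",
      k, k, min(counts)))
  }
  rng <- local_rng(seed)
  for (lab in names(counts)) {
    idx <- rng(sample(which(labels == lab)))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Run `expr` under a private RNG state seeded with `seed`; global state
# untouched. Returns a function applying that stream to expressions.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    set.seed(seed)
    st <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    st
  }
  function(expr) {
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    expr
  }
}

#' Per-group accuracy of a candidate partition
#'
#' Relabels the samples by their group, trains the configured M-class
#' classifier under stratified k-fold cross validation, and returns each
#' group's recall averaged over folds. A single-group partition scores
#' `T = 1` by definition.
#'
#' @param features Data frame / matrix of motion features (rows are
#'   six-second segments).
#' @param labels Activity label per row.
#' @param partition Candidate partition of the label set.
#' @param config A [har_config()]; `cv_folds`, `seed` and the injected
#'   `classifier` are used.
#' @param folds Optional precomputed fold assignment (so that every
#'   candidate in one search round is scored on identical folds).
#' @return Tibble `group, t` with one row per group, `t` in `[0, 1]`.
#' @export
group_accuracy <- function(features, labels, partition,
                           config = har_config(), folds = NULL) {
  config <- as_har_config(config)
  partition <- as_partition(partition, labels = unique(as.character(labels)))
  labels <- as.character(labels)
  if (nrow(as.data.frame(features)) != length(labels)) {
    abort("`features` and `labels` must have the same number of rows")
  }
  keys <- purrr::map_chr(partition, paste, collapse = "+")
  if (length(partition) == 1) {
    return(tibble(group = keys, t = 1))
  }
  lookup <- group_lookup(partition)
  group_labels <- factor(lookup[labels], levels = keys)
  x <- as.matrix(as.data.frame(features))
  folds <- folds %||% make_folds(labels, config$cv_folds, config$seed)
  clf <- get_classifier(config, probability = FALSE)
  recall <- matrix(NA_real_, nrow = max(folds), ncol = length(keys),
                   dimnames = list(NULL, keys))
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- clf$fit(x[!test, , drop = FALSE], droplevels(group_labels[!test]),
                     config)
    pred <- as.character(clf$predict(model, x[test, , drop = FALSE]))
    truth <- as.character(group_labels[test])
    for (key in keys) {
      in_group <- truth == key
      if (any(in_group)) recall[f, key] <- mean(pred[in_group] == key)
    }
  }
  tibble(group = keys, t = colMeans(recall, na.rm = TRUE))
}

#' Greedy group-selection search
#'
#' Builds the first-layer grouping of the hierarchical classifier. Round
#' M = 2 scores every 2-group partition of the N activity labels with
#' [group_accuracy()] and [q_score()]; each subsequent round generates
#' candidates only by splitting one group of the incumbent best partition
#' ([refine_candidates()]), and the search continues while the best score
#' strictly improves and M < N. The returned partition is the incumbent
#' with the highest score over all completed rounds.
#'
#' @inheritParams group_accuracy
#' @return A `group_selection` object: list with `partition` (the selected
#'   partition), `q` (its score) and `trace` (tibble per round:
#'   `m, n_candidates, e_max, best_partition` list-column, `improved`).
#' @export
select_groups <- function(features, labels, config = har_config()) {
  config <- as_har_config(config)
  labels <- as.character(labels)
  label_set <- sort(unique(labels))
  n <- length(label_set)
  if (n < 2) abort("group selection needs at least 2 activity labels")
  folds <- make_folds(labels, config$cv_folds, config$seed)

  score_all <- function(cands) {
    qs <- purrr::map_dbl(cands, function(p) {
      q_score(group_accuracy(features, labels, p, config, folds = folds)$t)
    })
    best <- which.max(qs)   # first max wins; candidates in canonical order
    list(q = qs[best], partition = cands[[best]], n = length(cands))
  }

  trace <- list()
  incumbent <- NULL
  e_prev <- -Inf
  m <- 2L
  cands <- all_bipartitions(label_set)
  repeat {
    round_best <- score_all(cands)
    improved <- round_best$q > e_prev
    trace[[length(trace) + 1]] <- tibble(
      m = m, n_candidates = round_best$n, e_max = round_best$q,
      best_partition = list(round_best$partition), improved = improved
    )
    if (improved) {
      incumbent <- round_best$partition
      e_prev <- round_best$q
    }
    if (!(m == 2L || improved) || m >= n) break
    cands <- refine_candidates(round_best$partition)
    if (length(cands) == 0) break
    m <- m + 1L
  }

  structure(
    list(partition = incumbent, q = e_prev, trace = dplyr::bind_rows(trace),
         labels = label_set, config = config),
    class = "group_selection"
  )
}

#' @export
print.group_selection <- function(x, ...) {
  cat(sprintf("<group_selection> M = %d, Q = %.3f\n",
              length(x$partition), x$q))
  print(x$partition)
  invisible(x)
}

#' @export
tidy.group_selection <- function(x, ...) {
  dplyr::mutate(x$trace,
                partition = purrr::map_chr(.data$best_partition, partition_key))
}

#' @export
glance.group_selection <- function(x, ...) {
  tibble(m = length(x$partition), q = x$q, n_labels = length(x$labels),
         rounds = nrow(x$trace))
}

#' Q-versus-M curve of a group-selection run
#'
#' @param object A `group_selection`.
#' @param ... Unused.
#' @return A ggplot of the best score per round; the peak marks the
#'   selected number of groups.
#' @export
autoplot.group_selection <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$m, y = .data$e_max)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$improved), size = 2) +
    ggplot2::scale_x_continuous(breaks = object$trace$m) +
    ggplot2::labs(x = "number of groups M", y = "best Q score",
                  title = "Group-selection search trace")
}
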