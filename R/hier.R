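# Two-layer hierarchical recognition. Layer 1 classifies the selected
# activity groups from motion features; layer 2 classifies all N
# activities from visual features; the two probability tables are fused
# per segment as score(a) = P(a | image) * P(group(a) | sensor) and the
# argmax wins. When the subject is out of camera view a single-layer
# motion-only classifier over four simple activities takes over.

#' Train the two-layer hierarchical activity model
#'
#' Layer 1 is an M-class probabilistic classifier over motion features
#' with labels mapped to their groups under `partition` (a one-group
#' partition degenerates to a constant-probability layer); layer 2 is one
#' global N-class probabilistic classifier over visual features involving
#' all activities.
#'
#' @param motion Data frame / matrix of per-segment motion features.
#' @param visual Data frame / matrix of per-segment visual features,
#'   row-aligned with `motion`.
#' @param labels Activity label per segment; every label must belong to a
#'   group of `partition`.
#' @param partition Partition of the activity label set (e.g. from
#'   [select_groups()]).
#' @param config A [har_config()].
#' @return A `hier_model` object.
#' @export
train_hierarchical <- function(motion, visual, labels, partition,
                               config = har_config()) {
  config <- as_har_config(config)
  labels <- as.character(labels)
  xm <- as.matrix(as.data.frame(motion))
  xv <- as.matrix(as.data.frame(visual))
  if (nrow(xm) != length(labels) || nrow(xv) != length(labels)) {
    abort("`motion`, `visual` and `labels` must have the same number of rows")
  }
  partition <- as_partition(partition)
  if (!all(labels %in% unlist(partition))) {
    abort("every label must belong to a group of the partition")
  }
  if (!all(unlist(partition) %in% labels)) {
    abort("every activity of the partition needs training samples")
  }
  activity_levels <- sort(unique(unlist(partition)))
  lookup <- group_lookup(partition)
  group_levels <- sort(unique(lookup))
  clf <- get_classifier(config, probability = TRUE)
  layer1 <- clf$fit(xm, factor(lookup[labels], levels = group_levels), config)
  layer2 <- clf$fit(xv, factor(labels, levels = activity_levels), config)
  structure(
    list(partition = partition, layer1 = layer1, layer2 = layer2,
         group_of = lookup, activity_levels = activity_levels,
         group_levels = group_levels, classifier = clf, config = config),
    class = "hier_model"
  )
}

#' @export
print.hier_model <- function(x, ...) {
  cat(sprintf("<hier_model> %d activities in %d groups\n",
              length(x$activity_levels), length(x$partition)))
  print(x$partition)
  invisible(x)
}

#' @export
glance.hier_model <- function(x, ...) {
  tibble(n_activities = length(x$activity_levels),
         n_groups = length(x$partition))
}

as_prob_matrix <- function(prob, levels) {
  out <- matrix(0, nrow = nrow(prob), ncol = length(levels),
                dimnames = list(NULL, levels))
  out[, colnames(prob)] <- prob
  out
}

#' Fuse the two layers into a final prediction
#'
#' For each segment and each activity `a` belonging to group `g(a)`,
#' `score(a) = P(a | image) * P(g(a) | sensor)`; the activity with the
#' highest score wins, ties breaking to the first activity in canonical
#' (alphabetical) order.
#'
#' @param model A trained `hier_model`.
#' @param motion,visual Per-segment feature rows (vector, matrix or data
#'   frame), row-aligned.
#' @return Tibble with `activity`, `path = "hierarchical"` and one
#'   `score_<label>` column per activity.
#' @export
fuse_predict <- function(model, motion, visual) {
  if (!inherits(model, "hier_model")) abort("`model` must be a hier_model")
  xm <- as_feature_matrix(motion)
  xv <- as_feature_matrix(visual)
  if (nrow(xm) != nrow(xv)) abort("motion and visual rows must align")
  p_group <- as_prob_matrix(model$classifier$predict_prob(model$layer1, xm),
                            model$group_levels)
  p_act <- as_prob_matrix(model$classifier$predict_prob(model$layer2, xv),
                          model$activity_levels)
  scores <- fuse_scores(p_act, p_group, model$group_of)
  build_prediction(scores, path = "hierarchical")
}

# score(a) = P(a | image) * P(group(a) | sensor), columns in canonical
# activity order.
fuse_scores <- function(p_act, p_group, group_of) {
  acts <- colnames(p_act)
  scores <- p_act * p_group[, group_of[acts], drop = FALSE]
  colnames(scores) <- acts
  scores
}

build_prediction <- function(scores, path) {
  acts <- colnames(scores)
  pick <- apply(scores, 1, which.max)   # first max = canonical tie-break
  out <- tibble(activity = acts[pick], path = path)
  score_cols <- as_tibble(as.data.frame(scores))
  names(score_cols) <- paste0("score_", acts)
  dplyr::bind_cols(out, score_cols)
}

as_feature_matrix <- function(x) {
  if (is.null(dim(x))) {
    matrix(as.numeric(x), nrow = 1, dimnames = list(NULL, names(x)))
  } else {
    as.matrix(as.data.frame(x))
  }
}

#' @param object A `hier_model`.
#' @param ... Unused.
#' @rdname fuse_predict
#' @export
predict.hier_model <- function(object, motion, visual, ...) {
  fuse_predict(object, motion, visual)
}

#' Train the motion-only fallback model
#'
#' When the subject is outside the camera view only the wrist sensor is
#' available and only four simple activities are distinguishable:
#' walking, standing, sitting and running (configurable via
#' `motion_only_labels`). Trains a single-layer probabilistic classifier
#' over motion features.
#'
#' @param motion Per-segment motion features.
#' @param labels Activity label per segment; the label set must equal
#'   `config$motion_only_labels` exactly.
#' @param config A [har_config()].
#' @return A `motion_model` object.
#' @export
train_motion_only <- function(motion, labels, config = har_config()) {
  config <- as_har_config(config)
  labels <- as.character(labels)
  expected <- sort(config$motion_only_labels)
  if (!setequal(unique(labels), expected)) {
    abort(sprintf("motion-only labels must be exactly {%s}",
                  paste(expected, collapse = ", ")))
  }
  xm <- as.matrix(as.data.frame(motion))
  clf <- get_classifier(config, probability = TRUE)
  model <- clf$fit(xm, factor(labels, levels = expected), config)
  structure(list(model = model, activity_levels = expected,
                 classifier = clf, config = config),
            class = "motion_model")
}

#' @param object A `motion_model`.
#' @param motion Per-segment motion features.
#' @param ... Unused.
#' @rdname train_motion_only
#' @export
predict.motion_model <- function(object, motion, ...) {
  xm <- as_feature_matrix(motion)
  prob <- as_prob_matrix(object$classifier$predict_prob(object$model, xm),
                         object$activity_levels)
  build_prediction(prob, path = "motion_only")
}

#' Train a single-layer comparison model
#'
#' The flat baselines the hierarchical method is compared against: one
#' N-class probabilistic classifier over the concatenated motion+visual
#' features (`mode = "flat"`), over motion features alone
#' (`"sensor-only"`) or over visual features alone (`"image-only"`).
#'
#' @inheritParams train_hierarchical
#' @param mode Which feature set the single layer uses.
#' @return A `flat_model` object; `predict()` returns the same shape as
#'   [fuse_predict()].
#' @export
train_flat <- function(motion, visual, labels,
                       mode = c("flat", "sensor-only", "image-only"),
                       config = har_config()) {
  config <- as_har_config(config)
  mode <- match.arg(mode)
  labels <- as.character(labels)
  x <- switch(mode,
    "flat" = cbind(as.matrix(as.data.frame(motion)),
                   as.matrix(as.data.frame(visual))),
    "sensor-only" = as.matrix(as.data.frame(motion)),
    "image-only" = as.matrix(as.data.frame(visual))
  )
  if (nrow(x) != length(labels)) {
    abort("features and labels must have the same number of rows")
  }
  levels <- sort(unique(labels))
  clf <- get_classifier(config, probability = TRUE)
  model <- clf$fit(x, factor(labels, levels = levels), config)
  structure(list(model = model, mode = mode, activity_levels = levels,
                 n_motion = ncol(as.matrix(as.data.frame(motion))),
                 classifier = clf, config = config),
            class = "flat_model")
}

#' @param object A `flat_model`.
#' @param ... Unused.
#' @rdname train_flat
#' @export
predict.flat_model <- function(object, motion, visual = NULL, ...) {
  x <- switch(object$mode,
    "flat" = cbind(as_feature_matrix(motion), as_feature_matrix(visual)),
    "sensor-only" = as_feature_matrix(motion),
    "image-only" = as_feature_matrix(visual)
  )
  prob <- as_prob_matrix(object$classifier$predict_prob(object$model, x),
                         object$activity_levels)
  build_prediction(prob, path = object$mode)
}

#' Dispatch a prediction on sensor availability
#'
#' Uses the hierarchical path when a visual feature row is available and
#' falls back to the motion-only model otherwise; the path taken is
#' recorded per segment. Rows whose visual features are entirely `NA`
#' count as absent.
#'
#' @param models List with elements `hier` (a `hier_model`) and
#'   `motion_only` (a `motion_model`); either may be `NULL` if never
#'   needed.
#' @param motion Per-segment motion features (required).
#' @param visual Per-segment visual features, `NULL` when the subject was
#'   never in view, or containing all-`NA` rows for out-of-view segments.
#' @return Tibble `activity, path` (score columns are per-path and
#'   reported in the `scores` list-column).
#' @export
predict_dispatch <- function(models, motion, visual = NULL) {
  if (is.null(motion)) abort("motion features are required for any prediction")
  xm <- as_feature_matrix(motion)
  has_visual <- if (is.null(visual)) {
    rep(FALSE, nrow(xm))
  } else {
    xv <- as_feature_matrix(visual)
    if (nrow(xv) != nrow(xm)) abort("motion and visual rows must align")
    rowSums(!is.na(xv)) > 0
  }
  out <- vector("list", nrow(xm))
  if (any(has_visual)) {
    if (is.null(models$hier)) abort("no hierarchical model supplied")
    pred <- fuse_predict(models$hier, xm[has_visual, , drop = FALSE],
                         xv[has_visual, , drop = FALSE])
    out[which(has_visual)] <- split_rows(pred)
  }
  if (any(!has_visual)) {
    if (is.null(models$motion_only)) abort("no motion-only model supplied")
    pred <- predict(models$motion_only, xm[!has_visual, , drop = FALSE])
    out[which(!has_visual)] <- split_rows(pred)
  }
  dplyr::bind_rows(purrr::map(out, function(row) {
    tibble(activity = row$activity, path = row$path,
           scores = list(dplyr::select(row, dplyr::starts_with("score_"))))
  }))
}

split_rows <- function(df) {
  purrr::map(seq_len(nrow(df)), function(i) df[i, , drop = FALSE])
}
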