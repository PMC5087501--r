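# Injected classifier contract. Every learning stage talks to a plain
# list of three functions so that tests can swap in a deterministic
# oracle; the default is a linear-kernel SVM with class-balanced weights
# and pairwise-coupling calibrated probability output.

#' Default linear SVM classifier contract
#'
#' Returns the classifier used throughout the package unless another is
#' injected via `har_config(classifier = ...)`: a linear-kernel
#' support-vector machine (cost `svm_cost`, class weights inverse to
#' class frequency) whose probability outputs are calibrated by pairwise
#' coupling. Any list providing the same three functions satisfies the
#' contract:
#' \describe{
#'   \item{`fit(x, y, config)`}{train on feature matrix `x` and factor `y`,
#'     returning an opaque model object;}
#'   \item{`predict(model, x)`}{hard labels as a character vector;}
#'   \item{`predict_prob(model, x)`}{a numeric matrix, one column per
#'     class level of `y`, rows summing to 1.}
#' }
#'
#' @param probability Train the probability model (slower); needed by the
#'   hierarchical layers, not by the group-selection search. Default TRUE.
#' @return A classifier contract list.
#' @export
svm_classifier <- function(probability = TRUE) {
  list(
    fit = function(x, y, config) {
      y <- droplevels(as.factor(y))
      if (nlevels(y) < 2) {
        return(structure(list(level = levels(y)), class = "constant_clf"))
      }
      weights <- length(y) / (nlevels(y) * table(y))
      # e1071's probability calibration uses internal CV; pin its RNG so a
      # fitted model is a pure function of (x, y, config).
      rng <- local_rng(config$seed)
      rng(e1071::svm(x, y, kernel = "linear", cost = config$svm_cost,
                     class.weights = weights, probability = probability,
                     scale = FALSE))
    },
    predict = function(model, x) {
      if (inherits(model, "constant_clf")) {
        return(rep(model$level, nrow(x)))
      }
      as.character(predict(model, x))
    },
    predict_prob = function(model, x) {
      if (inherits(model, "constant_clf")) {
        return(matrix(1, nrow = nrow(x), ncol = 1,
                      dimnames = list(NULL, model$level)))
      }
      pred <- predict(model, x, probability = TRUE)
      prob <- attr(pred, "probabilities")
      prob[, sort(colnames(prob)), drop = FALSE]
    }
  )
}

#' Deterministic nearest-centroid oracle classifier
#'
#' A trivial classifier satisfying the injected-classifier contract:
#' class centroids at training time, softmax over negative distances at
#' prediction time. Entirely deterministic; used to exercise search and
#' fusion logic independently of SVM internals.
#'
#' @return A classifier contract list.
#' @export
centroid_classifier <- function() {
  list(
    fit = function(x, y, config) {
      y <- droplevels(as.factor(y))
      centroids <- t(vapply(levels(y), function(lev) {
        colMeans(x[y == lev, , drop = FALSE])
      }, numeric(ncol(x))))
      structure(list(centroids = centroids, levels = levels(y)),
                class = "centroid_clf")
    },
    predict = function(model, x) {
      d <- centroid_distances(model, x)
      model$levels[apply(d, 1, which.min)]
    },
    predict_prob = function(model, x) {
      d <- centroid_distances(model, x)
      w <- exp(-d + apply(d, 1, min))
      prob <- w / rowSums(w)
      colnames(prob) <- model$levels
      prob[, sort(model$levels), drop = FALSE]
    }
  )
}

centroid_distances <- function(model, x) {
  t(apply(x, 1, function(row) {
    sqrt(colSums((t(model$centroids) - row)^2))
  }))
}

get_classifier <- function(config, probability = TRUE) {
  config$classifier %||% svm_classifier(probability = probability)
}
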