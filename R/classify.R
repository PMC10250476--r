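#' Balanced class weights
#'
#' Weights inversely proportional to class frequency,
#' `w_c = total / (n_classes * count_c)`, so that rare behaviors carry the
#' same total training weight as common ones. The weights satisfy
#' `sum(w_c * count_c) = total` exactly.
#'
#' @param class_counts named vector of per-class observation counts, all
#'   positive.
#' @return named numeric vector of weights.
#' @export
class_weights <- function(class_counts) {
  counts <- as.numeric(class_counts)
  if (length(counts) == 0L || any(counts <= 0))
    stop("all class counts must be positive")
  w <- sum(counts) / (length(counts) * counts)
  stats::setNames(w, names(class_counts))
}

# --- classifier backend contract ----------------------------------------
# A backend is a list of two functions:
#   fit(x, y, weights, config, seed) -> opaque fit object
#   predict_proba(fit, x)            -> matrix windows x classes, columns
#                                       named by class, rows summing to 1
# Deep time-series backends can be registered here without touching the
# rest of the pipeline; only the random forest ships.

backend_registry <- new.env(parent = emptyenv())

#' Register or fetch a classifier backend
#'
#' @param name backend identifier.
#' @param backend list with functions `fit(x, y, weights, config, seed)` and
#'   `predict_proba(fit, x)`; omit to fetch the registered backend.
#' @return the backend list, invisibly on registration.
#' @export
classifier_backend <- function(name, backend = NULL) {
  if (is.null(backend)) {
    if (!exists(name, envir = backend_registry))
      stop("unknown classifier backend: '", name, "'")
    return(get(name, envir = backend_registry))
  }
  stopifnot(is.function(backend$fit), is.function(backend$predict_proba))
  assign(name, backend, envir = backend_registry)
  invisible(backend)
}

# Random forest backend: probability forest, max-features rule
# mtry = floor(sqrt(p)), balanced class weights, single-threaded for
# bitwise reproducibility under a fixed seed.
rf_backend <- list(
  fit = function(x, y, weights, config, seed) {
    if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
    ranger::ranger(
      x = x, y = y,
      num.trees = config$n_estimators,
      mtry = floor(sqrt(ncol(x))),
      class.weights = weights[levels(y)],
      probability = TRUE,
      seed = seed,
      num.threads = 1L,
      min.node.size = config$min_node_size,
      max.depth = config$max_depth
    )
  },
  predict_proba = function(fit, x) {
    if (is.null(colnames(x)) ||
        !identical(colnames(x), fit$forest$independent.variable.names))
      colnames(x) <- fit$forest$independent.variable.names
    stats::predict(fit, data = x, num.threads = 1L)$predictions
  }
)

classifier_backend("random_forest", rf_backend)

#' Classifier configuration
#'
#' @param n_estimators number of trees (default 20, a good
#'   accuracy/time tradeoff; validation curves explore 1..100).
#' @param seed integer seed making the fit deterministic.
#' @param backend backend identifier (default `"random_forest"`).
#' @param min_node_size,max_depth tree-level hyperparameters, kept at the
#'   library defaults (`NULL`) and recorded in the model metadata.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_estimators = 20L, seed = 1L,
                              backend = "random_forest",
                              min_node_size = NULL, max_depth = NULL) {
  n_estimators <- as.integer(n_estimators)
  if (is.na(n_estimators) || n_estimators < 1L)
    stop("n_estimators must be a positive integer")
  structure(list(n_estimators = n_estimators, seed = as.integer(seed),
                 backend = backend, min_node_size = min_node_size,
                 max_depth = max_depth,
                 max_features_rule = "sqrt", class_weighting = "balanced"),
            class = "classifier_config")
}

#' Fit an imbalance-aware behavior classifier on window vectors
#'
#' The central model fit: a random-forest (or pluggable backend) classifier
#' on flattened sliding-window feature vectors, trained with balanced class
#' weights ([class_weights()]) so that rare behaviors are not swamped by
#' common ones. The number of candidate features per split follows the
#' square-root rule `floor(sqrt(p))` where `p` is the input-vector length.
#' Refitting with the same data, configuration and seed reproduces
#' identical predictions.
#'
#' @param dataset a labeled `window_dataset` from [make_windows()] with at
#'   least two classes.
#' @param config a [classifier_config()].
#' @param feature_names optional character vector naming the per-frame
#'   features, stored as metadata.
#' @return An object of class `behavior_classifier` with components `fit`
#'   (backend fit), `classes` (class order), `spec` (window spec),
#'   `config`, `weights`, `feature_names` and `versions`.
#' @export
behavior_classifier <- function(dataset, config = classifier_config(),
                                feature_names = NULL) {
  stopifnot(inherits(dataset, "window_dataset"))
  if (is.null(dataset$labels))
    stop("dataset is unlabeled; training requires labels")
  classes <- sort(unique(dataset$labels))
  if (length(classes) < 2L)
    stop("training requires at least two classes; got ", length(classes))
  y <- factor(dataset$labels, levels = classes)
  counts <- table(y)
  w <- class_weights(stats::setNames(as.numeric(counts), names(counts)))
  backend <- classifier_backend(config$backend)
  fit <- backend$fit(dataset$x, y, w, config, config$seed)
  structure(
    list(fit = fit, classes = classes, spec = dataset$spec,
         config = config, weights = w, feature_names = feature_names,
         versions = c(poseclass = as.character(utils::packageVersion("poseclass")),
                      ranger = as.character(utils::packageVersion("ranger")))),
    class = "behavior_classifier"
  )
}

#' @export
print.behavior_classifier <- function(x, ...) {
  cat("<behavior_classifier> backend '", x$config$backend, "', ",
      x$config$n_estimators, " trees, window ", x$spec$window_size,
      " frame(s)\n", sep = "")
  cat("  classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.behavior_classifier <- function(object, ...) {
  cat("Behavior classifier\n")
  cat("  backend:        ", object$config$backend, "\n")
  cat("  trees:          ", object$config$n_estimators, "\n")
  cat("  window size:    ", object$spec$window_size, " frame(s)\n")
  cat("  input length:   ", object$spec$n_features * object$spec$window_size,
      "\n")
  cat("  split features: ",
      floor(sqrt(object$spec$n_features * object$spec$window_size)),
      " (sqrt rule)\n")
  cat("  class weights (balanced):\n")
  print(round(object$weights, 4))
  invisible(object)
}

#' Per-window class probabilities
#'
#' Runs the fitted classifier over a window dataset and returns one
#' probability vector per window, attributed to the window's anchor frame.
#' Rows sum to 1.
#'
#' @param model a [behavior_classifier()].
#' @param dataset a `window_dataset` whose vector length matches the model.
#' @return A `probability_track`: list with `classes`, matrix `probs`
#'   (windows x classes) and `anchor_frames`.
#' @export
predict_proba <- function(model, dataset) {
  stopifnot(inherits(model, "behavior_classifier"),
            inherits(dataset, "window_dataset"))
  p_model <- model$spec$n_features * model$spec$window_size
  if (ncol(dataset$x) != p_model)
    stop("input vector length mismatch: model expects ", p_model,
         ", dataset provides ", ncol(dataset$x))
  backend <- classifier_backend(model$config$backend)
  probs <- backend$predict_proba(model$fit, dataset$x)
  probs <- probs[, model$classes, drop = FALSE]
  probability_track(probs, model$classes, dataset$anchor_frames)
}

#' @rdname predict_proba
#' @param object a `behavior_classifier`.
#' @param newdata a `window_dataset`.
#' @param type `"prob"` for a probability track, `"class"` for argmax
#'   behavior predictions.
#' @param ... unused.
#' @export
predict.behavior_classifier <- function(object, newdata,
                                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pt <- predict_proba(object, newdata)
  if (type == "prob") pt else argmax_prediction(pt)
}

#' Construct a probability track
#'
#' @param probs matrix windows x classes, rows summing to 1.
#' @param classes ordered class names.
#' @param anchor_frames 0-based frame each row is attributed to.
#' @return A `probability_track`.
#' @export
probability_track <- function(probs, classes, anchor_frames) {
  probs <- as.matrix(probs)
  if (ncol(probs) != length(classes))
    stop("probs must have one column per class")
  if (nrow(probs) > 0L) {
    if (any(probs < -1e-12 | probs > 1 + 1e-12))
      stop("probabilities must lie in [0, 1]")
    if (any(abs(rowSums(probs) - 1) > 1e-9))
      stop("probability rows must sum to 1")
  }
  colnames(probs) <- classes
  structure(list(classes = as.character(classes), probs = probs,
                 anchor_frames = as.integer(anchor_frames)),
            class = "probability_track")
}

#' @export
print.probability_track <- function(x, ...) {
  cat("<probability_track> ", nrow(x$probs), " frames x ",
      length(x$classes), " classes\n", sep = "")
  invisible(x)
}
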