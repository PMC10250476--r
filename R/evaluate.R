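#' Per-class precision, recall and F1
#'
#' Precision is `TP / (TP + FP)`, recall `TP / (TP + FN)` and F1 their
#' harmonic mean `2 / (1/precision + 1/recall)`. Any quantity whose
#' denominator is zero (class never predicted, never true, or both) is 0 by
#' convention.
#'
#' @param truth,pred character/factor vectors of equal length.
#' @param class the class to score.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(truth, pred, class) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length (", length(truth), " vs ",
         length(pred), ")")
  tp <- sum(truth == class & pred == class)
  fp <- sum(truth != class & pred == class)
  fn <- sum(truth == class & pred != class)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Support-weighted F1 over all classes
#'
#' The per-class F1 scores averaged with weights proportional to each
#' class's true-label support:
#' `F1_weighted = (1/total) * sum_i F1_i * support_i`. Classes are taken
#' from the true labels (a class never true contributes zero support).
#'
#' @param truth,pred character/factor vectors of equal length, non-empty.
#' @return weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) == 0L) stop("empty label vectors")
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  classes <- unique(truth)
  f1s <- vapply(classes, function(cl)
    precision_recall_f1(truth, pred, cl)[["f1"]], numeric(1))
  supp <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1s * supp) / length(truth)
}

#' Confusion matrix, absolute and row-normalized
#'
#' Rows are true classes, columns predicted classes. The relative matrix
#' divides each row by its sum; empty rows stay zero.
#'
#' @param truth,pred label vectors of equal length.
#' @param classes class order for rows/columns; default: union, sorted.
#' @return list with integer matrix `absolute` and numeric `relative`.
#' @export
confusion_matrix <- function(truth, pred,
                             classes = sort(unique(c(as.character(truth),
                                                     as.character(pred))))) {
  t_ <- factor(as.character(truth), levels = classes)
  p_ <- factor(as.character(pred), levels = classes)
  absolute <- table(truth = t_, predicted = p_)
  absolute <- matrix(as.integer(absolute), nrow = length(classes),
                     dimnames = list(truth = classes, predicted = classes))
  rs <- rowSums(absolute)
  relative <- absolute / ifelse(rs == 0, 1, rs)
  list(absolute = absolute, relative = relative)
}

#' Contiguous five-fold split of a window index range
#'
#' Indices `1..n` are cut into `k` contiguous blocks of `floor(n/k)`
#' windows, the remainder going to the last block; fold `i` tests on block
#' `i` and trains on the others. With `k = 5` the last fold trains on the
#' first ~80% and tests on the last ~20% of windows — fold assignment is
#' never shuffled, because neighbouring frames of high-fps video are nearly
#' identical and shuffling would leak them across the train/test split.
#'
#' @param n number of windows.
#' @param k number of folds.
#' @return list of `k` lists with integer vectors `train` and `test`.
#' @export
blocked_folds <- function(n, k = 5L) {
  if (n < k) stop("need at least ", k, " windows for ", k, "-fold CV; got ", n)
  base <- n %/% k
  starts <- (0:(k - 1L)) * base + 1L
  ends <- c(starts[-1L] - 1L, n)
  lapply(seq_len(k), function(i) {
    test <- starts[i]:ends[i]
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Five-fold non-shuffled cross-validation
#'
#' Evaluates a classifier configuration with blocked (contiguous,
#' non-shuffled) five-fold cross-validation; the overall score is the
#' arithmetic mean of the five per-fold weighted F1 values. The last fold's
#' predictions (train on first ~80%, test on last ~20%) are kept for
#' per-class reporting.
#'
#' @param dataset a labeled `window_dataset` in original temporal order.
#' @param config a [classifier_config()].
#' @param k number of folds (default 5).
#' @return An `eval_report`: list with `fold_scores` (per-fold weighted F1),
#'   `cv_score` (their mean), `fold_details` (per-fold truth and
#'   predictions), `per_class` (data frame of
#'   precision/recall/F1/support on the last fold), `confusion` (last-fold
#'   absolute + relative matrices), `last_fold` (truth, pred, probs,
#'   anchor_frames) and `classes`.
#' @export
cv5_nonshuffled <- function(dataset, config = classifier_config(), k = 5L) {
  stopifnot(inherits(dataset, "window_dataset"))
  if (is.null(dataset$labels)) stop("cross-validation requires labels")
  n <- nrow(dataset$x)
  folds <- blocked_folds(n, k)
  fold_scores <- numeric(k)
  fold_details <- vector("list", k)
  last <- NULL
  for (i in seq_len(k)) {
    tr <- subset_windows(dataset, folds[[i]]$train)
    te <- subset_windows(dataset, folds[[i]]$test)
    model <- behavior_classifier(tr, config)
    pt <- predict_proba(model, te)
    pred <- argmax_prediction(pt)$behavior
    fold_scores[i] <- weighted_f1(te$labels, pred)
    fold_details[[i]] <- list(truth = te$labels, pred = pred)
    if (i == k)
      last <- list(truth = te$labels, pred = pred, probs = pt,
                   anchor_frames = te$anchor_frames, model = model)
  }
  classes <- sort(unique(dataset$labels))
  prf <- t(vapply(classes, function(cl)
    precision_recall_f1(last$truth, last$pred, cl), numeric(3)))
  per_class <- data.frame(class = classes, prf,
                          support = vapply(classes, function(cl)
                            sum(last$truth == cl), numeric(1)),
                          row.names = NULL)
  structure(
    list(fold_scores = fold_scores, cv_score = mean(fold_scores),
         fold_details = fold_details, per_class = per_class,
         confusion = confusion_matrix(last$truth, last$pred, classes),
         last_fold = last, classes = classes, config = config),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", length(x$fold_scores),
      "-fold non-shuffled CV weighted F1: ",
      sprintf("%.4f", x$cv_score), " (folds: ",
      paste(sprintf("%.3f", x$fold_scores), collapse = ", "), ")\n",
      sep = "")
  cat("last-fold per-class metrics:\n")
  print(transform(x$per_class,
                  precision = round(precision, 3),
                  recall = round(recall, 3),
                  f1 = round(f1, 3)))
  invisible(x)
}

#' Validation curve over a hyperparameter
#'
#' Recomputes the blocked cross-validation score for each candidate value of
#' one hyperparameter, everything else fixed. `"n_estimators"` varies the
#' tree count on a fixed window dataset; `"window_size"` re-windows the
#' labeled frame features for each value (pass `features`, `frame_indices`
#' and `labels` instead of `dataset`).
#'
#' @param param `"n_estimators"` or `"window_size"`.
#' @param values candidate values, non-empty.
#' @param dataset labeled `window_dataset` (for `"n_estimators"`).
#' @param features,frame_indices,labels per-frame inputs (for
#'   `"window_size"`).
#' @param config base [classifier_config()].
#' @param k folds.
#' @return data frame with columns `value`, `mean` (cv score), `sd`
#'   (over folds).
#' @export
validation_curve <- function(param, values, dataset = NULL, features = NULL,
                             frame_indices = NULL, labels = NULL,
                             config = classifier_config(), k = 5L) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (!param %in% c("n_estimators", "window_size"))
    stop("unknown hyperparameter: '", param, "'")
  res <- lapply(values, function(v) {
    if (param == "n_estimators") {
      cfg <- config; cfg$n_estimators <- as.integer(v)
      ds <- dataset
    } else {
      spec <- window_spec(v, ncol(features))
      ds <- make_windows(features, spec, frame_indices, labels)
      cfg <- config
    }
    rep_ <- cv5_nonshuffled(ds, cfg, k)
    c(mean = rep_$cv_score, sd = stats::sd(rep_$fold_scores))
  })
  data.frame(value = values,
             mean = vapply(res, `[[`, numeric(1), "mean"),
             sd = vapply(res, `[[`, numeric(1), "sd"))
}

#' Learning curve over training-set size
#'
#' For each fraction, each fold trains on a contiguous prefix of its
#' training indices (preserving the non-shuffled discipline) and tests on
#' its full test block; the score is the mean weighted F1 over folds.
#' Fraction 1 reproduces the plain cross-validation score.
#'
#' @param dataset labeled `window_dataset`.
#' @param fractions training-set fractions in `(0, 1]`.
#' @param config a [classifier_config()].
#' @param k folds.
#' @return data frame with columns `fraction`, `mean`, `sd`.
#' @export
learning_curve <- function(dataset, fractions, config = classifier_config(),
                           k = 5L) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  n <- nrow(dataset$x)
  folds <- blocked_folds(n, k)
  out <- lapply(fractions, function(f) {
    scores <- vapply(folds, function(fold) {
      m <- max(1L, floor(f * length(fold$train)))
      if (f * length(fold$train) < 1)
        stop("fraction ", f, " yields fewer than one training window")
      tr <- subset_windows(dataset, fold$train[seq_len(m)])
      if (length(unique(tr$labels)) < 2L)
        return(NA_real_)
      te <- subset_windows(dataset, fold$test)
      model <- behavior_classifier(tr, config)
      pred <- argmax_prediction(predict_proba(model, te))$behavior
      weighted_f1(te$labels, pred)
    }, numeric(1))
    c(mean = mean(scores, na.rm = TRUE), sd = stats::sd(scores, na.rm = TRUE))
  })
  data.frame(fraction = fractions,
             mean = vapply(out, `[[`, numeric(1), "mean"),
             sd = vapply(out, `[[`, numeric(1), "sd"))
}
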