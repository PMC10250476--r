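test_that("precision, recall and F1 follow their defining ratios", {
  # TP=8, FP=2, FN=8: truth has 16 positives, 8 found, 2 false alarms
  truth <- c(rep("pos", 16), rep("neg", 10))
  pred <- c(rep("pos", 8), rep("neg", 8), rep("pos", 2), rep("neg", 8))
  out <- precision_recall_f1(truth, pred, "pos")
  expect_equal(out[["precision"]], 0.8)
  expect_equal(out[["recall"]], 0.5)
  expect_equal(out[["f1"]], 2 / (1 / 0.8 + 1 / 0.5), tolerance = 1e-9)

  expect_equal(unname(precision_recall_f1(c("a", "b"), c("a", "b"), "a")),
               c(1, 1, 1))
  # class never predicted and never true: all zero by convention
  expect_equal(unname(precision_recall_f1(c("a", "b"), c("a", "b"), "c")),
               c(0, 0, 0))
  expect_error(precision_recall_f1("a", c("a", "b"), "a"), "equal length")
})

test_that("weighted F1 is the support-weighted mean of per-class F1", {
  truth <- c("A", "A", "A", "B", "B")
  pred <- c("A", "A", "A", "B", "A")
  # A: TP=3, FP=1 -> p=3/4, r=1, f1=6/7, support 3
  # B: TP=1, FN=1, FP=0 -> p=1, r=1/2, f1=2/3, support 2
  expect_equal(weighted_f1(truth, pred),
               (3 * 6 / 7 + 2 * 2 / 3) / 5, tolerance = 1e-12)
  # pure support-weighting example: one class perfect, one at f1 = 1/2
  truth2 <- c("A", "A", "A", "B", "B", "B")
  pred2 <- c("A", "A", "A", "B", "C", "C")
  # B: p=1, r=1/3, f1=1/2; A perfect
  expect_equal(weighted_f1(truth2, pred2), (3 * 1 + 3 * 0.5) / 6,
               tolerance = 1e-12)
  expect_equal(weighted_f1(c("x", "y"), c("x", "y")), 1)
  expect_error(weighted_f1(character(), character()), "empty")
})

test_that("metrics agree exactly with a brute-force tally oracle", {
  set.seed(99)
  for (i in 1:50) {
    lp <- random_label_pair(n = sample(10:80, 1), k = sample(2:5, 1))
    for (cl in unique(lp$truth))
      expect_equal(precision_recall_f1(lp$truth, lp$pred, cl),
                   oracle_prf(lp$truth, lp$pred, cl), tolerance = 1e-12)
    expect_equal(weighted_f1(lp$truth, lp$pred),
                 oracle_weighted_f1(lp$truth, lp$pred), tolerance = 1e-12)
  }
})

test_that("confusion matrices tally truths by rows, predictions by columns", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "a", "b"))
  expect_equal(unname(cm$absolute), matrix(c(2L, 0L, 0L, 1L), 2))
  expect_equal(unname(cm$relative), diag(2))

  cm2 <- confusion_matrix(rep("a", 4), rep("b", 4), classes = c("a", "b"))
  expect_equal(cm2$absolute["a", "b"], 4L)
  expect_equal(cm2$relative["a", "b"], 1)
  expect_equal(unname(rowSums(cm2$relative)), c(1, 0))

  set.seed(4)
  lp <- random_label_pair(60, 4)
  cm3 <- confusion_matrix(lp$truth, lp$pred)
  expect_equal(sum(cm3$absolute), 60)
  expect_equal(unname(rowSums(cm3$absolute)),
               unname(as.integer(table(factor(lp$truth,
                                              levels = rownames(cm3$absolute))))))
})

test_that("blocked folds are contiguous, disjoint and exhaustive", {
  f10 <- blocked_folds(10, 5)
  expect_true(all(vapply(f10, function(f) length(f$test), integer(1)) == 2L))
  f11 <- blocked_folds(11, 5)
  expect_equal(length(f11[[5]]$test), 3L)       # remainder to last block
  for (folds in list(f10, f11, blocked_folds(137, 5))) {
    tests <- lapply(folds, `[[`, "test")
    expect_true(all(vapply(tests, function(t)
      all(diff(t) == 1L), logical(1))))          # contiguous
    all_idx <- sort(unlist(tests))
    expect_identical(all_idx, seq_along(all_idx)) # partition
    for (f in folds)
      expect_length(intersect(f$train, f$test), 0L)
  }
  expect_error(blocked_folds(4, 5), "at least 5")
})

# A small but learnable multi-behavior window dataset for CV-level tests.
cv_dataset <- function(window = 4, seed = 21) {
  sim <- generate_track(
    data.frame(behavior = rep(c("standing", "eating", "walking"), 4),
               duration = 60),
    sim_config(seed = seed))
  nt <- normalize_track(sim$track)
  lf <- apply_labels(sim$labels, sim$track)
  sel <- select_features(sim$track)
  fm <- poseclass:::feature_matrix(nt$track, sel$parts, lf$frame_indices)
  make_windows(fm, window_spec(window, ncol(fm)), lf$frame_indices,
               lf$labels)
}

test_that("five-fold non-shuffled CV scores and reports are coherent", {
  ds <- cv_dataset()
  cfg <- classifier_config(n_estimators = 5, seed = 2)
  rep_ <- cv5_nonshuffled(ds, cfg)
  expect_length(rep_$fold_scores, 5L)
  expect_equal(rep_$cv_score, mean(rep_$fold_scores))
  expect_true(all(rep_$fold_scores >= 0 & rep_$fold_scores <= 1))
  expect_equal(sum(rep_$confusion$absolute),
               length(rep_$last_fold$truth))
  expect_equal(rep_$per_class$support,
               unname(vapply(rep_$per_class$class, function(cl)
                 sum(rep_$last_fold$truth == cl), numeric(1))))
  # weighted F1 of the stored last fold matches the last fold score
  expect_equal(weighted_f1(rep_$last_fold$truth, rep_$last_fold$pred),
               rep_$fold_scores[5])
})

test_that("a singleton validation curve equals the direct CV score", {
  ds <- cv_dataset()
  cfg <- classifier_config(n_estimators = 5, seed = 2)
  vc <- validation_curve("n_estimators", 5, dataset = ds, config = cfg)
  expect_equal(nrow(vc), 1L)
  expect_equal(vc$mean, cv5_nonshuffled(ds, cfg)$cv_score, tolerance = 1e-12)
  expect_error(validation_curve("max_depth", 3, dataset = ds), "unknown")
  expect_error(validation_curve("n_estimators", numeric(), dataset = ds),
               "non-empty")
})

test_that("learning curve at fraction 1 reproduces CV; bad fractions error", {
  ds <- cv_dataset()
  cfg <- classifier_config(n_estimators = 5, seed = 2)
  lc <- learning_curve(ds, c(0.5, 1), cfg)
  expect_equal(lc$mean[2], cv5_nonshuffled(ds, cfg)$cv_score,
               tolerance = 1e-12)
  expect_error(learning_curve(ds, 0), "\\(0, 1]")
  expect_error(learning_curve(ds, 1.5), "\\(0, 1]")
})
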