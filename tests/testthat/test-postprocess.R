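mk_probs <- function(m, classes, frames = seq_len(nrow(m)) - 1L) {
  probability_track(m, classes, frames)
}

test_that("argmax picks the maximal class with a deterministic tie-break", {
  pt <- mk_probs(rbind(c(0.1, 0.7, 0.2)), c("a", "b", "c"))
  pred <- argmax_prediction(pt)
  expect_equal(pred$behavior, "b")
  expect_equal(pred$probability, 0.7)
  expect_false(pred$tie)

  unif <- mk_probs(rbind(rep(1 / 3, 3)), c("a", "b", "c"))
  tied <- argmax_prediction(unif)
  expect_equal(tied$behavior, "a")   # first class in order
  expect_true(tied$tie)
})

test_that("probability tracks validate their invariants", {
  expect_error(mk_probs(rbind(c(0.5, 0.6)), c("a", "b")), "sum to 1")
  expect_error(mk_probs(rbind(c(1.2, -0.2)), c("a", "b")), "\\[0, 1\\]")
  expect_error(probability_track(rbind(c(0.5, 0.5)), "a", 0L), "one column")
})

test_that("tuple thresholds reassign the target when the fallback holds", {
  classes <- c("standing", "head_shake", "eating")
  pt <- mk_probs(rbind(c(0.25, 0.60, 0.15),
                       c(0.15, 0.70, 0.15),
                       c(0.10, 0.10, 0.80)), classes)
  pred <- argmax_prediction(pt)
  tup <- tuple_threshold("standing", "head_shake", 0.2)
  post <- apply_tuple_thresholds(pred, pt, tup)
  expect_equal(post$behavior, c("standing", "head_shake", "eating"))
  expect_identical(post$reassigned, c(TRUE, FALSE, FALSE))
  expect_equal(post$probability[1], 0.25)   # carries the fallback's mass

  # empty tuple list is the identity
  expect_identical(apply_tuple_thresholds(pred, pt, list()), pred)
  expect_error(apply_tuple_thresholds(pred, pt,
                                      tuple_threshold("standing", "hopping", 0.2)),
               "unknown class")
  expect_error(tuple_threshold("a", "a", 0.2), "differ")
  expect_error(tuple_threshold("a", "b", 1.2), "\\[0, 1\\]")
})

test_that("first matching tuple wins and at most one reassignment per frame", {
  classes <- c("standing", "eating", "head_shake")
  pt <- mk_probs(rbind(c(0.3, 0.3, 0.4)), classes)
  pred <- argmax_prediction(pt)
  tuples <- list(tuple_threshold("eating", "head_shake", 0.25),
                 tuple_threshold("standing", "head_shake", 0.25))
  post <- apply_tuple_thresholds(pred, pt, tuples)
  expect_equal(post$behavior, "eating")     # list order decides
  # second application target no longer matches; prediction unchanged
  post2 <- apply_tuple_thresholds(post, pt, tuples)
  expect_equal(post2$behavior, "eating")
})

test_that("the threshold acts monotonically on the target class count", {
  set.seed(8)
  n <- 200
  raw <- matrix(runif(3 * n), n, 3)
  raw <- raw / rowSums(raw)
  pt <- mk_probs(raw, c("standing", "head_shake", "eating"))
  pred <- argmax_prediction(pt)
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1.0000001), function(th) {
    post <- apply_tuple_thresholds(pred, pt,
                                   tuple_threshold("standing", "head_shake",
                                                   min(th, 1)))
    sum(post$behavior == "head_shake")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # threshold 0 reassigns every target-class frame
  post0 <- apply_tuple_thresholds(pred, pt,
                                  tuple_threshold("standing", "head_shake", 0))
  expect_equal(sum(post0$behavior == "head_shake"), 0)
  # unreachable threshold is the identity
  post1 <- apply_tuple_thresholds(pred, pt,
                                  tuple_threshold("standing", "head_shake", 1))
  expect_equal(post1$behavior, pred$behavior)
})
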