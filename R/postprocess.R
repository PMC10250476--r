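#' Argmax behavior prediction
#'
#' The conservative decision rule: each frame is assigned the class of
#' maximal probability, `b(f) = argmax(x_p(f))`. Ties break
#' deterministically to the first class in class order and are flagged.
#'
#' @param probs a [probability_track()].
#' @return A `prediction_track`: data frame with columns `frame`,
#'   `behavior`, `probability`, `reassigned` (logical), `tie` (logical),
#'   plus a `classes` attribute.
#' @export
argmax_prediction <- function(probs) {
  stopifnot(inherits(probs, "probability_track"))
  p <- probs$probs
  if (nrow(p) == 0L) {
    out <- data.frame(frame = integer(), behavior = character(),
                      probability = numeric(), reassigned = logical(),
                      tie = logical())
  } else {
    j <- max.col(p, ties.method = "first")
    win <- p[cbind(seq_len(nrow(p)), j)]
    tie <- rowSums(p == win) > 1L
    out <- data.frame(frame = probs$anchor_frames,
                      behavior = probs$classes[j],
                      probability = win,
                      reassigned = FALSE,
                      tie = tie)
  }
  structure(out, classes = probs$classes,
            class = c("prediction_track", "data.frame"))
}

#' Pairwise tuple thresholds
#'
#' A tuple `(fallback, target): threshold` overrides an argmax prediction
#' of `target` whenever the probability assigned to `fallback` reaches the
#' threshold — trading recall of the target class for precision. The
#' canonical example is `(standing, head_shake): 0.2`: a frame predicted as
#' head shake is demoted to standing whenever standing still holds at least
#' probability 0.2.
#'
#' @param fallback class to fall back to.
#' @param target class whose argmax prediction may be overridden.
#' @param threshold fallback-probability threshold in `[0, 1]`.
#' @return A `tuple_threshold` list.
#' @export
tuple_threshold <- function(fallback, target, threshold) {
  if (identical(fallback, target))
    stop("fallback and target must differ")
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  structure(list(fallback = fallback, target = target,
                 threshold = threshold),
            class = "tuple_threshold")
}

#' Apply tuple thresholds to argmax predictions
#'
#' Tuples are applied in list order; the first tuple matching a frame wins
#' and at most one reassignment happens per frame. A frame matches a tuple
#' when its current prediction equals the tuple's target and the fallback
#' class's probability is at least the tuple's threshold. Reassigned frames
#' are flagged and carry the fallback's probability.
#'
#' @param preds a `prediction_track` from [argmax_prediction()].
#' @param probs the [probability_track()] the predictions came from.
#' @param tuples list of [tuple_threshold()] objects (or a single one).
#' @return the modified `prediction_track`.
#' @export
apply_tuple_thresholds <- function(preds, probs, tuples) {
  stopifnot(inherits(preds, "prediction_track"),
            inherits(probs, "probability_track"))
  if (inherits(tuples, "tuple_threshold")) tuples <- list(tuples)
  if (length(tuples) == 0L) return(preds)
  for (tp in tuples) {
    unknown <- setdiff(c(tp$fallback, tp$target), probs$classes)
    if (length(unknown))
      stop("tuple threshold references unknown class: ", unknown[1])
  }
  done <- rep(FALSE, nrow(preds))
  for (tp in tuples) {
    hit <- !done & preds$behavior == tp$target &
      probs$probs[, tp$fallback] >= tp$threshold
    if (any(hit)) {
      preds$behavior[hit] <- tp$fallback
      preds$probability[hit] <- probs$probs[hit, tp$fallback]
      preds$reassigned[hit] <- TRUE
      done <- done | hit
    }
  }
  preds
}
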