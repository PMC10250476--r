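#' Select stable features by mean tracking likelihood
#'
#' Keypoints whose tracking confidence is chronically low (the beak of a
#' feeding pigeon is frequently occluded by its own body, for instance)
#' destabilise the classifier; they are dropped wholesale. A part is kept
#' when its mean likelihood over the track is at least
#' `min_mean_likelihood`; the features are then the x and y coordinates of
#' the kept parts, in part order.
#'
#' @param track a [pose_track()] with likelihoods.
#' @param min_mean_likelihood threshold in `[0, 1]`; default 0.6, matching
#'   the usual pose-estimation prediction cutoff.
#' @return List with `features` (character vector like `"head_x"`,
#'   `"head_y"`, ...), `parts` (kept part names) and `excluded` (dropped
#'   part names).
#' @export
select_features <- function(track, min_mean_likelihood = 0.6) {
  stopifnot(inherits(track, "pose_track"))
  mean_lik <- colMeans(track$likelihood)
  keep <- mean_lik >= min_mean_likelihood
  if (!any(keep))
    stop("all body parts fall below the mean-likelihood threshold (",
         min_mean_likelihood, ")")
  parts <- track$parts[keep]
  list(
    features = as.vector(t(outer(parts, c("x", "y"), paste, sep = "_"))),
    parts = parts,
    excluded = track$parts[!keep]
  )
}

#' Sliding-window specification
#'
#' @param window_size window length in frames (>= 1).
#' @param n_features number of scalar features per frame.
#' @return A `window_spec` list; the flattened input-vector length is
#'   `n_features * window_size`.
#' @export
window_spec <- function(window_size, n_features) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L)
    stop("window_size must be a positive integer")
  structure(list(window_size = window_size, step = 1L,
                 n_features = as.integer(n_features)),
            class = "window_spec")
}

# Per-frame feature matrix (frames x 2*parts) for the kept parts of a
# normalized track, restricted to the given original frame indices.
feature_matrix <- function(track, parts, frame_indices = NULL) {
  idx <- if (is.null(frame_indices)) seq_len(n_frames(track)) else
    frame_indices + 1L
  cols <- match(parts, track$parts)
  np <- length(cols)
  m <- matrix(NA_real_, length(idx), 2L * np)
  m[, seq(1L, by = 2L, length.out = np)] <- track$x[idx, cols, drop = FALSE]
  m[, seq(2L, by = 2L, length.out = np)] <- track$y[idx, cols, drop = FALSE]
  colnames(m) <- as.vector(t(outer(parts, c("x", "y"), paste, sep = "_")))
  m
}

#' Segment labeled frames into sliding windows
#'
#' Slides a window of `window_size` frames with step 1 over the feature
#' time series and flattens each window into one classifier input vector of
#' length `n_features * window_size` (frame features concatenated in time
#' order). In training mode a window is emitted only when it lies entirely
#' inside a contiguous run of identically labeled frames — windows never
#' straddle a label boundary or a gap left by unlabeled-frame removal — and
#' carries that run's label. In inference mode (`labels = NULL`) every
#' window over a contiguous frame run is emitted, unlabeled. Each window is
#' attributed to its last frame (causal anchoring), so a prediction for a
#' window refers to the moment the window ends.
#'
#' @param features numeric matrix, one row per frame in temporal order.
#' @param frame_indices 0-based original frame index per row; gaps break
#'   runs. Defaults to `0:(nrow-1)`.
#' @param labels behavior per row, or `NULL` for inference mode.
#' @param spec a [window_spec()]; its `n_features` must equal
#'   `ncol(features)`.
#' @return A `window_dataset`: list with matrix `x` (windows x
#'   `n_features * window_size`), `labels` (character or `NULL`),
#'   `anchor_frames` (0-based original index of each window's last frame)
#'   and `spec`.
#' @export
make_windows <- function(features, spec, frame_indices = NULL,
                         labels = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  features <- as.matrix(features)
  nfr <- nrow(features)
  if (ncol(features) != spec$n_features)
    stop("feature matrix has ", ncol(features), " columns but spec expects ",
         spec$n_features)
  if (is.null(frame_indices)) frame_indices <- seq_len(nfr) - 1L
  w <- spec$window_size

  # runs: maximal stretches that are frame-contiguous and (training mode)
  # share one label
  brk <- diff(frame_indices) != 1L
  if (!is.null(labels)) brk <- brk | labels[-1L] != labels[-nfr]
  run_id <- if (nfr > 0L) cumsum(c(TRUE, brk)) else integer()
  starts <- which(!duplicated(run_id))
  ends <- if (length(starts)) c(starts[-1L] - 1L, nfr) else integer()

  rows_list <- list()
  lab_out <- character()
  anchor <- integer()
  for (r in seq_along(starts)) {
    a <- starts[r]; b <- ends[r]
    len <- b - a + 1L
    if (len < w) next
    pos <- a:(b - w + 1L)                      # window start rows
    idx <- outer(pos, 0:(w - 1L), `+`)         # n_win x w row indices
    flat <- matrix(t(features[as.vector(t(idx)), , drop = FALSE]),
                   nrow = nrow(idx), byrow = TRUE)
    rows_list[[length(rows_list) + 1L]] <- flat
    anchor <- c(anchor, frame_indices[pos + w - 1L])
    if (!is.null(labels))
      lab_out <- c(lab_out, rep(labels[a], length(pos)))
  }
  x <- if (length(rows_list)) do.call(rbind, rows_list) else
    matrix(numeric(), 0L, spec$n_features * w)
  base_names <- colnames(features)
  if (is.null(base_names)) base_names <- paste0("f", seq_len(spec$n_features))
  colnames(x) <- paste0(rep(base_names, w), "_t",
                        rep(seq_len(w) - 1L, each = spec$n_features))
  structure(
    list(x = x,
         labels = if (is.null(labels)) NULL else lab_out,
         anchor_frames = as.integer(anchor),
         spec = spec),
    class = "window_dataset"
  )
}

#' @export
print.window_dataset <- function(x, ...) {
  cat("<window_dataset> ", nrow(x$x), " windows of ", x$spec$window_size,
      " frame(s), vector length ", ncol(x$x),
      if (is.null(x$labels)) " (unlabeled)" else "", "\n", sep = "")
  invisible(x)
}

# Subset a window dataset by window index (used by cross-validation).
subset_windows <- function(ds, i) {
  structure(
    list(x = ds$x[i, , drop = FALSE],
         labels = if (is.null(ds$labels)) NULL else ds$labels[i],
         anchor_frames = ds$anchor_frames[i],
         spec = ds$spec),
    class = "window_dataset"
  )
}
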