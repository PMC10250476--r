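#' Construct a pose track
#'
#' A pose track holds, for every video frame, the image coordinates and the
#' tracking confidence ("likelihood") of a named set of body parts, as
#' produced by markerless pose estimators such as DeepLabCut. Frames are
#' 0-based and contiguous; row `i` of each matrix is frame `i - 1`.
#'
#' @param x numeric matrix, frames x parts, x coordinates in pixels.
#' @param y numeric matrix, frames x parts, y coordinates in pixels.
#' @param likelihood numeric matrix in `[0, 1]`, frames x parts, or `NULL`
#'   (treated as all 1).
#' @param parts character vector of unique body-part names, one per column.
#' @param fps frames per second, or `NA` when unknown.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(x, y, likelihood = NULL, parts = colnames(x),
                       fps = NA_real_) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (is.null(parts)) stop("body-part names are required")
  parts <- as.character(parts)
  if (anyDuplicated(parts)) stop("body-part names must be unique")
  if (length(parts) == 0L) stop("at least one body part is required")
  if (!identical(dim(x), dim(y)))
    stop("x and y coordinate matrices must have identical dimensions")
  if (ncol(x) != length(parts))
    stop("number of columns must equal the number of body parts")
  if (is.null(likelihood)) {
    likelihood <- matrix(1, nrow(x), ncol(x))
  } else {
    likelihood <- as.matrix(likelihood)
    if (!identical(dim(likelihood), dim(x)))
      stop("likelihood matrix must match coordinate dimensions")
  }
  if (nrow(x) > 0L) {
    if (!all(is.finite(x)) || !all(is.finite(y)))
      stop("coordinates must be finite")
    if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE))
      stop("likelihood values must lie in [0, 1]")
  }
  dimnames(x) <- dimnames(y) <- dimnames(likelihood) <- list(NULL, parts)
  structure(
    list(x = x, y = y, likelihood = likelihood, parts = parts,
         fps = as.numeric(fps)),
    class = "pose_track"
  )
}

#' Number of frames in a pose track
#' @param track a `pose_track`.
#' @return integer frame count.
#' @export
n_frames <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  nrow(track$x)
}

#' @export
print.pose_track <- function(x, ...) {
  cat("<pose_track> ", nrow(x$x), " frames, ", length(x$parts), " body parts",
      if (!is.na(x$fps)) sprintf(", %.2f fps", x$fps), "\n", sep = "")
  cat("  parts: ", paste(x$parts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Extract one frame as a parts x 2 coordinate matrix (rows named by part).
frame_coords <- function(track, frame) {
  i <- frame + 1L
  m <- cbind(x = track$x[i, ], y = track$y[i, ])
  rownames(m) <- track$parts
  m
}

require_parts <- function(track, needed) {
  missing <- setdiff(needed, track$parts)
  if (length(missing))
    stop("pose track is missing required body part(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
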