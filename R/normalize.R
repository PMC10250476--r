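#' Egocentric normalization of pose tracks
#'
#' Markerless pose estimators report absolute image coordinates, but behavior
#' lives in the animal's own reference frame. Normalization makes each frame
#' egocentric in two steps, applied independently per frame:
#'
#' 1. *Translation*: the displacement vector `s = (-x_body, -y_body)` is
#'    added to every body part, putting the body at the origin.
#' 2. *Rotation*: a synthetic body part, the *middle neck* vector
#'    `v = v_left_neck - v_right_neck` (computed on translated coordinates),
#'    defines the heading. The rotation angle is
#'    `rot = atan2(v_x, v_y) * 180 / pi` — the signed angle of `v` measured
#'    from the positive y axis — and the counter-clockwise rotation matrix
#'    `R = [[cos, -sin], [sin, cos]]` by that angle is applied to all parts,
#'    which maps `v` onto the non-negative y axis.
#'
#' The transform removes global position and heading while preserving all
#' within-frame geometry (it is a rigid motion), so two tracks differing
#' only by a global rotation plus shift normalize identically.
#'
#' @name normalization
NULL

#' Displacement vector of a frame
#'
#' @param frame a parts x 2 coordinate matrix with rownames, as one frame of
#'   a pose track.
#' @param body name of the body-center part.
#' @return length-2 numeric vector `(-x_body, -y_body)`.
#' @export
displacement_vector <- function(frame, body = "body") {
  if (!body %in% rownames(frame))
    stop("frame has no part named '", body, "'")
  -frame[body, c("x", "y")]
}

#' Translate all parts of a frame by a vector
#'
#' @param frame a parts x 2 coordinate matrix.
#' @param s length-2 translation vector.
#' @return the translated coordinate matrix.
#' @export
translate_frame <- function(frame, s) {
  stopifnot(length(s) == 2L, all(is.finite(s)))
  sweep(frame, 2L, -as.numeric(s))
}

#' Middle-neck vector of a frame
#'
#' The difference between the left- and right-neck keypoints. `mode =
#' "midpoint"` instead returns the point halfway between them (relative to
#' the origin); the difference form is the default heading definition.
#'
#' @param frame a parts x 2 coordinate matrix (translated coordinates).
#' @param mode `"difference"` (left minus right) or `"midpoint"`.
#' @return length-2 numeric vector.
#' @export
middle_neck <- function(frame, mode = c("difference", "midpoint")) {
  mode <- match.arg(mode)
  need <- c("left_neck", "right_neck")
  miss <- setdiff(need, rownames(frame))
  if (length(miss))
    stop("frame has no part named '", miss[1], "'")
  l <- frame["left_neck", c("x", "y")]
  r <- frame["right_neck", c("x", "y")]
  if (mode == "difference") l - r else (l + r) / 2
}

#' Rotation angle aligning a vector with the positive y axis
#'
#' @param v length-2 numeric vector; the zero vector is degenerate and maps
#'   to 0 degrees.
#' @return signed angle in degrees in `(-180, 180]`.
#' @export
rotation_angle <- function(v) {
  stopifnot(length(v) == 2L)
  if (v[1] == 0 && v[2] == 0) return(0)
  atan2(v[1], v[2]) * 180 / pi
}

# Counter-clockwise rotation matrix for an angle in degrees.
rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

#' Rotate all parts of a frame counter-clockwise
#'
#' @param frame a parts x 2 coordinate matrix (already translated).
#' @param rot_norm rotation angle in degrees.
#' @return the rotated coordinate matrix.
#' @export
apply_rotation <- function(frame, rot_norm) {
  out <- frame %*% t(rotation_matrix(rot_norm))
  colnames(out) <- c("x", "y")
  out
}

#' Normalize a pose track into the egocentric frame
#'
#' Applies the per-frame translation and rotation described in
#' [normalization] to every frame. Likelihoods pass through unchanged.
#' Frames whose middle-neck vector is the zero vector are degenerate: they
#' are translated but not rotated (angle 0) and flagged in the state.
#'
#' @param track a [pose_track()] containing parts `body`, `left_neck`,
#'   `right_neck`.
#' @param middle_neck_mode heading definition, see [middle_neck()].
#' @return A list of class `normalized_track` with elements `track` (the
#'   normalized [pose_track()]) and `state`, a data frame with per-frame
#'   columns `s_x`, `s_y` (displacement), `v_x`, `v_y` (middle-neck vector),
#'   `rot_norm` (degrees) and `degenerate`.
#' @export
normalize_track <- function(track, middle_neck_mode = "difference") {
  stopifnot(inherits(track, "pose_track"))
  require_parts(track, c("body", "left_neck", "right_neck"))
  nf <- n_frames(track)
  ib <- match("body", track$parts)
  il <- match("left_neck", track$parts)
  ir <- match("right_neck", track$parts)

  s_x <- -track$x[, ib]
  s_y <- -track$y[, ib]
  tx <- track$x + s_x   # recycles per column: frames x parts + frames vector
  ty <- track$y + s_y
  if (identical(middle_neck_mode, "midpoint")) {
    v_x <- (tx[, il] + tx[, ir]) / 2
    v_y <- (ty[, il] + ty[, ir]) / 2
  } else {
    v_x <- tx[, il] - tx[, ir]
    v_y <- ty[, il] - ty[, ir]
  }
  degenerate <- v_x == 0 & v_y == 0
  rot <- ifelse(degenerate, 0, atan2(v_x, v_y) * 180 / pi)
  a <- rot * pi / 180
  ca <- cos(a); sa <- sin(a)
  # R %*% (x, y) = (x cos - y sin, x sin + y cos), vectorized over frames
  nx <- tx * ca - ty * sa
  ny <- tx * sa + ty * ca
  if (nf == 0L) { nx <- tx; ny <- ty }
  ndeg <- sum(degenerate)
  if (ndeg > 0L)
    message(ndeg, " frame(s) with degenerate middle-neck vector; left unrotated")
  state <- data.frame(
    frame = seq_len(nf) - 1L, s_x = s_x, s_y = s_y,
    v_x = v_x, v_y = v_y, rot_norm = rot, degenerate = degenerate,
    row.names = NULL
  )
  structure(
    list(track = pose_track(nx, ny, track$likelihood, parts = track$parts,
                            fps = track$fps),
         state = state),
    class = "normalized_track"
  )
}

#' @export
print.normalized_track <- function(x, ...) {
  cat("<normalized_track> ", n_frames(x$track), " frames (",
      sum(x$state$degenerate), " degenerate)\n", sep = "")
  invisible(x)
}
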