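#' Read a pose track from a DeepLabCut-dialect CSV file
#'
#' The DeepLabCut CSV dialect has three header rows (`scorer`, `bodyparts`,
#' `coords`), a first column holding the frame index, and then an
#' `x, y, likelihood` column triple per body part. Row order is preserved as
#' frame order. A file whose coords row carries only `x, y` pairs (no
#' likelihood) is rejected unless `allow_missing_likelihood = TRUE`, in which
#' case likelihoods are filled with 1 and a message is emitted.
#'
#' @param path path to the CSV file.
#' @param fps optional frames-per-second metadata attached to the result.
#' @param allow_missing_likelihood tolerate `x, y`-only files (hand-made
#'   fixtures); the likelihood matrix is then all 1.
#' @return A [pose_track()].
#' @export
read_pose_csv <- function(path, fps = NA_real_,
                          allow_missing_likelihood = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("malformed pose CSV: expected 3 header rows (scorer / bodyparts / coords), got ",
         length(lines), " line(s)")
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  tags <- vapply(hdr, `[`, character(1), 1L)
  expected <- c("scorer", "bodyparts", "coords")
  bad <- which(tolower(tags) != expected)
  if (length(bad))
    stop("malformed pose CSV header: row ", bad[1], " should start with '",
         expected[bad[1]], "' but reads '", tags[bad[1]], "'")
  bodyparts <- hdr[[2]][-1]
  coords <- hdr[[3]][-1]
  if (length(bodyparts) != length(coords))
    stop("malformed pose CSV header: bodyparts row has ", length(bodyparts),
         " entries but coords row has ", length(coords))

  parts <- unique(bodyparts)
  has_lik <- "likelihood" %in% coords
  cycle <- if (has_lik) c("x", "y", "likelihood") else c("x", "y")
  k <- length(cycle)
  if (length(coords) %% k != 0L ||
      !identical(coords, rep(cycle, length(coords) %/% k)))
    stop("malformed pose CSV header: coords row must cycle ",
         paste(cycle, collapse = ","), " per body part; got: ",
         paste(utils::head(coords, 6), collapse = ","))
  if (!identical(bodyparts, rep(parts, each = k)))
    stop("malformed pose CSV header: bodyparts row does not repeat each part ",
         k, " times in order")
  if (!has_lik && !allow_missing_likelihood)
    stop("malformed pose CSV header: coords row has no likelihood column")

  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  nf <- length(body)
  np <- length(parts)
  xm <- matrix(NA_real_, nf, np)
  ym <- matrix(NA_real_, nf, np)
  lm <- matrix(1, nf, np)
  if (nf > 0L) {
    cells <- strsplit(body, ",", fixed = TRUE)
    width <- 1L + np * k
    for (i in seq_len(nf)) {
      row <- cells[[i]]
      if (length(row) != width)
        stop("parse error at frame ", i - 1L, ": expected ", width,
             " fields, got ", length(row))
      vals <- suppressWarnings(as.numeric(row[-1L]))
      if (anyNA(vals)) {
        j <- which(is.na(vals))[1]
        stop("parse error at frame ", i - 1L, ", part '",
             parts[(j - 1L) %/% k + 1L], "': non-numeric cell '",
             row[-1L][j], "'")
      }
      idx <- seq(1L, by = k, length.out = np)
      xm[i, ] <- vals[idx]
      ym[i, ] <- vals[idx + 1L]
      if (has_lik) lm[i, ] <- vals[idx + 2L]
    }
  }
  if (!has_lik)
    message("pose CSV has no likelihood columns; filling likelihood with 1.0")
  pose_track(xm, ym, lm, parts = parts, fps = fps)
}

#' Write a pose track as a DeepLabCut-dialect CSV file
#'
#' Values are serialized with enough digits that
#' `read_pose_csv(write_pose_csv(track))` reproduces coordinates and
#' likelihoods to at least 1e-6.
#'
#' @param track a [pose_track()].
#' @param path output path.
#' @param scorer scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "poseclass") {
  stopifnot(inherits(track, "pose_track"))
  np <- length(track$parts)
  hdr1 <- paste(c("scorer", rep(scorer, 3L * np)), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(track$parts, each = 3L)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), np)), collapse = ",")
  nf <- nrow(track$x)
  rows <- character(nf)
  if (nf > 0L) {
    wide <- matrix(NA_real_, nf, 3L * np)
    wide[, seq(1L, by = 3L, length.out = np)] <- track$x
    wide[, seq(2L, by = 3L, length.out = np)] <- track$y
    wide[, seq(3L, by = 3L, length.out = np)] <- track$likelihood
    rows <- paste(seq_len(nf) - 1L,
                  apply(wide, 1L, function(v)
                    paste(formatC(v, format = "g", digits = 10),
                          collapse = ",")),
                  sep = ",")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr1, hdr2, hdr3, rows), con)
  invisible(path)
}

#' Read or write frame-range behavior labels
#'
#' Label files are plain CSV with columns `start_frame`, `end_frame`,
#' `behavior`. Frames are 0-based and ranges are inclusive on both ends.
#'
#' @param path path to the label CSV.
#' @param vocabulary optional character vector of admissible behavior names;
#'   defaults to the distinct behaviors found in the file.
#' @return A `label_set`: a data frame with columns `start_frame`,
#'   `end_frame`, `behavior`, and a `vocabulary` attribute.
#' @export
read_labels <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_frame", "end_frame", "behavior")
  if (!all(need %in% names(df)))
    stop("label CSV must have columns ", paste(need, collapse = ", "))
  label_set(df$start_frame, df$end_frame, df$behavior, vocabulary)
}

#' @rdname read_labels
#' @param labels a `label_set`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_set"))
  utils::write.csv(as.data.frame(unclass(labels))[
    c("start_frame", "end_frame", "behavior")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a label set
#'
#' @param start_frame,end_frame 0-based inclusive frame bounds.
#' @param behavior behavior name per slice.
#' @param vocabulary admissible behavior names (default: distinct behaviors).
#' @return A `label_set` data frame.
#' @export
label_set <- function(start_frame, end_frame, behavior, vocabulary = NULL) {
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  behavior <- as.character(behavior)
  n <- length(behavior)
  if (length(start_frame) != n || length(end_frame) != n)
    stop("start_frame, end_frame and behavior must have equal length")
  bad <- which(start_frame > end_frame)
  if (length(bad))
    stop("invalid time slice at row ", bad[1], ": start_frame ",
         start_frame[bad[1]], " > end_frame ", end_frame[bad[1]])
  if (any(start_frame < 0L))
    stop("frame indices must be non-negative (0-based)")
  if (is.null(vocabulary)) vocabulary <- unique(behavior)
  structure(
    data.frame(start_frame = start_frame, end_frame = end_frame,
               behavior = behavior, stringsAsFactors = FALSE),
    vocabulary = as.character(vocabulary),
    class = c("label_set", "data.frame")
  )
}

#' Expected frame count of a recording
#'
#' Number of frames a recording of a given duration yields at a given frame
#' rate: `round(duration_s * fps)`. A 10-minute recording at 119.88 fps, for
#' example, yields 71,928 frames.
#'
#' @param duration_s duration in seconds, positive.
#' @param fps frame rate in frames per second, positive.
#' @return integer frame count.
#' @export
expected_frame_count <- function(duration_s, fps) {
  if (any(duration_s <= 0) || any(fps <= 0))
    stop("duration_s and fps must be positive")
  as.integer(round(duration_s * fps))
}

#' Per-frame size of keypoint-reduced video data
#'
#' Pose estimation reduces each decompressed video frame to a handful of
#' coordinates: `n_parts * coords_per_part * bit_depth` bits per frame
#' (e.g. 10 parts x 2 coordinates x 32 bit = 640 bit).
#'
#' @param n_parts number of tracked body parts.
#' @param coords_per_part coordinates stored per part (2 for x, y).
#' @param bit_depth bits per coordinate value.
#' @return bits per frame.
#' @export
reduced_bits_per_frame <- function(n_parts, coords_per_part, bit_depth) {
  if (any(c(n_parts, coords_per_part, bit_depth) <= 0) ||
      any(c(n_parts, coords_per_part, bit_depth) %% 1 != 0))
    stop("all arguments must be positive integers")
  n_parts * coords_per_part * bit_depth
}
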