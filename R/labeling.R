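#' Validate behavior labels against a pose track
#'
#' Checks the integrity of a frame-range label set before it is applied:
#' behavior names must match the vocabulary exactly after trimming
#' surrounding whitespace and lower-casing (anything else — stray
#' capitalisation, trailing spaces, typos — is reported), slices must not
#' overlap, and no slice may extend beyond the track.
#'
#' @param labels a [label_set()].
#' @param track a [pose_track()] the labels refer to.
#' @param vocabulary admissible behavior names; defaults to the label set's
#'   own vocabulary attribute.
#' @return A `label_report`: list with character vector `name_issues`,
#'   data frames `overlaps` and `out_of_range`, and logical `valid`.
#' @export
validate_labels <- function(labels, track,
                            vocabulary = attr(labels, "vocabulary")) {
  stopifnot(inherits(labels, "label_set"), inherits(track, "pose_track"))
  canon <- function(x) tolower(trimws(x))
  bad <- which(!(labels$behavior %in% vocabulary))
  near <- canon(labels$behavior[bad]) %in% canon(vocabulary)
  name_issues <- c(
    sprintf("row %d: behavior '%s' differs from a vocabulary entry only by case/whitespace",
            bad[near], labels$behavior[bad[near]]),
    sprintf("row %d: behavior '%s' is not in the vocabulary",
            bad[!near], labels$behavior[bad[!near]])
  )

  ov <- NULL
  if (nrow(labels) > 1L) {
    o <- order(labels$start_frame, labels$end_frame)
    s <- labels$start_frame[o]; e <- labels$end_frame[o]
    clash <- which(s[-1] <= e[-length(e)])
    if (length(clash))
      ov <- data.frame(row_a = o[clash], row_b = o[clash + 1L])
  }
  if (is.null(ov)) ov <- data.frame(row_a = integer(), row_b = integer())

  nf <- n_frames(track)
  oob <- which(labels$end_frame > nf - 1L)
  out_of_range <- data.frame(row = oob,
                             end_frame = labels$end_frame[oob],
                             track_frames = rep(nf, length(oob)))
  rep_ <- list(name_issues = name_issues, overlaps = ov,
               out_of_range = out_of_range)
  rep_$valid <- length(name_issues) == 0L && nrow(ov) == 0L &&
    length(oob) == 0L
  class(rep_) <- "label_report"
  rep_
}

#' @export
print.label_report <- function(x, ...) {
  if (x$valid) {
    cat("<label_report> valid: no findings\n")
  } else {
    cat("<label_report> INVALID:\n")
    if (length(x$name_issues))
      cat("  name issues:\n", paste0("    ", x$name_issues, "\n"), sep = "")
    if (nrow(x$overlaps))
      cat("  overlapping slices (rows): ",
          paste(sprintf("%d/%d", x$overlaps$row_a, x$overlaps$row_b),
                collapse = ", "), "\n", sep = "")
    if (nrow(x$out_of_range))
      cat("  slices beyond track end (rows): ",
          paste(x$out_of_range$row, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Apply frame-range labels to a track, dropping unlabeled frames
#'
#' Every frame inside a slice receives that slice's behavior; frames covered
#' by no slice are removed. Original frame indices are retained so that
#' windows and predictions remain traceable to the source video.
#'
#' @param labels a [label_set()]; must pass [validate_labels()].
#' @param track a [pose_track()].
#' @return A `labeled_frames` object: list with `frame_indices` (0-based
#'   original indices, ascending), `labels` (behavior per retained frame)
#'   and `class_counts` (named integer vector).
#' @export
apply_labels <- function(labels, track) {
  rep_ <- validate_labels(labels, track)
  if (!rep_$valid) {
    print(rep_)
    stop("label set failed validation; see report above")
  }
  frames <- integer(0)
  behav <- character(0)
  if (nrow(labels) > 0L) {
    o <- order(labels$start_frame)
    frames <- unlist(lapply(o, function(i)
      labels$start_frame[i]:labels$end_frame[i]), use.names = FALSE)
    behav <- rep(labels$behavior[o],
                 labels$end_frame[o] - labels$start_frame[o] + 1L)
  }
  counts <- table(factor(behav, levels = sort(unique(behav))))
  structure(
    list(frame_indices = as.integer(frames), labels = behav,
         class_counts = stats::setNames(as.integer(counts), names(counts))),
    class = "labeled_frames"
  )
}

#' @export
print.labeled_frames <- function(x, ...) {
  cat("<labeled_frames> ", length(x$frame_indices), " labeled frames, ",
      length(x$class_counts), " classes\n", sep = "")
  if (length(x$class_counts)) print(x$class_counts)
  invisible(x)
}
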