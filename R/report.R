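#' Build an ethogram from a prediction track
#'
#' An ethogram is the time-resolved catalogue of predicted behaviors: one
#' behavior per predicted frame, drawn as class rows over time. Returns the
#' ethogram object and optionally writes a CSV (`frame, behavior,
#' probability, reassigned`) and a plot file; the CSV is lossless with
#' respect to the prediction labels.
#'
#' @param preds a non-empty `prediction_track`.
#' @param csv optional path for the CSV.
#' @param plot_file optional path for a PNG or SVG plot.
#' @return An `ethogram`: data frame `(frame, behavior, probability,
#'   reassigned)` with a `classes` attribute.
#' @export
make_ethogram <- function(preds, csv = NULL, plot_file = NULL) {
  stopifnot(inherits(preds, "prediction_track"))
  if (nrow(preds) == 0L) stop("prediction track is empty")
  classes <- attr(preds, "classes")
  etho <- data.frame(frame = preds$frame, behavior = preds$behavior,
                     probability = preds$probability,
                     reassigned = preds$reassigned)
  attr(etho, "classes") <- classes
  class(etho) <- c("ethogram", "data.frame")
  if (!is.null(csv))
    utils::write.csv(as.data.frame(unclass(etho))[
      c("frame", "behavior", "probability", "reassigned")],
      csv, row.names = FALSE, quote = FALSE)
  if (!is.null(plot_file)) {
    ext <- tolower(tools::file_ext(plot_file))
    if (ext == "svg") grDevices::svg(plot_file, width = 9, height = 4)
    else grDevices::png(plot_file, width = 1200, height = 500)
    plot(etho)
    grDevices::dev.off()
  }
  etho
}

#' @export
plot.ethogram <- function(x, ...) {
  classes <- attr(x, "classes")
  if (is.null(classes)) classes <- sort(unique(x$behavior))
  yi <- match(x$behavior, classes)
  graphics::plot(NA, xlim = range(x$frame), ylim = c(0.5, length(classes) + 0.5),
                 xlab = "frame", ylab = "", yaxt = "n",
                 main = "Ethogram of predicted behaviors", ...)
  graphics::axis(2, at = seq_along(classes), labels = classes, las = 1,
                 cex.axis = 0.8)
  cols <- grDevices::hcl.colors(length(classes), "Dark 3")
  graphics::segments(x$frame, yi - 0.35, x$frame, yi + 0.35,
                     col = cols[yi])
  invisible(x)
}

# Frame index -> SRT timestamp "HH:MM:SS,mmm"
srt_time <- function(frame, fps) {
  s <- frame / fps
  h <- floor(s / 3600); s <- s - 3600 * h
  m <- floor(s / 60); s <- s - 60 * m
  sprintf("%02d:%02d:%02d,%03d", h, m, floor(s), round((s - floor(s)) * 1000))
}

#' Subtitle-style overlay manifest
#'
#' Writes the predictions as an SRT subtitle file: one cue per maximal run
#' of constant predicted behavior, spanning from the run's first frame to
#' just past its last. Any external video player or renderer can lay the
#' cues over the original recording, so no video codec enters the package.
#'
#' @param preds a `prediction_track`.
#' @param fps frame rate of the source video (frames/second).
#' @param path optional output path; when `NULL` the cue table is returned
#'   only.
#' @return data frame with columns `start_frame`, `end_frame`, `behavior`,
#'   `start_time`, `end_time`.
#' @export
overlay_manifest <- function(preds, fps, path = NULL) {
  stopifnot(inherits(preds, "prediction_track"))
  if (missing(fps) || is.null(fps) || is.na(fps))
    stop("fps is required to convert frames to times")
  if (nrow(preds) == 0L) {
    cues <- data.frame(start_frame = integer(), end_frame = integer(),
                       behavior = character(), start_time = character(),
                       end_time = character())
  } else {
    o <- order(preds$frame)
    b <- preds$behavior[o]; f <- preds$frame[o]
    new_run <- c(TRUE, b[-1] != b[-length(b)] | diff(f) != 1L)
    run <- cumsum(new_run)
    start_f <- f[new_run]
    end_f <- f[c(new_run[-1], TRUE)]
    cues <- data.frame(
      start_frame = start_f, end_frame = end_f,
      behavior = b[new_run],
      start_time = srt_time(start_f, fps),
      end_time = srt_time(end_f + 1L, fps),
      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    blocks <- if (nrow(cues)) unlist(lapply(seq_len(nrow(cues)), function(i)
      c(i, paste(cues$start_time[i], "-->", cues$end_time[i]),
        cues$behavior[i], ""))) else character()
    writeLines(blocks, path)
  }
  cues
}
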