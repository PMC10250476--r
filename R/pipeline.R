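#' Assemble a pipeline configuration
#'
#' The pipeline chains the stages: normalize -> label -> feature selection
#' -> windowing -> train/evaluate (or predict) -> post-process -> report.
#' A configuration plus a seed fully determines every numeric output.
#'
#' @param track path to a pose CSV (DeepLabCut dialect).
#' @param labels path to a label CSV (train mode).
#' @param out output directory.
#' @param mode `"train"` or `"predict"`.
#' @param model path to a saved model (`.rds`, predict mode).
#' @param window_size sliding-window length in frames.
#' @param min_likelihood mean-likelihood cutoff for feature selection.
#' @param n_estimators number of trees.
#' @param seed integer seed.
#' @param fps frame rate (for the overlay manifest).
#' @param tuples list of `list(fallback=, target=, threshold=)` entries
#'   applied in order after the argmax rule.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(track, labels = NULL, out = ".",
                            mode = c("train", "predict"), model = NULL,
                            window_size = 16L, min_likelihood = 0.6,
                            n_estimators = 20L, seed = 1L, fps = 119.88,
                            tuples = list()) {
  mode <- match.arg(mode)
  if (mode == "train" && is.null(labels))
    stop("pipeline stage 'labeling': train mode requires a label file")
  if (mode == "predict" && is.null(model))
    stop("pipeline stage 'classify': predict mode requires a saved model")
  structure(
    list(track = track, labels = labels, out = out, mode = mode,
         model = model, window_size = as.integer(window_size),
         min_likelihood = min_likelihood,
         n_estimators = as.integer(n_estimators), seed = as.integer(seed),
         fps = fps, tuples = tuples),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

as_tuple_list <- function(tuples) {
  lapply(tuples, function(t)
    tuple_threshold(t$fallback, t$target, as.numeric(t$threshold)))
}

#' Run the full classification pipeline
#'
#' Train mode: normalizes the track, validates and applies the labels,
#' selects stable features, windows the series, runs five-fold non-shuffled
#' cross-validation, fits the final model on all windows, applies the
#' argmax rule plus any tuple thresholds to the last fold's probabilities
#' and writes the evaluation report, model, ethogram and overlay manifest
#' into `config$out`. Predict mode: loads a saved model, windows the
#' (unlabeled) normalized track and writes predictions, ethogram and
#' overlay manifest. All outputs embed the resolved configuration and the
#' package version.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return list of in-memory results (invisible file side effects in
#'   `config$out`): in train mode `model`, `report`, `predictions`,
#'   `ethogram`; in predict mode `predictions`, `ethogram`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  track <- stage("io", read_pose_csv(config$track, fps = config$fps))
  norm <- stage("normalize", normalize_track(track))
  sel <- stage("features", select_features(track, config$min_likelihood))
  meta <- list(config = unclass(config),
               package_version = as.character(utils::packageVersion("poseclass")),
               features = sel$features, excluded_parts = sel$excluded)

  if (config$mode == "train") {
    labels <- stage("labeling", read_labels(config$labels))
    lf <- stage("labeling", apply_labels(labels, track))
    feats <- feature_matrix(norm$track, sel$parts, lf$frame_indices)
    spec <- window_spec(config$window_size, ncol(feats))
    ds <- stage("features",
                make_windows(feats, spec, lf$frame_indices, lf$labels))
    cfg <- classifier_config(n_estimators = config$n_estimators,
                             seed = config$seed)
    report <- stage("evaluate", cv5_nonshuffled(ds, cfg))
    model <- stage("classify",
                   behavior_classifier(ds, cfg, feature_names = sel$features))
    preds <- argmax_prediction(report$last_fold$probs)
    if (length(config$tuples))
      preds <- stage("postprocess",
                     apply_tuple_thresholds(preds, report$last_fold$probs,
                                            as_tuple_list(config$tuples)))
    etho <- stage("report",
                  make_ethogram(preds,
                                csv = file.path(config$out, "ethogram.csv"),
                                plot_file = file.path(config$out,
                                                      "ethogram.png")))
    overlay_manifest(preds, fps = config$fps,
                     path = file.path(config$out, "overlay.srt"))
    saveRDS(c(list(model = model), meta),
            file.path(config$out, "model.rds"))
    jsonlite::write_json(
      list(metadata = meta,
           cv_score = report$cv_score, fold_scores = report$fold_scores,
           per_class = report$per_class,
           confusion_absolute = report$confusion$absolute,
           confusion_relative = report$confusion$relative),
      file.path(config$out, "report.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    invisible(list(model = model, report = report, predictions = preds,
                   ethogram = etho))
  } else {
    stored <- stage("classify", readRDS(config$model))
    model <- stored$model
    # use the training-time feature set so the vector layout matches
    parts <- unique(sub("_[xy]$", "", model$feature_names))
    feats <- feature_matrix(norm$track, parts)
    ds <- stage("features",
                make_windows(feats, model$spec))
    pt <- stage("classify", predict_proba(model, ds))
    preds <- argmax_prediction(pt)
    if (length(config$tuples))
      preds <- stage("postprocess",
                     apply_tuple_thresholds(preds, pt,
                                            as_tuple_list(config$tuples)))
    etho <- stage("report",
                  make_ethogram(preds,
                                csv = file.path(config$out, "ethogram.csv"),
                                plot_file = file.path(config$out,
                                                      "ethogram.png")))
    overlay_manifest(preds, fps = config$fps,
                     path = file.path(config$out, "overlay.srt"))
    utils::write.csv(as.data.frame(preds),
                     file.path(config$out, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(list(predictions = preds, ethogram = etho))
  }
}
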