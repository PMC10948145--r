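# One-call pipeline: synthesize movies, build a clip library, train the
# classifier, run detection + tracking on a held-out movie, and score the
# result.

#' Run the full pipeline end to end
#'
#' Deterministic given `seed`: generates a training clip library from
#' synthetic movies, trains the Conv-Transformer, synthesizes a held-out
#' evaluation movie (a seed stream never used for training), runs detection,
#' NMS and tracking on it, and evaluates the tracked events against the
#' generator's ground truth.
#'
#' @param seed master seed; every random stage derives its own stream from
#'   it.
#' @param synth a [synth_config()] for the evaluation movie (its `seed` is
#'   overridden); training movies reuse its geometry.
#' @param model_cfg a [model_config()] (the compact preset by default).
#' @param train_cfg a [train_config()].
#' @param pipeline a [pipeline_config()].
#' @param n_per_class training clips per class.
#' @param neg_ratio training negatives per positive.
#' @return List of class `end2end_result`: `model`, `movie`, `truth`,
#'   `detections`, `tracks`, `events`, `report` (an `evaluation_report`) and
#'   `summary` (flat named list of the headline numbers).
#' @export
run_end2end <- function(seed = 1L,
                        synth = synth_config(),
                        model_cfg = model_config_compact(),
                        train_cfg = train_config(),
                        pipeline = pipeline_config(),
                        n_per_class = 200L,
                        neg_ratio = 1) {
  lib_cfg <- synth
  lib_cfg$seed <- derive_seed(seed, 1L)
  lib <- generate_clip_library(lib_cfg, n_per_class, neg_ratio)
  split <- assemble_training_set(clip_set_subset(lib, which(lib$label == 1L)),
                                 clip_set_subset(lib, which(lib$label == 0L)),
                                 ratio = neg_ratio,
                                 seed = derive_seed(seed, 2L))
  model <- build_model(model_cfg, seed = derive_seed(seed, 3L))
  tc <- train_cfg
  tc$seed <- derive_seed(seed, 4L)
  model <- train_model(model, split$train, split$val, tc)

  eval_cfg <- synth
  eval_cfg$seed <- derive_seed(seed, 5L)
  sm <- generate_movie(eval_cfg)
  detections <- detect_events(sm$movie, model, pipeline)
  tracks <- track_detections(detections, pipeline$gap,
                             pipeline$dist_threshold)
  events <- tracks_to_events(tracks)
  report <- evaluate_events(events, sm$truth, dim(sm$movie$frames),
                            seed = derive_seed(seed, 6L))
  structure(list(
    model = model, movie = sm$movie, truth = sm$truth,
    detections = detections, tracks = tracks, events = events,
    report = report,
    summary = list(
      seed = seed,
      n_truth = report$n_truth, n_events = report$n_pred,
      n_detections = nrow(detections), n_tracks = length(unique(tracks$track_id)),
      tpr = report$tpr, fpr = report$fpr,
      mean_spatial_error = report$mean_spatial_error,
      mean_abs_temporal_offset = report$temporal$mean_abs,
      pearson_r = report$pearson_r,
      val_acc = max(model$history$val_acc))),
    class = "end2end_result")
}

#' @export
print.end2end_result <- function(x, ...) {
  cat("end-to-end run (seed", x$summary$seed, ")\n")
  print(x$report)
  invisible(x)
}
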