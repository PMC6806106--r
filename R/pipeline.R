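# End-to-end train/detect/evaluate flow and model persistence.
#
# adl_train() is the fitting entry point: it learns the scene model,
# encodes/discovers activities, learns per-region codebooks, discovers
# activity classes and trains the HAM set, returning a classed adl_model.
# adl_detect() (also predict()) replays the online encode/discover/
# recognize pass on new sequences; adl_evaluate() wraps the metrics
# protocol.

#' Default pipeline configuration
#'
#' @param fps frames per second (default 25).
#' @param k_high coarse region count or `"auto"` (BIC).
#' @param multipliers mid/low region-count multipliers, default `c(2, 3)`.
#' @param k_stage1 per-subject stage-1 clusters, default 8.
#' @param codebook_size code words per region codebook (default 16; the
#'   conventional range is 16..512).
#' @param per_region_k activity classes per region or `"auto"`.
#' @param min_stay_frames jitter-suppression threshold for Stay runs.
#' @param eps recognition score floor.
#' @param seed integer seed threading all randomized stages.
#' @return named list of class `adl_config`.
#' @export
adl_config <- function(fps = 25, k_high = "auto", multipliers = c(2L, 3L),
                       k_stage1 = 8L, codebook_size = 16L,
                       per_region_k = "auto", min_stay_frames = 1L,
                       eps = EPS_FLOOR, seed = 1L) {
  structure(list(fps = fps, k_high = k_high, multipliers = multipliers,
                 k_stage1 = k_stage1, codebook_size = codebook_size,
                 per_region_k = per_region_k,
                 min_stay_frames = min_stay_frames,
                 eps = eps, seed = as.integer(seed)),
            class = "adl_config")
}

# Encode one sequence at the three levels and discover its activities.
encode_and_discover <- function(seq, scene, min_stay_frames = 1L) {
  pes <- lapply(scene$topologies, function(tp)
    encode_primitive_events(seq, tp, min_stay_frames = min_stay_frames))
  discover_activities(pes$high, pes$mid, pes$low)
}

#' Train the full activity-detection model
#'
#' Learns the three-level scene model from the training trajectories,
#' discovers activities per sequence, learns one codebook per coarse scene
#' region from the descriptors of the activities discovered there, clusters
#' activities into model classes, and fits the Hierarchical Activity
#' Models.
#'
#' @param sequences list of [trajectory_sequence()] (or a single one).
#' @param descriptors optional list (parallel to `sequences`) of
#'   descriptor-segment lists; when NULL, models are global-motion only.
#' @param config an [adl_config()].
#' @return object of class `adl_model`: `scene` ([learn_scene_model()]
#'   result), `codebooks` (named by region id), `models` (HAM list),
#'   `config`, `training` (class counts).
#' @export
adl_train <- function(sequences, descriptors = NULL, config = adl_config()) {
  if (inherits(sequences, "trajectory_sequence")) sequences <- list(sequences)
  if (!is.null(descriptors) && length(descriptors) != length(sequences)) {
    stopf("descriptors must have one entry (possibly empty) per sequence")
  }
  scene <- learn_scene_model(sequences, k_high = config$k_high,
                             multipliers = config$multipliers,
                             seed = config$seed,
                             k_stage1 = config$k_stage1)
  das <- list()
  for (i in seq_along(sequences)) {
    d <- encode_and_discover(sequences[[i]], scene, config$min_stay_frames)
    if (!is.null(descriptors)) d <- attach_descriptors(d, descriptors[[i]])
    das <- c(das, d)
  }
  if (!length(das)) stopf("no activities discovered from the training set")
  # one codebook per coarse region, from the stay DAs discovered there
  codebooks <- list()
  if (!is.null(descriptors)) {
    for (P in unique(vapply(das, function(d) d$from, integer(1)))) {
      rows <- do.call(rbind, lapply(das, function(d) {
        if (d$type == "stay" && d$from == P) d$descriptors else NULL
      }))
      if (!is.null(rows) && nrow(rows) >= 2L) {
        size <- min(config$codebook_size, nrow(rows))
        codebooks[[as.character(P)]] <-
          learn_codebook(rows, size, seed = config$seed + P, region_id = P)
      }
    }
  }
  classes <- discover_model_classes(das, codebooks,
                                    per_region_k = config$per_region_k,
                                    seed = config$seed)
  models <- train_models(das, classes, codebooks, fps = config$fps)
  structure(list(scene = scene, codebooks = codebooks, models = models,
                 config = config,
                 training = list(n_sequences = length(sequences),
                                 n_das = length(das),
                                 class_counts = table(classes$class_id))),
            class = "adl_model")
}

#' @export
print.adl_model <- function(x, ...) {
  ks <- vapply(x$scene$topologies, function(t) t$k, integer(1))
  cat(sprintf("<adl_model> scene k = %s; %d codebook(s); %d activity model(s)\n",
              paste(ks, collapse = "/"), length(x$codebooks),
              length(x$models)))
  invisible(x)
}

#' @export
summary.adl_model <- function(object, ...) {
  print(object)
  cat("activity models:\n")
  for (m in object$models) {
    cat(sprintf("  %-28s prior %.3f  instances %d  nodes %d\n",
                m$model_id, m$prior, m$n_instances, length(m$nodes)))
  }
  invisible(object)
}

#' Detect and recognize activities in new sequences
#'
#' Online pass over each sequence: encode primitive events with the trained
#' topologies, discover activities, attach descriptors, and recognize each
#' closed activity with the recursive MAP score.
#'
#' @param model an [adl_train()] result.
#' @param sequences list of [trajectory_sequence()] (or one).
#' @param descriptors optional parallel list of descriptor-segment lists.
#' @return list per sequence: `track` ([annotation_track()] of recognized
#'   model ids with log scores), `results` (list of `recognition_result`).
#' @export
adl_detect <- function(model, sequences, descriptors = NULL) {
  stopifnot(inherits(model, "adl_model"))
  if (inherits(sequences, "trajectory_sequence")) sequences <- list(sequences)
  if (!is.null(descriptors) && length(descriptors) != length(sequences)) {
    stopf("descriptors must have one entry per sequence")
  }
  lapply(seq_along(sequences), function(i) {
    das <- encode_and_discover(sequences[[i]], model$scene,
                               model$config$min_stay_frames)
    if (!is.null(descriptors)) das <- attach_descriptors(das, descriptors[[i]])
    res <- lapply(das, recognize, models = model$models,
                  codebooks = model$codebooks, eps = model$config$eps)
    labels <- vapply(res, function(r) r$winner, character(1))
    scores <- vapply(res, function(r)
      if (is.null(r$ranked)) NA_real_ else r$ranked$log_score[1L], numeric(1))
    list(track = das_to_track(das, labels = labels, scores = scores),
         results = res)
  })
}

#' @export
predict.adl_model <- function(object, newdata, descriptors = NULL, ...) {
  adl_detect(object, newdata, descriptors = descriptors)
}

#' Evaluate predictions against ground truth
#'
#' Convenience wrapper around [evaluate_tracks()] accepting lists of tracks
#' (concatenated with per-sequence frame offsets so sequences do not
#' overlap in time).
#'
#' @param pred,gt single tracks or parallel lists of tracks.
#' @param ... passed to [evaluate_tracks()].
#' @return a `metrics_report`.
#' @export
adl_evaluate <- function(pred, gt, ...) {
  if (inherits(pred, "annotation_track")) pred <- list(pred)
  if (inherits(gt, "annotation_track")) gt <- list(gt)
  if (length(pred) != length(gt)) stopf("pred and gt lists differ in length")
  offset <- 0L
  pl <- list(); gl <- list()
  for (i in seq_along(pred)) {
    p <- as.data.frame(pred[[i]]); g <- as.data.frame(gt[[i]])
    hi <- max(c(p$end_frame, g$end_frame, -1L))
    p$start_frame <- p$start_frame + offset; p$end_frame <- p$end_frame + offset
    g$start_frame <- g$start_frame + offset; g$end_frame <- g$end_frame + offset
    pl[[i]] <- p; gl[[i]] <- g
    offset <- offset + hi + 2L
  }
  bind <- function(lst) {
    df <- do.call(rbind, lst)
    annotation_track(df$label, df$start_frame, df$end_frame,
                     score = if ("score" %in% names(df)) df$score,
                     overlap_tolerance = 1L)
  }
  evaluate_tracks(bind(pl), bind(gl), ...)
}

# ---- persistence ----------------------------------------------------------

#' Serialize a trained model to JSON
#'
#' Deterministic (byte-identical for identical models): full numeric
#' precision, fixed key order.
#'
#' @param model an `adl_model`.
#' @param path output path.
#' @export
write_adl_model <- function(model, path) {
  topo_js <- lapply(model$scene$topologies, function(tp)
    list(level = tp$level, k = tp$k, coords = tp$coords,
         regions = tp$regions))
  cb_js <- lapply(model$codebooks, function(cb)
    list(region_id = cb$region_id, size = cb$size,
         words = apply(cb$words, 1L, as.numeric, simplify = FALSE),
         norm_hist = cb$norm_hist))
  mdl_js <- lapply(model$models, function(m)
    list(model_id = m$model_id, root_key = m$root_key,
         root_type = m$root_type, prior = m$prior, region = m$region,
         codebook_ref = m$codebook_ref, class_hist = m$class_hist,
         n_instances = m$n_instances, degenerate = m$degenerate,
         nodes = lapply(m$nodes, function(nd)
           list(level = nd$level, type_key = nd$type_key,
                parent = nd$parent, children = I(nd$children),
                mu_d = nd$mu_d, sigma2_d = nd$sigma2_d,
                n_members = nd$n_members,
                mixture = nd$mixture, timelapse = nd$timelapse))))
  doc <- list(schema = "adlrec-model-v1",
              config = unclass(model$config),
              scene = list(fps = model$scene$fps, meta = model$scene$meta,
                           topologies = topo_js),
              codebooks = cb_js,
              models = mdl_js,
              training = list(n_sequences = model$training$n_sequences,
                              n_das = model$training$n_das))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Load a trained model from JSON
#'
#' @param path path written by [write_adl_model()].
#' @return an `adl_model`.
#' @export
read_adl_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$schema, "adlrec-model-v1")) {
    stopf("unsupported model schema '%s'", doc$schema)
  }
  topologies <- lapply(doc$scene$topologies, function(tp)
    structure(list(level = tp$level, k = as.integer(tp$k),
                   regions = as.data.frame(tp$regions),
                   coords = tp$coords),
              class = "topology"))
  scene <- structure(list(topologies = topologies, fps = doc$scene$fps,
                          meta = doc$scene$meta),
                     class = "scene_model")
  codebooks <- lapply(doc$codebooks, function(cb)
    structure(list(region_id = cb$region_id, size = as.integer(cb$size),
                   words = do.call(rbind, lapply(cb$words, unlist)),
                   norm_hist = as.numeric(cb$norm_hist)),
              class = "codebook"))
  models <- lapply(doc$models, function(m) {
    nodes <- lapply(m$nodes, function(nd)
      list(level = as.integer(nd$level), type_key = nd$type_key,
           parent = if (is.null(nd$parent)) NA_character_ else nd$parent,
           children = as.character(unlist(nd$children)),
           mu_d = nd$mu_d, sigma2_d = nd$sigma2_d,
           n_members = nd$n_members,
           mixture = nd$mixture, timelapse = nd$timelapse))
    structure(list(model_id = m$model_id, root_key = m$root_key,
                   root_type = m$root_type, nodes = nodes,
                   prior = m$prior, region = m$region,
                   codebook_ref = m$codebook_ref,
                   class_hist = if (length(m$class_hist))
                                  as.numeric(m$class_hist) else NULL,
                   n_instances = m$n_instances,
                   degenerate = isTRUE(m$degenerate)),
              class = "ham_model")
  })
  cfg <- doc$config
  config <- adl_config(fps = cfg$fps, k_high = cfg$k_high,
                       multipliers = as.integer(unlist(cfg$multipliers)),
                       k_stage1 = as.integer(cfg$k_stage1),
                       codebook_size = as.integer(cfg$codebook_size),
                       per_region_k = cfg$per_region_k,
                       min_stay_frames = as.integer(cfg$min_stay_frames),
                       eps = cfg$eps, seed = as.integer(cfg$seed))
  structure(list(scene = scene, codebooks = codebooks, models = models,
                 config = config,
                 training = doc$training),
            class = "adl_model")
}
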