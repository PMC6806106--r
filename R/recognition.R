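# Recursive MAP recognition: score a test discovered activity against the
# trained HAM models and return the maximum-a-posteriori model.
#
# Per node the likelihood factors into (i) a type indicator, (ii) a bounded
# duration term exp(-|dur - mu_d| / sigma_d), and (iii) at the root only, a
# descriptor-distance indicator that is 1 for the model whose class
# histogram is nearest (Bhattacharyya-based) to the test histogram.  The
# tree score is the log-space sum over matched nodes plus the log model
# prior; mismatched types pay a small floor instead of a hard zero so that
# partially matching models remain comparable.

EPS_FLOOR <- 1e-6

#' Build a single-instance HAM from a test activity
#'
#' Same construction as training, applied to one discovered activity:
#' durations are exact, variances floored.
#'
#' @param da a `discovered_activity`.
#' @param fps frames per second.
#' @return attributed node list as from [fit_attributes()].
#' @export
build_test_ham <- function(da, fps = da$fps) {
  fit_attributes(cluster_nodes(list(build_neighborhood(da))), fps)
}

#' Likelihood factors for one node pair
#'
#' @param model_node,test_node attributed HAM nodes of the same level.
#' @param is_root TRUE for the level-1 node.
#' @param distance_winner logical: is this model the minimum-distance model
#'   for the test segment (root only)? `NA` neutralizes the factor
#'   (descriptor-less segment).
#' @param eps score floor replacing hard zeros.
#' @return list of class `node_score`: `type_match` (0/1), `duration_term`
#'   in (0, 1\], `distance_term` (0/1, root only; 1 elsewhere), `log_score`.
#' @export
node_likelihood <- function(model_node, test_node, is_root = FALSE,
                            distance_winner = NA, eps = EPS_FLOOR) {
  type_match <- as.numeric(identical(model_node$type_key, test_node$type_key))
  sigma_d <- sqrt(model_node$sigma2_d)
  duration_term <- exp(-abs(test_node$mu_d - model_node$mu_d) / sigma_d)
  distance_term <- if (is_root && !is.na(distance_winner)) {
    as.numeric(distance_winner)
  } else 1
  score <- max(type_match * duration_term * distance_term, eps)
  structure(list(type_match = type_match, duration_term = duration_term,
                 distance_term = distance_term, log_score = log(score)),
            class = "node_score")
}

#' Recursive log score of a test HAM against a model
#'
#' Descends the levels of the test tree; each test node is paired with the
#' model node of the same (level, type key). Matched pairs contribute the
#' log node likelihood; unmatched test nodes contribute `log(eps)`;
#' unmatched model nodes are ignored. The total adds the log model prior
#' (MAP). The caller is expected to have filtered models by root type.
#'
#' @param model a `ham_model`.
#' @param test an attributed node list from [build_test_ham()].
#' @param distance_winner passed to [node_likelihood()] at the root.
#' @param eps score floor.
#' @return list with `total` (log prior + log likelihood) and `trace`
#'   (named list of `node_score` per test-node key).
#' @export
recursive_score <- function(model, test, distance_winner = NA,
                            eps = EPS_FLOOR) {
  trace <- list()
  total <- log(model$prior)
  keys <- names(test)
  keys <- keys[order(vapply(test, function(n) n$level, integer(1)), keys)]
  for (key in keys) {
    tn <- test[[key]]
    mn <- model$nodes[[key]]
    if (is.null(mn)) {
      trace[[key]] <- structure(list(type_match = 0, duration_term = NA_real_,
                                     distance_term = 1, log_score = log(eps)),
                                class = "node_score")
      total <- total + log(eps)
    } else {
      ns <- node_likelihood(mn, tn, is_root = tn$level == 1L,
                            distance_winner = distance_winner, eps = eps)
      trace[[key]] <- ns
      total <- total + ns$log_score
    }
  }
  list(total = total, trace = trace)
}

#' Recognize a discovered activity
#'
#' Builds the test HAM, filters the models to those sharing the root type
#' (hard filter), computes the descriptor-distance ranking once (the model
#' whose class histogram is Bhattacharyya-nearest to the test histogram is
#' the distance winner; descriptor-less activities neutralize the factor),
#' and returns the MAP model.
#'
#' @param da a `discovered_activity`.
#' @param models list of `ham_model` (e.g. from [train_models()]).
#' @param codebooks named list of per-region codebooks.
#' @param fps frames per second (defaults to the DA's).
#' @param eps score floor.
#' @return object of class `recognition_result`: `winner` (model id, or
#'   `"unknown"` when no model passes the root-type filter), `ranked`
#'   (data frame model_id/log_score/prior), `distance` (named distances or
#'   NULL), `trace` (per-model node traces).
#' @export
recognize <- function(da, models, codebooks, fps = da$fps, eps = EPS_FLOOR) {
  if (!length(models)) stopf("need at least one model")
  test <- build_test_ham(da, fps)
  root_type <- da$type_key
  cand <- models[vapply(models, function(m) identical(m$root_type, root_type),
                        logical(1))]
  if (!length(cand)) {
    return(structure(list(winner = "unknown", ranked = NULL, distance = NULL,
                          trace = NULL),
                     class = "recognition_result"))
  }
  # one distance ranking per test DA over the candidates' class histograms
  dists <- rep(NA_real_, length(cand))
  names(dists) <- vapply(cand, function(m) m$model_id, character(1))
  winner_flags <- rep(NA, length(cand))
  if (!is.null(da$descriptors)) {
    for (i in seq_along(cand)) {
      m <- cand[[i]]
      cb <- codebooks[[as.character(m$codebook_ref)]]
      if (!is.null(cb) && length(m$class_hist) == cb$size) {
        h <- encode_histogram(da$descriptors, cb)
        dists[i] <- codebook_distance(h, m$class_hist)
      }
    }
    if (any(!is.na(dists))) {
      best <- order(dists, names(dists))[1L]
      winner_flags <- seq_along(cand) == best
      winner_flags[is.na(dists)] <- NA   # models without histograms: neutral
    }
  }
  scored <- lapply(seq_along(cand), function(i)
    recursive_score(cand[[i]], test, distance_winner = winner_flags[i],
                    eps = eps))
  ranked <- data.frame(model_id = names(dists),
                       log_score = vapply(scored, function(s) s$total,
                                          numeric(1)),
                       prior = vapply(cand, function(m) m$prior, numeric(1)),
                       stringsAsFactors = FALSE)
  ord <- order(-ranked$log_score, -ranked$prior, ranked$model_id)
  ranked <- ranked[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  traces <- lapply(scored, function(s) s$trace)[ord]
  names(traces) <- ranked$model_id
  structure(list(winner = ranked$model_id[1L], ranked = ranked,
                 distance = if (any(!is.na(dists))) dists else NULL,
                 trace = traces),
            class = "recognition_result")
}

#' @export
print.recognition_result <- function(x, ...) {
  if (identical(x$winner, "unknown")) {
    cat("<recognition_result> unknown (no model shares the root type)\n")
  } else {
    cat(sprintf("<recognition_result> winner '%s' (log score %.3f of %d candidates)\n",
                x$winner, x$ranked$log_score[1L], nrow(x$ranked)))
  }
  invisible(x)
}
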