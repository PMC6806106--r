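# Evaluation protocol for unsupervised output: correspondence-matrix label
# mapping, interval-overlap detection metrics, and frame-wise FA1 /
# F-score / IoU.
#
# Recognized activities carry internal labels ("Activity 2 in Zone 1");
# they are mapped one-to-one onto ground-truth labels by maximizing total
# frame co-occurrence before any metric is computed.

# Expand a track into a per-frame label vector over [range[1], range[2]].
# Boundary frames shared by adjacent intervals belong to the earlier one
# (entries are start-sorted; first writer wins).
expand_track <- function(track, range) {
  n <- range[2L] - range[1L] + 1L
  lab <- rep(NA_character_, n)
  for (i in seq_len(nrow(track))) {
    a <- max(track$start_frame[i], range[1L]) - range[1L] + 1L
    b <- min(track$end_frame[i], range[2L]) - range[1L] + 1L
    if (a > b) next
    sel <- a:b
    sel <- sel[is.na(lab[sel])]
    lab[sel] <- track$label[i]
  }
  lab
}

track_range <- function(...) {
  tracks <- list(...)
  tracks <- tracks[vapply(tracks, nrow, integer(1)) > 0L]
  if (!length(tracks)) return(NULL)
  c(min(vapply(tracks, function(t) min(t$start_frame), integer(1))),
    max(vapply(tracks, function(t) max(t$end_frame), integer(1))))
}

#' Frame co-occurrence (correspondence) matrix
#'
#' `counts[i, j]` is the number of frames carrying recognized label i in
#' `pred` and ground-truth label j in `gt`; frames unlabeled on either side
#' are excluded.
#'
#' @param pred,gt [annotation_track()]s over a common frame range.
#' @return integer matrix of class `correspondence_matrix` with recognized
#'   labels as rows and ground-truth labels as columns.
#' @export
correspondence_matrix <- function(pred, gt) {
  rng <- track_range(pred, gt)
  if (is.null(rng)) {
    warnf("empty tracks; empty correspondence matrix")
    m <- matrix(0L, 0L, 0L)
    class(m) <- c("correspondence_matrix", class(m))
    return(m)
  }
  pl <- expand_track(pred, rng)
  gl <- expand_track(gt, rng)
  keep <- !is.na(pl) & !is.na(gl)
  ra <- sort(unique(pred$label))
  gtl <- sort(unique(gt$label))
  m <- matrix(0L, length(ra), length(gtl), dimnames = list(ra, gtl))
  if (any(keep)) {
    tab <- table(factor(pl[keep], levels = ra), factor(gl[keep], levels = gtl))
    m[] <- as.integer(tab)
  }
  class(m) <- c("correspondence_matrix", class(m))
  m
}

#' Map recognized labels onto ground-truth labels
#'
#' Maximum-total-co-occurrence one-to-one assignment (weighted bipartite
#' matching on the correspondence counts). Recognized labels left
#' unassigned map to `"none"`.
#'
#' @param cor a [correspondence_matrix()].
#' @return named character vector: `mapping[ra_label] = gt_label` or
#'   `"none"`.
#' @export
map_labels <- function(cor) {
  nr <- nrow(cor); nc <- ncol(cor)
  if (!nr || !nc) stopf("empty correspondence matrix")
  mapping <- rep("none", nr)
  names(mapping) <- rownames(cor)
  g <- igraph::make_empty_graph(n = nr + nc, directed = FALSE)
  igraph::V(g)$type <- rep(c(FALSE, TRUE), c(nr, nc))
  edges <- integer(0); w <- numeric(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (cor[i, j] > 0) {
      edges <- c(edges, i, nr + j)
      w <- c(w, cor[i, j])
    }
  }
  if (!length(edges)) return(mapping)
  g <- igraph::add_edges(g, edges)
  match <- igraph::max_bipartite_match(g, weights = w)$matching
  for (i in seq_len(nr)) {
    if (!is.na(match[i])) mapping[i] <- colnames(cor)[match[i] - nr]
  }
  mapping
}

apply_mapping <- function(track, mapping) {
  lab <- unname(mapping[track$label])
  lab[is.na(lab)] <- "none"
  track$label <- lab
  track
}

#' Interval-level detection metrics
#'
#' A ground-truth interval counts as a true positive when a prediction with
#' its (mapped) label overlaps strictly more than `overlap_frac` of the
#' ground-truth interval's frames. Each prediction validates at most one
#' ground-truth interval (greedy assignment by descending overlap);
#' leftover predictions are false positives, leftover ground truth false
#' negatives.
#'
#' @param pred,gt [annotation_track()]s.
#' @param mapping named vector from [map_labels()] (identity when omitted).
#' @param overlap_frac required overlap fraction of the ground-truth
#'   interval, default 0.8 (strictly exceeded).
#' @return data frame per class: `label`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f` (classes with P + R = 0 score F = 0).
#' @export
detection_metrics <- function(pred, gt, mapping = NULL, overlap_frac = 0.8) {
  if (!is.numeric(overlap_frac) || overlap_frac <= 0 || overlap_frac > 1) {
    stopf("overlap_frac must lie in (0, 1]")
  }
  if (!is.null(mapping)) pred <- apply_mapping(pred, mapping)
  classes <- sort(unique(gt$label))
  out <- lapply(classes, function(cl) {
    gi <- which(gt$label == cl)
    pi <- which(pred$label == cl)
    # candidate (pred, gt) pairs exceeding the overlap threshold
    cand <- NULL
    for (p in pi) for (g in gi) {
      ov <- min(pred$end_frame[p], gt$end_frame[g]) -
        max(pred$start_frame[p], gt$start_frame[g]) + 1L
      glen <- gt$end_frame[g] - gt$start_frame[g] + 1L
      if (ov > overlap_frac * glen) {
        cand <- rbind(cand, c(p = p, g = g, ov = ov))
      }
    }
    tp <- 0L
    used_p <- integer(0); used_g <- integer(0)
    if (!is.null(cand)) {
      cand <- cand[order(-cand[, "ov"], cand[, "g"], cand[, "p"]), ,
                   drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        p <- cand[r, "p"]; g <- cand[r, "g"]
        if (p %in% used_p || g %in% used_g) next
        used_p <- c(used_p, p); used_g <- c(used_g, g)
        tp <- tp + 1L
      }
    }
    fn <- length(gi) - tp
    fp <- length(pi) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(label = cl, tp = tp, fp = fp, fn = fn,
               precision = prec, recall = rec, f = f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Frame-wise metrics: FA1, mean F-score, mean IoU
#'
#' Per class c over the evaluated frames: TP/FP/FN frame counts, precision,
#' recall, `F_c = 2 P_c R_c / (P_c + R_c)`, `IoU_c = TP / (TP + FP + FN)`.
#' FA1 is the fraction of evaluated frames whose mapped prediction equals
#' the ground truth; the mean F-score and mean IoU average over the classes
#' present on either side. A neutral/background class can be excluded from
#' the class averages while still counting in FA1's denominator.
#'
#' @param pred,gt [annotation_track()]s.
#' @param mapping named vector from [map_labels()] (identity when omitted).
#' @param neutral_label label treated as background (default `"Neutral"`).
#' @param include_neutral count neutral ground-truth frames in FA1's
#'   denominator (default TRUE); neutral is always excluded from the
#'   per-class averages.
#' @return list with `fa1`, `mean_f`, `mean_iou`, `per_class` data frame,
#'   `n_frames` evaluated.
#' @export
frame_metrics <- function(pred, gt, mapping = NULL,
                          neutral_label = "Neutral",
                          include_neutral = TRUE) {
  if (!is.null(mapping)) pred <- apply_mapping(pred, mapping)
  rng <- track_range(pred, gt)
  if (is.null(rng)) stopf("both tracks are empty")
  pl <- expand_track(pred, rng)
  gl <- expand_track(gt, rng)
  eval_mask <- !is.na(gl)
  if (!include_neutral) eval_mask <- eval_mask & gl != neutral_label
  n_eval <- sum(eval_mask)
  fa1 <- if (n_eval) {
    sum(!is.na(pl[eval_mask]) & pl[eval_mask] == gl[eval_mask]) / n_eval
  } else NA_real_
  classes <- sort(setdiff(union(unique(gl[eval_mask]),
                                unique(pl[eval_mask & !is.na(pl)])),
                          c(NA, "none", neutral_label)))
  per_class <- lapply(classes, function(cl) {
    p_is <- !is.na(pl[eval_mask]) & pl[eval_mask] == cl
    g_is <- gl[eval_mask] == cl
    tp <- sum(p_is & g_is)
    fp <- sum(p_is & !g_is)
    fn <- sum(!p_is & g_is)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    iou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0
    data.frame(label = cl, tp = tp, fp = fp, fn = fn, precision = prec,
               recall = rec, f = f, iou = iou, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, per_class)
  list(fa1 = fa1,
       mean_f = if (length(classes)) mean(per_class$f) else NA_real_,
       mean_iou = if (length(classes)) mean(per_class$iou) else NA_real_,
       per_class = per_class,
       n_frames = n_eval)
}

#' Full evaluation of a prediction track against ground truth
#'
#' Runs the complete protocol: correspondence matrix, one-to-one label
#' mapping, interval-level detection metrics at `overlap_frac`, and
#' frame-wise metrics.
#'
#' @inheritParams detection_metrics
#' @inheritParams frame_metrics
#' @return object of class `metrics_report`: `mapping`, `correspondence`,
#'   `detection` (per-class data frame + macro averages), `frames`
#'   (frame-wise list), `overlap_frac`.
#' @export
evaluate_tracks <- function(pred, gt, overlap_frac = 0.8,
                            neutral_label = "Neutral",
                            include_neutral = TRUE) {
  cor <- correspondence_matrix(pred, gt)
  mapping <- map_labels(cor)
  det <- detection_metrics(pred, gt, mapping, overlap_frac = overlap_frac)
  det_cls <- det[det$label != neutral_label, , drop = FALSE]
  fr <- frame_metrics(pred, gt, mapping, neutral_label = neutral_label,
                      include_neutral = include_neutral)
  structure(list(mapping = mapping,
                 correspondence = cor,
                 detection = det,
                 detection_macro = list(
                   precision = mean(det_cls$precision),
                   recall = mean(det_cls$recall),
                   f = mean(det_cls$f)),
                 frames = fr,
                 overlap_frac = overlap_frac),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report>\n")
  cat("label mapping:\n")
  for (ra in names(x$mapping)) {
    cat(sprintf("  %-28s -> %s\n", ra, x$mapping[[ra]]))
  }
  cat(sprintf("detection (> %.0f%% overlap): macro P %.3f, R %.3f, F %.3f\n",
              100 * x$overlap_frac, x$detection_macro$precision,
              x$detection_macro$recall, x$detection_macro$f))
  cat(sprintf("frame-wise: FA1 %.3f, mean F %.3f, mean IoU %.3f (%d frames)\n",
              x$frames$fa1, x$frames$mean_f, x$frames$mean_iou,
              x$frames$n_frames))
  invisible(x)
}
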