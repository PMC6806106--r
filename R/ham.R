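# Hierarchical Activity Models (HAM): attribute-bearing trees built from
# unlabeled discovered activities and their primitive-event neighborhoods.
#
# Level 1 is the discovered activity itself (root), level 2 its mid-level
# primitive events, level 3 the low-level ones.  Nodes group events of the
# same type key within a level; each node carries a Gaussian duration
# attribute plus mixture (type-composition fractions) and timelapse
# (child-duration) Gaussians over its child types.

#' Hierarchical neighborhood of a discovered activity
#'
#' Recursive representation linking a DA to its finer-resolution primitive
#' events: every mid-level PE overlapping the DA, and under each of them the
#' low-level PEs overlapping that mid-level PE.
#'
#' @param da a `discovered_activity` (see [discover_activities()]).
#' @return nested list: `type_key`, `start_frame`, `end_frame`,
#'   `duration_s`, `level`, and `children` (same structure, one per mid PE;
#'   each mid entry's `children` hold the overlapping low PEs).
#' @export
build_neighborhood <- function(da) {
  stopifnot(inherits(da, "discovered_activity"))
  low <- da$children$low
  mid <- da$children$mid
  mids <- lapply(seq_len(nrow(mid)), function(i) {
    sel <- intervals_overlap(mid$start_frame[i], mid$end_frame[i],
                             low$start_frame, low$end_frame)
    lows <- lapply(which(sel), function(j) {
      list(type_key = type_key(low$type[j], low$from[j], low$to[j]),
           start_frame = low$start_frame[j], end_frame = low$end_frame[j],
           duration_s = low$duration_s[j], level = 3L, children = list())
    })
    list(type_key = type_key(mid$type[i], mid$from[i], mid$to[i]),
         start_frame = mid$start_frame[i], end_frame = mid$end_frame[i],
         duration_s = mid$duration_s[i], level = 2L, children = lows)
  })
  list(type_key = da$type_key, start_frame = da$start_frame,
       end_frame = da$end_frame, duration_s = da$duration_s,
       level = 1L, children = mids)
}

node_key <- function(level, type_key) sprintf("L%d:%s", level, type_key)

#' Cluster neighborhood instances into a HAM tree skeleton
#'
#' Groups primitive events by type key at each level, one node per
#' (level, type) observed across the training instances, and links nodes
#' from the neighborhoods: a low-level type attaches to the mid-level type
#' it overlaps the most (total overlapping frames across instances; ties to
#' the lexicographically smallest key).
#'
#' @param neighborhoods list of [build_neighborhood()] structures, one per
#'   training instance of the model class (all sharing the root type key).
#' @return list of nodes keyed `"L<level>:<type>"`: each node has `level`,
#'   `type_key`, `parent` (key or NA), `children` (keys), and `instances`
#'   (per training instance, a data frame of member spans
#'   `start_frame`/`end_frame`/`duration_s`).
#' @export
cluster_nodes <- function(neighborhoods) {
  if (!length(neighborhoods)) stopf("need at least one instance")
  root_types <- unique(vapply(neighborhoods, function(nb) nb$type_key,
                              character(1)))
  if (length(root_types) > 1L) {
    stopf("instances have mixed root types: %s",
          paste(root_types, collapse = ", "))
  }
  nodes <- list()
  ensure <- function(nodes, level, tk, parent) {
    key <- node_key(level, tk)
    if (is.null(nodes[[key]])) {
      nodes[[key]] <- list(level = level, type_key = tk, parent = parent,
                           children = character(0),
                           instances = vector("list", length(neighborhoods)))
    }
    nodes
  }
  add_member <- function(nodes, key, inst, sf, ef, dur) {
    row <- data.frame(start_frame = sf, end_frame = ef, duration_s = dur)
    cur <- nodes[[key]]$instances[[inst]]
    nodes[[key]]$instances[[inst]] <- if (is.null(cur)) row else rbind(cur, row)
    nodes
  }
  root_key <- node_key(1L, root_types)
  nodes <- ensure(nodes, 1L, root_types, NA_character_)
  # (mid type, low type) -> total overlapping frames, for parent election
  covote <- new.env(parent = emptyenv())
  for (inst in seq_along(neighborhoods)) {
    nb <- neighborhoods[[inst]]
    nodes <- add_member(nodes, root_key, inst, nb$start_frame, nb$end_frame,
                        nb$duration_s)
    for (mid in nb$children) {
      mkey <- node_key(2L, mid$type_key)
      nodes <- ensure(nodes, 2L, mid$type_key, root_key)
      nodes <- add_member(nodes, mkey, inst, mid$start_frame, mid$end_frame,
                          mid$duration_s)
      for (low in mid$children) {
        nodes <- ensure(nodes, 3L, low$type_key, NA_character_)
        nodes <- add_member(nodes, node_key(3L, low$type_key), inst,
                            low$start_frame, low$end_frame, low$duration_s)
        ov <- min(mid$end_frame, low$end_frame) -
          max(mid$start_frame, low$start_frame)
        vkey <- paste(mid$type_key, low$type_key, sep = "\r")
        covote[[vkey]] <- (if (is.null(covote[[vkey]])) 0 else covote[[vkey]]) +
          max(ov, 0L) + 1L   # +1 so zero-length overlaps still vote
      }
    }
  }
  # elect one parent per low-level type: most overlapped mid type
  low_keys <- names(nodes)[vapply(nodes, function(n) n$level == 3L, logical(1))]
  for (lk in low_keys) {
    ltype <- nodes[[lk]]$type_key
    votes <- ls(covote)
    votes <- votes[vapply(strsplit(votes, "\r", fixed = TRUE),
                          function(p) p[2L] == ltype, logical(1))]
    mids <- vapply(strsplit(votes, "\r", fixed = TRUE), `[`, character(1), 1L)
    wts <- vapply(votes, function(v) covote[[v]], numeric(1))
    best <- mids[order(-wts, mids)][1L]
    nodes[[lk]]$parent <- node_key(2L, best)
  }
  for (key in names(nodes)) {
    p <- nodes[[key]]$parent
    if (!is.na(p)) nodes[[p]]$children <- sort(union(nodes[[p]]$children, key))
  }
  nodes
}

#' Fit Gaussian attributes on a HAM tree skeleton
#'
#' Per node: `mu_d` is the mean member duration in seconds (frame length
#' over fps) and `sigma2_d` the population variance (expectation form),
#' floored at `(1 frame / fps)^2`. Per child type: a mixture Gaussian over
#' the per-instance fraction of the node's frame span covered by children
#' of that type, and a timelapse Gaussian over the child durations.
#'
#' @param nodes a [cluster_nodes()] skeleton.
#' @param fps frames per second.
#' @return the node list with `mu_d`, `sigma2_d`, `n_members`, `mixture`
#'   and `timelapse` fields added per node.
#' @export
fit_attributes <- function(nodes, fps) {
  sigma2_min <- (1 / fps)^2
  gauss <- function(v) {
    list(mu = mean(v), sigma2 = max(pop_var(v), sigma2_min))
  }
  for (key in names(nodes)) {
    nd <- nodes[[key]]
    members <- do.call(rbind, nd$instances[!vapply(nd$instances, is.null,
                                                   logical(1))])
    g <- gauss(members$duration_s)
    nd$mu_d <- g$mu
    nd$sigma2_d <- g$sigma2
    nd$n_members <- nrow(members)
    nd$mixture <- list()
    nd$timelapse <- list()
    for (ck in nd$children) {
      child <- nodes[[ck]]
      fracs <- vapply(seq_along(nd$instances), function(i) {
        own <- nd$instances[[i]]
        sub <- child$instances[[i]]
        if (is.null(own)) return(NA_real_)
        span <- sum(own$end_frame - own$start_frame)
        if (span <= 0 || is.null(sub)) return(0)
        sum(sub$end_frame - sub$start_frame) / span
      }, numeric(1))
      fracs <- fracs[!is.na(fracs)]
      durs <- do.call(rbind, child$instances[!vapply(child$instances, is.null,
                                                     logical(1))])$duration_s
      nd$mixture[[child$type_key]] <- gauss(fracs)
      nd$timelapse[[child$type_key]] <- gauss(durs)
    }
    nodes[[key]] <- nd
  }
  nodes
}

#' Select a cluster count by average silhouette width
#'
#' Sweeps `2..k_max`, clusters with seeded k-means, and returns the k with
#' the highest average silhouette width, provided the structure is strong
#' (mean silhouette at least `threshold`) and every cluster has at least
#' two members (a class needs two instances to carry a variance); otherwise
#' returns 1. Suited to the few-samples regime of per-region activity
#' sub-clustering, where likelihood-based criteria overfit.
#'
#' @param x numeric matrix of points (rows).
#' @param k_max largest k considered, default 3.
#' @param seed integer seed.
#' @param threshold minimum average silhouette width accepted for k > 1,
#'   default 0.5 (the conventional "reasonable structure" level).
#' @return list with `k`, `silhouette` (best width, NA when k = 1 was
#'   forced), and `trace` (data frame k / silhouette / min cluster size).
#' @export
select_k_silhouette <- function(x, k_max = 3L, seed = 1L, threshold = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L || nrow(unique(x)) < 2L) {
    return(list(k = 1L, silhouette = NA_real_, trace = NULL))
  }
  D <- as.matrix(stats::dist(x))
  rows <- list()
  best_k <- 1L; best_s <- -Inf
  for (k in 2:min(k_max, n - 1L, nrow(unique(x)))) {
    km <- seeded_kmeans(x, k, seed)
    cl <- km$cluster
    min_size <- min(tabulate(cl, k))
    ms <- NA_real_
    if (min_size >= 2L) {
      s <- vapply(seq_len(n), function(i) {
        a <- mean(D[i, cl == cl[i] & seq_len(n) != i])
        b <- min(vapply(setdiff(seq_len(k), cl[i]), function(cc)
          mean(D[i, cl == cc]), numeric(1)))
        (b - a) / max(a, b)
      }, numeric(1))
      ms <- mean(s)
      if (ms > best_s) { best_s <- ms; best_k <- k }
    }
    rows[[length(rows) + 1L]] <- data.frame(k = k, silhouette = ms,
                                            min_size = min_size)
  }
  if (best_s < threshold) best_k <- 1L
  list(k = best_k,
       silhouette = if (is.finite(best_s)) best_s else NA_real_,
       trace = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Discover activity-model classes among discovered activities
#'
#' Stay DAs within one scene region are sub-clustered by their encoded
#' descriptor histograms, realizing the separation of different actions
#' performed inside the same region. Clustering happens in the Hellinger
#' embedding (square-root frequencies, where Euclidean distance is
#' proportional to the Hellinger distance used for codebook matching) with
#' k-means; in auto mode the class count is chosen by average silhouette
#' width ([select_k_silhouette()]). Descriptor-less regions fall back to
#' one class per region (global motion only). Every Change DA joins the
#' class of its directed region pair.
#'
#' @param das list of `discovered_activity` (descriptors attached where
#'   available).
#' @param codebooks named list of per-region [learn_codebook()] results
#'   (names = region ids).
#' @param per_region_k number of activity classes per region, or `"auto"`.
#' @param seed integer seed.
#' @param k_max upper bound of the per-region class sweep, default 3.
#' @return list with `class_id` (character vector, one per DA) and
#'   `histograms` (list of `segment_histogram` or NULL, one per DA).
#' @export
discover_model_classes <- function(das, codebooks, per_region_k = "auto",
                                   seed = 1L, k_max = 3L) {
  n <- length(das)
  class_id <- character(n)
  histograms <- vector("list", n)
  is_stay <- vapply(das, function(d) d$type == "stay", logical(1))
  for (i in which(!is_stay)) {
    class_id[i] <- sprintf("Change %d to %d", das[[i]]$from, das[[i]]$to)
  }
  for (P in unique(vapply(das[is_stay], function(d) d$from, integer(1)))) {
    idx <- which(is_stay & vapply(das, function(d) d$from == P, logical(1)))
    cb <- codebooks[[as.character(P)]]
    has_desc <- vapply(das[idx], function(d) !is.null(d$descriptors),
                       logical(1))
    if (is.null(cb) || !any(has_desc)) {
      class_id[idx] <- sprintf("Activity 1 in Zone %d", P)
      next
    }
    hs <- lapply(das[idx], function(d) encode_histogram(d$descriptors, cb))
    histograms[idx] <- hs
    H <- do.call(rbind, lapply(hs, function(h) h$normalized))
    enc <- idx[has_desc]
    Henc <- sqrt(H[has_desc, , drop = FALSE])  # Hellinger embedding
    k <- if (identical(per_region_k, "auto")) {
      select_k_silhouette(Henc, k_max = k_max, seed = seed + P)$k
    } else {
      min(per_region_k, nrow(unique(Henc)))
    }
    if (k <= 1L) {
      class_id[idx] <- sprintf("Activity 1 in Zone %d", P)
      next
    }
    fit <- seeded_kmeans(Henc, k, seed + P)
    # stable class numbering: order cluster centers lexicographically
    ord <- do.call(order, as.data.frame(fit$centers))
    rank <- match(seq_len(k), ord)
    cl <- rank[fit$cluster]
    class_id[enc] <- sprintf("Activity %d in Zone %d", cl, P)
    # descriptor-less stay DAs in a mixed region join the largest class
    if (any(!has_desc)) {
      major <- as.integer(names(which.max(table(cl))))
      class_id[idx[!has_desc]] <- sprintf("Activity %d in Zone %d", major, P)
    }
  }
  list(class_id = class_id, histograms = histograms)
}

#' Train Hierarchical Activity Models
#'
#' Builds one HAM per discovered class: neighborhoods of the member DAs are
#' clustered into a node tree and Gaussian attributes fitted. Priors are the
#' class relative frequencies in the training set; the class histogram is
#' the normalized mean encoded histogram of member DAs (when descriptors
#' exist).
#'
#' @param das list of `discovered_activity`.
#' @param classes a [discover_model_classes()] result (or a character vector
#'   of class ids).
#' @param codebooks named list of per-region codebooks.
#' @param fps frames per second.
#' @return list of `ham_model` objects: each has `model_id`, `root_key`,
#'   `nodes` (attributed tree), `prior`, `region`, `codebook_ref`,
#'   `class_hist`, `n_instances`, `degenerate`.
#' @export
train_models <- function(das, classes, codebooks, fps) {
  class_id <- if (is.list(classes)) classes$class_id else classes
  histograms <- if (is.list(classes)) classes$histograms
                else vector("list", length(das))
  if (length(class_id) != length(das)) stopf("classes must cover all DAs")
  models <- list()
  for (cid in sort(unique(class_id))) {
    idx <- which(class_id == cid)
    if (!length(idx)) next
    nbs <- lapply(das[idx], build_neighborhood)
    nodes <- fit_attributes(cluster_nodes(nbs), fps)
    region <- das[[idx[1L]]]$from
    hs <- histograms[idx]
    have <- vapply(hs, function(h) !is.null(h) && !isTRUE(h$empty), logical(1))
    class_hist <- if (any(have)) {
      m <- colMeans(do.call(rbind,
                            lapply(hs[have], function(h) h$normalized)))
      m / sum(m)
    } else NULL
    models[[cid]] <- structure(
      list(model_id = cid,
           root_key = node_key(1L, das[[idx[1L]]]$type_key),
           root_type = das[[idx[1L]]]$type_key,
           nodes = nodes,
           prior = length(idx) / length(das),
           region = region,
           codebook_ref = if (!is.null(codebooks[[as.character(region)]]))
             region else NA_integer_,
           class_hist = class_hist,
           n_instances = length(idx),
           degenerate = length(idx) < 2L),
      class = "ham_model")
  }
  models
}

#' @export
print.ham_model <- function(x, ...) {
  cat(sprintf("<ham_model> '%s': prior %.3f, %d instance(s), %d nodes%s\n",
              x$model_id, x$prior, x$n_instances, length(x$nodes),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
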