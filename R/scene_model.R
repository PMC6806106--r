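# Multi-resolution scene model: Gaussian scene regions learned from
# trajectory density by two-stage k-means, with BIC-selected K.
#
# Stage 1 clusters each subject's own trajectory points (robustness against
# per-subject outliers); stage 2 re-clusters the pooled stage-1 centers into
# the final regions of a topology.  A scene model holds three topologies
# (high/mid/low abstraction, i.e. few to many regions).

SIGMA_FLOOR <- 1e-6  # scene units; avoids zero-variance degenerate regions

#' Stage-1 clustering of one subject's trajectory points
#'
#' Clusters the points of a single trajectory sequence into `k` candidate
#' scene regions; the per-cluster standard deviation is computed from the
#' member point coordinates.
#'
#' @param seq a [trajectory_sequence()].
#' @param k number of clusters (must not exceed the number of points).
#' @param seed integer seed (k-means++-style restarts are deterministic
#'   given the seed).
#' @param use_z cluster in 3D when a `z` column is present (default FALSE).
#' @return data frame with one row per cluster: center columns (`mu_x`,
#'   `mu_y`[, `mu_z`]), per-axis standard deviations (`sigma_x`, ...), and
#'   `n` member points.
#' @export
cluster_stage1 <- function(seq, k, seed = 1L, use_z = FALSE) {
  stopifnot(inherits(seq, "trajectory_sequence"))
  if (!is_count(k) || k < 1L) stopf("k must be a positive integer")
  coords <- c("x", "y", if (use_z && "z" %in% names(seq$points)) "z")
  x <- as.matrix(seq$points[, coords, drop = FALSE])
  if (nrow(x) < k) {
    stopf("subject '%s' has %d points, fewer than k = %d",
          seq$subject_id, nrow(x), k)
  }
  k_eff <- min(k, nrow(unique(x)))
  fit <- seeded_kmeans(x, k_eff, seed)
  out <- lapply(seq_len(k_eff), function(c_i) {
    member <- x[fit$cluster == c_i, , drop = FALSE]
    c(colMeans(member), pop_sd(member), n = nrow(member))
  })
  out <- as.data.frame(do.call(rbind, out))
  names(out) <- c(paste0("mu_", coords), paste0("sigma_", coords), "n")
  out
}

# Spherical-Gaussian k-means BIC (x-means family): log-likelihood under a
# pooled per-axis spherical variance, penalized by (p/2) log n with
# p = k (d + 1) + 1 free parameters (k centers in d dims, k mixing weights,
# one shared variance).
kmeans_bic <- function(x, fit) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  k <- nrow(fit$centers)
  rss <- fit$tot.withinss
  sigma2 <- rss / (d * max(n - k, 1L))
  sigma2 <- max(sigma2, .Machine$double.eps)
  sizes <- tabulate(fit$cluster, nbins = k)
  ll <- sum(ifelse(sizes > 0, sizes * log(sizes / n), 0)) -
    n * d / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2)
  p <- k * (d + 1) + 1
  ll - p / 2 * log(n)
}

#' Select the number of clusters by BIC
#'
#' Sweeps `k_min..k_max`, fits seeded k-means at each k, and returns the k
#' maximizing the spherical-Gaussian k-means BIC. The full score trace is
#' returned so the selection can be audited.
#'
#' @param points numeric matrix (rows = points) or data frame of coordinates.
#' @param k_min,k_max sweep range (`1 <= k_min <= k_max < n`).
#' @param seed integer seed.
#' @return list with `k` (chosen), `trace` (data frame k/bic), and
#'   `degenerate` (TRUE when all points were identical and k = 1 was forced).
#' @export
select_k_bic <- function(points, k_min = 1L, k_max = 8L, seed = 1L) {
  x <- as.matrix(points)
  if (!is_count(k_min) || k_min < 1L) stopf("k_min must be >= 1")
  if (!is_count(k_max) || k_max < k_min) stopf("k_max must be >= k_min")
  if (nrow(x) <= k_max) stopf("need more points (%d) than k_max (%d)",
                              nrow(x), k_max)
  n_distinct <- nrow(unique(x))
  if (n_distinct == 1L) {
    warnf("all points identical; returning k = 1")
    return(list(k = 1L,
                trace = data.frame(k = 1L, bic = NA_real_),
                degenerate = TRUE))
  }
  ks <- seq.int(k_min, min(k_max, n_distinct))
  bics <- vapply(ks, function(k) {
    fit <- seeded_kmeans(x, k, seed + k)
    kmeans_bic(x, fit)
  }, numeric(1))
  list(k = ks[which.max(bics)],
       trace = data.frame(k = ks, bic = bics),
       degenerate = FALSE)
}

#' Learn one scene topology
#'
#' Runs stage-1 clustering per subject, pools the resulting centers, and
#' re-clusters them into `k` scene regions (stage 2). Region means and
#' standard deviations are then recomputed from the original trajectory
#' points transitively assigned to each stage-2 cluster (a single
#' refinement pass), so sparsely populated candidate centers do not bias
#' the final regions; weights are the fractions of training points per
#' region (they sum to 1).
#'
#' @param sequences list of [trajectory_sequence()].
#' @param k number of scene regions.
#' @param seed integer seed.
#' @param level label of the topology (`"high"`, `"mid"` or `"low"`).
#' @param k_stage1 stage-1 clusters per subject (clipped to the subject's
#'   point count), default 8.
#' @param use_z cluster in 3D when z is available.
#' @return object of class `topology`: list with `level`, `k`, and `regions`
#'   (data frame `id`, `mu_*`, `sigma_*`, `weight`, `n`); region ids are
#'   contiguous from 0.
#' @export
learn_topology <- function(sequences, k, seed = 1L, level = "high",
                           k_stage1 = 8L, use_z = FALSE) {
  if (inherits(sequences, "trajectory_sequence")) sequences <- list(sequences)
  if (!length(sequences)) stopf("need at least one sequence")
  if (!is_count(k) || k < 1L) stopf("k must be a positive integer")
  coords <- c("x", "y",
              if (use_z && all(vapply(sequences,
                                      function(s) "z" %in% names(s$points),
                                      logical(1)))) "z")
  centers1 <- do.call(rbind, lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    k1 <- min(k_stage1, nrow(s$points))
    st1 <- cluster_stage1(s, k1, seed = seed + i, use_z = use_z)
    as.matrix(st1[, paste0("mu_", coords), drop = FALSE])
  }))
  if (nrow(unique(centers1)) < k) {
    stopf("only %d distinct stage-1 centers for k = %d regions",
          nrow(unique(centers1)), k)
  }
  fit2 <- seeded_kmeans(centers1, k, seed)
  # transitively assign every raw point to its nearest stage-2 centroid
  allpts <- do.call(rbind, lapply(sequences, function(s)
    as.matrix(s$points[, coords, drop = FALSE])))
  assign <- nearest_row(allpts, fit2$centers)
  regions <- lapply(seq_len(k), function(c_i) {
    member <- allpts[assign == c_i, , drop = FALSE]
    if (nrow(member)) {
      c(colMeans(member), pmax(pop_sd(member), SIGMA_FLOOR), nrow(member))
    } else {
      c(fit2$centers[c_i, ], rep(SIGMA_FLOOR, length(coords)), 0L)
    }
  })
  regions <- as.data.frame(do.call(rbind, regions))
  names(regions) <- c(paste0("mu_", coords), paste0("sigma_", coords), "n")
  regions$weight <- regions$n / sum(regions$n)
  # stable region ids: order by first mean axis, then second
  ord <- do.call(order, as.list(regions[, paste0("mu_", coords), drop = FALSE]))
  regions <- regions[ord, , drop = FALSE]
  regions <- cbind(id = seq_len(k) - 1L, regions)
  rownames(regions) <- NULL
  structure(list(level = level, k = k, regions = regions, coords = coords),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> level '%s': %d scene regions\n", x$level, x$k))
  print(x$regions, digits = 4)
  invisible(x)
}

# Row index in `centers` nearest (Euclidean) to each row of `x`; ties break
# to the lowest index.
nearest_row <- function(x, centers) {
  x <- as.matrix(x)
  centers <- as.matrix(centers)
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Learn a three-level scene model
#'
#' Builds the high/mid/low-abstraction topologies. The coarse region count
#' `k_high` is either given or selected by BIC on the pooled training
#' points; the mid and low counts are multiples of it (defaults x2 and x3,
#' reproducing the canonical 5/10/15 layout when `k_high = 5`).
#'
#' @param sequences list of [trajectory_sequence()].
#' @param k_high coarse region count, or `"auto"` for BIC selection.
#' @param multipliers length-2 integer vector `(m_mid, m_low)`, default
#'   `c(2, 3)`.
#' @param seed integer seed.
#' @param k_stage1 stage-1 clusters per subject.
#' @param k_max BIC sweep upper bound in auto mode, default 8.
#' @param use_z cluster in 3D when z is available.
#' @return object of class `scene_model`: list with `topologies`
#'   (named list `high`, `mid`, `low`), `fps`, and `meta` (seeds, chosen K,
#'   BIC trace).
#' @export
learn_scene_model <- function(sequences, k_high = "auto",
                              multipliers = c(2L, 3L), seed = 1L,
                              k_stage1 = 8L, k_max = 8L, use_z = FALSE) {
  if (inherits(sequences, "trajectory_sequence")) sequences <- list(sequences)
  if (!length(sequences)) stopf("need at least one sequence")
  if (length(multipliers) != 2L || any(multipliers < 1L)) {
    stopf("multipliers must be two integers >= 1")
  }
  bic_trace <- NULL
  if (identical(k_high, "auto")) {
    allpts <- do.call(rbind, lapply(sequences, function(s)
      as.matrix(s$points[, c("x", "y"), drop = FALSE])))
    sel <- select_k_bic(allpts, 1L, k_max, seed = seed)
    k_high <- sel$k
    bic_trace <- sel$trace
  }
  if (!is_count(k_high) || k_high < 1L) stopf("k_high must be a positive integer")
  ks <- c(high = k_high,
          mid = multipliers[1L] * k_high,
          low = multipliers[2L] * k_high)
  topologies <- lapply(names(ks), function(lev) {
    learn_topology(sequences, ks[[lev]], seed = seed, level = lev,
                   k_stage1 = k_stage1, use_z = use_z)
  })
  names(topologies) <- names(ks)
  fps <- sequences[[1L]]$fps
  structure(list(topologies = topologies, fps = fps,
                 meta = list(seed = seed, k = as.list(ks),
                             multipliers = as.integer(multipliers),
                             k_stage1 = k_stage1, bic_trace = bic_trace)),
            class = "scene_model")
}

#' @export
print.scene_model <- function(x, ...) {
  ks <- vapply(x$topologies, function(t) t$k, integer(1))
  cat(sprintf("<scene_model> three topologies (high/mid/low): k = %s; fps %g\n",
              paste(ks, collapse = "/"), x$fps))
  invisible(x)
}

#' Assign points to scene regions
#'
#' Returns the id of the region whose mean is nearest (Euclidean) to each
#' point; ties break deterministically to the lowest region id.
#'
#' @param points data frame or matrix with columns/axes matching the
#'   topology's coordinates (at least `x`, `y`).
#' @param topology a [learn_topology()] result.
#' @return integer vector of region ids (0-based).
#' @export
assign_region <- function(points, topology) {
  stopifnot(inherits(topology, "topology"))
  if (is.data.frame(points)) {
    points <- as.matrix(points[, topology$coords, drop = FALSE])
  } else {
    points <- matrix(as.numeric(points), ncol = length(topology$coords))
  }
  centers <- as.matrix(topology$regions[, paste0("mu_", topology$coords),
                                        drop = FALSE])
  topology$regions$id[nearest_row(points, centers)]
}
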