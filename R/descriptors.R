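# Local-descriptor machinery: geometric skeleton features, per-region
# bag-of-words codebooks, histogram encoding and Bhattacharyya matching.
#
# The raw pixel-level descriptors (dense trajectories, HOG/HOF/MBH, deep
# features) are consumed as precomputed matrices; the geometric pose
# descriptor is computed here from 8 skeleton joints.

#' Geometric skeleton features
#'
#' For each frame t, each joint pair (i, j) with i < j, and each lag
#' t' in {t, t-1, ..., t-w}: the Euclidean distance `F_d` between joint i at
#' frame t and joint j at frame t', and the polar angle
#' `F_a = atan2(x_i - x_j, y_i - y_j)`. Pairs are enumerated row-major
#' (1-2, 1-3, ..., 7-8); lags run from 0 to w; positions before the first
#' frame are zero-padded. Each output row is
#' `[F_d(lag 0) pairs..., F_a(lag 0) pairs..., F_d(lag 1)..., ...]`.
#'
#' @param frames a `skeleton_frames` object (see [read_skeletons()]) or a
#'   list of 8x2 joint matrices.
#' @param w sliding-window size in frames (>= 0).
#' @return numeric matrix, one row per frame, `(w+1) * 28 * 2` columns.
#' @export
geometric_features <- function(frames, w = 0L) {
  joints <- if (inherits(frames, "skeleton_frames")) frames$joints else frames
  if (!length(joints)) stopf("need at least one skeleton frame")
  if (!is_count(w) || w < 0L) stopf("w must be a non-negative integer")
  for (t in seq_along(joints)) {
    joints[[t]] <- as.matrix(joints[[t]])
    if (!identical(dim(joints[[t]]), c(8L, 2L))) {
      stopf("skeleton frame %d must be an 8x2 joint matrix", t)
    }
  }
  pairs <- which(upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  n <- length(joints)
  out <- matrix(0, n, (w + 1L) * nrow(pairs) * 2L)
  for (t in seq_len(n)) {
    row <- numeric(0)
    for (lag in 0:w) {
      tp <- t - lag
      if (tp >= 1L) {
        a <- joints[[t]][pairs[, 1L], , drop = FALSE]
        b <- joints[[tp]][pairs[, 2L], , drop = FALSE]
        dx <- a[, 1L] - b[, 1L]
        dy <- a[, 2L] - b[, 2L]
        fd <- sqrt(dx^2 + dy^2)
        fa <- atan2(dx, dy)
      } else {
        fd <- fa <- numeric(nrow(pairs))  # zero padding before sequence start
      }
      row <- c(row, fd, fa)
    }
    out[t, ] <- row
  }
  out
}

#' Learn a visual codebook
#'
#' Clusters descriptor rows with seeded k-means into `size` code words and
#' stores the normalized histogram of the training assignments as the
#' codebook's reference histogram.
#'
#' @param descriptors numeric matrix, one descriptor per row.
#' @param size number of code words (conventional sizes: 16, 32, 64, 128,
#'   256, 512).
#' @param seed integer seed.
#' @param region_id scene region the codebook belongs to (bookkeeping).
#' @return object of class `codebook`: list with `region_id`, `size`,
#'   `words` (size x D matrix), `norm_hist` (sums to 1).
#' @export
learn_codebook <- function(descriptors, size, seed = 1L, region_id = NA_integer_) {
  x <- as.matrix(descriptors)
  if (!is_count(size) || size < 1L) stopf("size must be a positive integer")
  if (nrow(x) < size) {
    stopf("%d descriptor rows < codebook size %d; use a smaller size",
          nrow(x), size)
  }
  size_eff <- min(size, nrow(unique(x)))
  fit <- seeded_kmeans(x, size_eff, seed)
  counts <- tabulate(fit$cluster, nbins = size_eff)
  structure(list(region_id = region_id, size = size_eff,
                 words = fit$centers,
                 norm_hist = counts / sum(counts)),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> region %s: %d words of dim %d\n",
              x$region_id, x$size, ncol(x$words)))
  invisible(x)
}

#' Encode descriptors as a codebook histogram
#'
#' Hard nearest-word assignment of each descriptor row, then normalization.
#' An empty segment yields the uniform histogram with the `empty` flag set,
#' so recognition can neutralize the descriptor-distance term.
#'
#' @param segment a [descriptor_segment()], or a descriptor matrix, or NULL.
#' @param codebook a [learn_codebook()] result.
#' @return object of class `segment_histogram`: list with `counts`,
#'   `normalized` (sums to 1), `empty` flag.
#' @export
encode_histogram <- function(segment, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  x <- if (is.null(segment)) NULL
       else if (inherits(segment, "descriptor_segment")) segment$vectors
       else as.matrix(segment)
  if (is.null(x) || nrow(x) == 0L) {
    k <- codebook$size
    return(structure(list(counts = rep(0L, k),
                          normalized = rep(1 / k, k), empty = TRUE),
                     class = "segment_histogram"))
  }
  if (ncol(x) != ncol(codebook$words)) {
    stopf("descriptor dimensionality %d does not match codebook words (%d)",
          ncol(x), ncol(codebook$words))
  }
  assign <- nearest_row(x, codebook$words)
  counts <- tabulate(assign, nbins = codebook$size)
  structure(list(counts = counts, normalized = counts / sum(counts),
                 empty = FALSE),
            class = "segment_histogram")
}

#' Bhattacharyya coefficient of two normalized histograms
#'
#' `BC(h, v) = sum_b sqrt(h_b * v_b)`; 1 for identical histograms, 0 for
#' disjoint supports.
#'
#' @param h,v non-negative numeric vectors of equal length summing to 1.
#' @return value in \[0, 1\].
#' @export
bhattacharyya_coefficient <- function(h, v) {
  if (length(h) != length(v)) {
    stopf("histogram lengths differ (%d vs %d)", length(h), length(v))
  }
  min(sum(sqrt(h * v)), 1)
}

# Hellinger distance between normalized histograms: sqrt(1 - BC).
hellinger_distance <- function(h, v) {
  sqrt(max(0, 1 - bhattacharyya_coefficient(h, v)))
}

#' Bhattacharyya-based codebook distance
#'
#' Distance between a segment's assignment histogram and a reference
#' histogram (a codebook's training histogram by default): the Hellinger
#' distance `sqrt(1 - BC)`, in \[0, 1\], 0 iff identical, monotone
#' decreasing in similarity so that minimum distance means most similar.
#'
#' @param h a `segment_histogram` (or normalized numeric vector).
#' @param cb a `codebook`, or a reference normalized histogram.
#' @return distance in \[0, 1\].
#' @export
codebook_distance <- function(h, cb) {
  hv <- if (inherits(h, "segment_histogram")) h$normalized else as.numeric(h)
  rv <- if (inherits(cb, "codebook")) cb$norm_hist else as.numeric(cb)
  if (length(hv) != length(rv)) {
    stopf("histogram size %d does not match reference size %d",
          length(hv), length(rv))
  }
  hellinger_distance(hv, rv)
}

#' Most similar codebook for a descriptor segment
#'
#' Encodes the segment against every codebook and returns the codebook with
#' the minimum Bhattacharyya-based distance (ties break to the lowest
#' region id / list position).
#'
#' @param segment a [descriptor_segment()] or descriptor matrix.
#' @param codebooks list of `codebook`.
#' @return list with `region_id` (of the minimizer), `index` (position in
#'   the list), `distances` (named by region id).
#' @export
nearest_codebook <- function(segment, codebooks) {
  if (!length(codebooks)) stopf("need at least one codebook")
  d <- vapply(codebooks, function(cb)
    codebook_distance(encode_histogram(segment, cb), cb), numeric(1))
  ids <- vapply(codebooks, function(cb) cb$region_id, numeric(1))
  ord <- order(d, ids, seq_along(d))
  best <- ord[1L]
  names(d) <- ids
  list(region_id = ids[best], index = best, distances = d)
}
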