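# Core sequence/interval containers and delimited-table readers/writers.
#
# All frames are 0-based; intervals are closed [start_frame, end_frame];
# a duration in frames is end - start, converted to seconds through fps.

#' Construct a trajectory sequence
#'
#' A trajectory sequence holds the ordered planar positions of one tracked
#' subject, as produced by a person tracker: one row per observed frame.
#'
#' @param subject_id label of the tracked subject.
#' @param points data frame with columns `frame`, `x`, `y` and optionally
#'   `z`. Frames must be non-negative integers, strictly increasing;
#'   coordinates finite.
#' @param fps frame rate of the recording (frames per second), default 25.
#' @return an object of class `trajectory_sequence`.
#' @export
trajectory_sequence <- function(subject_id, points, fps = 25) {
  if (!is.data.frame(points)) stopf("`points` must be a data frame")
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(points))
  if (length(miss)) stopf("points missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stopf("fps must be a positive number")
  }
  points <- points[order(points$frame), , drop = FALSE]
  rownames(points) <- NULL
  if (nrow(points)) {
    if (any(points$frame < 0)) stopf("frame indices must be >= 0")
    if (any(points$frame != round(points$frame))) {
      stopf("frame indices must be integers")
    }
    if (anyDuplicated(points$frame)) {
      d <- points$frame[duplicated(points$frame)][1L]
      stopf("duplicate frame %d for subject '%s'", d, subject_id)
    }
    coords <- c("x", "y", if ("z" %in% names(points)) "z")
    for (cc in coords) {
      if (!all(is.finite(points[[cc]]))) {
        stopf("non-finite %s coordinate for subject '%s'", cc, subject_id)
      }
    }
  }
  structure(list(subject_id = as.character(subject_id),
                 points = points, fps = fps),
            class = "trajectory_sequence")
}

#' @export
print.trajectory_sequence <- function(x, ...) {
  rng <- if (nrow(x$points)) {
    sprintf("frames %d..%d", min(x$points$frame), max(x$points$frame))
  } else "empty"
  cat(sprintf("<trajectory_sequence> subject '%s': %d points (%s), fps %g\n",
              x$subject_id, nrow(x$points), rng, x$fps))
  invisible(x)
}

#' Construct a frame interval
#'
#' Closed interval of 0-based frame indices.
#'
#' @param start_frame,end_frame integers with `start_frame <= end_frame`.
#' @return named integer vector of class `frame_interval`.
#' @export
frame_interval <- function(start_frame, end_frame) {
  if (start_frame > end_frame) {
    stopf("invalid interval [%s, %s]: start > end", start_frame, end_frame)
  }
  structure(c(start_frame = as.integer(start_frame),
              end_frame = as.integer(end_frame)),
            class = "frame_interval")
}

#' Construct an annotation track
#'
#' A labelled set of frame intervals, the common representation of both
#' ground-truth activity annotations and emitted predictions.
#'
#' @param label character vector of labels.
#' @param start_frame,end_frame integer vectors of closed interval bounds.
#' @param score optional numeric score per entry.
#' @param overlap_tolerance maximum number of frames two entries may share
#'   beyond a common endpoint (default 0: endpoint sharing only).
#' @return data frame of class `annotation_track` with columns `label`,
#'   `start_frame`, `end_frame` (and `score` when supplied), sorted by
#'   `start_frame`.
#' @export
annotation_track <- function(label = character(), start_frame = integer(),
                             end_frame = integer(), score = NULL,
                             overlap_tolerance = 0L) {
  n <- length(label)
  if (length(start_frame) != n || length(end_frame) != n) {
    stopf("label, start_frame and end_frame must have equal length")
  }
  bad <- which(start_frame > end_frame)
  if (length(bad)) {
    stopf("entry %d ('%s'): start_frame %d > end_frame %d",
          bad[1L], label[bad[1L]], start_frame[bad[1L]], end_frame[bad[1L]])
  }
  df <- data.frame(label = as.character(label),
                   start_frame = as.integer(start_frame),
                   end_frame = as.integer(end_frame),
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  df <- df[order(df$start_frame, df$end_frame), , drop = FALSE]
  rownames(df) <- NULL
  if (n > 1L) {
    ov <- df$end_frame[-n] - df$start_frame[-1L]   # shared frames - 1
    if (any(ov > overlap_tolerance)) {
      i <- which(ov > overlap_tolerance)[1L]
      stopf("entries %d and %d overlap by more than the tolerance (%d frames)",
            i, i + 1L, overlap_tolerance)
    }
  }
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Read trajectory tables
#'
#' Reads a delimited table with header `subject_id,frame,x,y[,z]` and splits
#' it into one [trajectory_sequence()] per distinct subject, points sorted
#' by frame. Duplicate (subject, frame) rows are rejected.
#'
#' @param path file path of the CSV table.
#' @param fps frame rate to attach to every sequence (default 25).
#' @return named list of `trajectory_sequence`, one per subject, in order of
#'   first appearance.
#' @export
read_trajectories <- function(path, fps = 25) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("trajectory table %s missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  ids <- unique(df$subject_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id,
              intersect(c("frame", "x", "y", "z"), names(df)), drop = FALSE]
    if (anyDuplicated(sub$frame)) {
      d <- sub$frame[duplicated(sub$frame)][1L]
      stopf("duplicate (subject '%s', frame %d) in %s", id, d, path)
    }
    trajectory_sequence(id, sub, fps = fps)
  })
  names(out) <- as.character(ids)
  out
}

#' Write trajectory sequences
#'
#' Inverse of [read_trajectories()]; round-trips exactly.
#'
#' @param seqs list of `trajectory_sequence`.
#' @param path output CSV path.
#' @export
write_trajectories <- function(seqs, path) {
  if (inherits(seqs, "trajectory_sequence")) seqs <- list(seqs)
  has_z <- any(vapply(seqs, function(s) "z" %in% names(s$points), logical(1)))
  rows <- lapply(seqs, function(s) {
    p <- s$points
    if (has_z && !"z" %in% names(p)) p$z <- NA_real_
    cbind(data.frame(subject_id = rep(s$subject_id, nrow(p)),
                     stringsAsFactors = FALSE),
          p[, c("frame", "x", "y", if (has_z) "z"), drop = FALSE])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation track
#'
#' Parses a delimited table `label,start_frame,end_frame[,score]` into an
#' [annotation_track()].
#'
#' @param path CSV path.
#' @param overlap_tolerance passed to [annotation_track()].
#' @return `annotation_track`.
#' @export
read_annotations <- function(path, overlap_tolerance = 0L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_frame", "end_frame")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("annotation table %s missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  annotation_track(df$label, df$start_frame, df$end_frame,
                   score = if ("score" %in% names(df)) df$score,
                   overlap_tolerance = overlap_tolerance)
}

#' Write an annotation track
#'
#' Writes predictions (or any annotation track) as CSV
#' `label,start_frame,end_frame[,score]`; round-trips with
#' [read_annotations()].
#'
#' @param track `annotation_track`.
#' @param path output path.
#' @export
write_predictions <- function(track, path) {
  df <- as.data.frame(track)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read skeleton-joint tables
#'
#' Parses a table `frame,joint_id,x,y` with joint ids 1..8 into a list of
#' skeleton frames (8 joints each), ordered by frame.
#'
#' @param path CSV path.
#' @return list with elements `frame` (integer vector) and `joints` (list of
#'   8x2 matrices, rows ordered by joint id), class `skeleton_frames`.
#' @export
read_skeletons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "joint_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("skeleton table %s missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  frames <- sort(unique(df$frame))
  joints <- lapply(frames, function(f) {
    sub <- df[df$frame == f, , drop = FALSE]
    sub <- sub[order(sub$joint_id), , drop = FALSE]
    if (nrow(sub) != 8L || !identical(as.integer(sub$joint_id), 1:8)) {
      stopf("frame %d in %s does not carry exactly joints 1..8", f, path)
    }
    m <- as.matrix(sub[, c("x", "y")])
    rownames(m) <- NULL
    m
  })
  structure(list(frame = as.integer(frames), joints = joints),
            class = "skeleton_frames")
}

#' Construct a descriptor segment
#'
#' A matrix of local-descriptor rows (e.g. precomputed dense-trajectory,
#' HOG/HOF/MBH or geometric pose descriptors) keyed to the frame interval
#' they were extracted from.
#'
#' @param start_frame,end_frame closed frame interval of the segment.
#' @param vectors numeric matrix, one descriptor per row.
#' @return object of class `descriptor_segment`.
#' @export
descriptor_segment <- function(start_frame, end_frame, vectors) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) < 1L) stopf("descriptor rows must have dimensionality > 0")
  structure(list(interval = frame_interval(start_frame, end_frame),
                 vectors = vectors),
            class = "descriptor_segment")
}

#' Read descriptor segments
#'
#' Parses a table `start_frame,end_frame,d1..dD` (one row per descriptor)
#' and groups rows by their interval into [descriptor_segment()]s.
#'
#' @param path CSV path.
#' @return list of `descriptor_segment`, ordered by start frame.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_frame", "end_frame")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("descriptor table %s missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  dcols <- setdiff(names(df), need)
  if (!length(dcols)) stopf("descriptor table %s has no descriptor columns", path)
  key <- paste(df$start_frame, df$end_frame)
  segs <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    descriptor_segment(df$start_frame[idx[1L]], df$end_frame[idx[1L]],
                       as.matrix(df[idx, dcols, drop = FALSE]))
  })
  segs <- unname(segs)
  ord <- order(vapply(segs, function(s) s$interval[["start_frame"]], integer(1)))
  segs[ord]
}

#' Write descriptor segments
#'
#' Inverse of [read_descriptors()].
#'
#' @param segments list of `descriptor_segment`.
#' @param path output CSV path.
#' @export
write_descriptors <- function(segments, path) {
  rows <- lapply(segments, function(s) {
    v <- s$vectors
    colnames(v) <- paste0("d", seq_len(ncol(v)))
    cbind(data.frame(start_frame = rep(s$interval[["start_frame"]], nrow(v)),
                     end_frame = rep(s$interval[["end_frame"]], nrow(v))),
          as.data.frame(v))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
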