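# Primitive-event encoding and unsupervised activity discovery.
#
# Every pair of consecutive trajectory points maps to an atomic motion
# unit: Stay(P) when both points fall in scene region P, Change(P,Q) when
# the region flips between the two frames.  Maximal runs of same-region
# Stay pairs merge into one Stay event; a Change spans exactly the two
# frames of the transition, so events tile the frame range with shared
# endpoints only.  Discovery happens at the coarse topology only; mid- and
# low-level events are attached as children by temporal overlap.

type_key <- function(type, from, to) {
  ifelse(type == "stay",
         sprintf("Stay_%d", from),
         sprintf("Change_%d_%d", from, to))
}

#' Encode a trajectory as primitive events
#'
#' Labels every point with its scene region under `topology` and converts
#' consecutive point pairs into Stay/Change primitive events, merging
#' maximal same-region Stay runs.
#'
#' @param seq a [trajectory_sequence()].
#' @param topology a [learn_topology()] result.
#' @param min_stay_frames Stay runs strictly shorter than this many frames
#'   are absorbed into the neighbouring events (jitter suppression);
#'   default 1 (off).
#' @return object of class `pe_sequence`: data frame with columns `type`
#'   ("stay"/"change"), `from`, `to`, `start_frame`, `end_frame`,
#'   `duration_s`; attributes `level` and `fps`.
#' @export
encode_primitive_events <- function(seq, topology, min_stay_frames = 1L) {
  stopifnot(inherits(seq, "trajectory_sequence"),
            inherits(topology, "topology"))
  fps <- seq$fps
  pts <- seq$points
  if (nrow(pts) < 2L) {
    warnf("sequence '%s' has fewer than 2 points; empty event sequence",
          seq$subject_id)
    return(pe_sequence_df(character(), integer(), integer(),
                          integer(), integer(), topology$level, fps))
  }
  lab <- assign_region(pts, topology)
  frames <- pts$frame
  n <- length(lab)
  # run-length encode the region labels; runs of length >= 1 points
  r <- rle(lab)
  ends <- cumsum(r$lengths)          # point index of last point in each run
  starts <- ends - r$lengths + 1L    # point index of first point
  if (min_stay_frames > 1L && length(r$values) > 2L) {
    # absorb interior short runs into the longer neighbour (border jitter)
    keep <- rep(TRUE, length(r$values))
    span <- frames[ends] - frames[starts]
    for (i in seq_along(r$values)[-c(1L, length(r$values))]) {
      if (span[i] < min_stay_frames) keep[i] <- FALSE
    }
    if (!all(keep)) {
      lab2 <- lab
      for (i in which(!keep)) {
        # relabel the run's points with the previous surviving run's label
        prev <- max(which(keep[seq_len(i - 1L)]))
        lab2[starts[i]:ends[i]] <- r$values[prev]
      }
      r <- rle(lab2)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
    }
  }
  m <- length(r$values)
  type <- character(0); from <- integer(0); to <- integer(0)
  sf <- integer(0); ef <- integer(0)
  for (i in seq_len(m)) {
    # a Stay event exists when the run has >= 2 points (>= 1 same-region pair)
    if (r$lengths[i] >= 2L) {
      type <- c(type, "stay")
      from <- c(from, r$values[i]); to <- c(to, r$values[i])
      sf <- c(sf, frames[starts[i]]); ef <- c(ef, frames[ends[i]])
    }
    if (i < m) {
      type <- c(type, "change")
      from <- c(from, r$values[i]); to <- c(to, r$values[i + 1L])
      sf <- c(sf, frames[ends[i]]); ef <- c(ef, frames[starts[i + 1L]])
    }
  }
  pe_sequence_df(type, from, to, sf, ef, topology$level, fps)
}

pe_sequence_df <- function(type, from, to, start_frame, end_frame, level, fps) {
  df <- data.frame(type = type, from = as.integer(from), to = as.integer(to),
                   start_frame = as.integer(start_frame),
                   end_frame = as.integer(end_frame),
                   stringsAsFactors = FALSE)
  df$duration_s <- (df$end_frame - df$start_frame) / fps
  attr(df, "level") <- level
  attr(df, "fps") <- fps
  class(df) <- c("pe_sequence", "data.frame")
  df
}

#' @export
print.pe_sequence <- function(x, ...) {
  cat(sprintf("<pe_sequence> level '%s': %d primitive events (%d stay, %d change)\n",
              attr(x, "level"), nrow(x), sum(x$type == "stay"),
              sum(x$type == "change")))
  invisible(x)
}

#' Closed-interval temporal overlap
#'
#' TRUE when the closed frame intervals `[a_start, a_end]` and
#' `[b_start, b_end]` share at least one frame (the four-clause
#' containment/straddle disjunction reduces to non-empty intersection).
#' Vectorized over all arguments.
#'
#' @param a_start,a_end,b_start,b_end integer frame bounds.
#' @return logical vector.
#' @export
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  a_start <= b_end & b_start <= a_end
}

#' Discover activities from a coarse event sequence
#'
#' Activity discovery clips the recording at coarse-level event boundaries:
#' every coarse Stay event becomes a Stay discovered activity (DA) and every
#' coarse Change event a Change DA (a single primitive event). Each DA's
#' children are the mid- and low-level primitive events whose intervals
#' overlap its own, giving the three-level activity hierarchy.
#'
#' @param coarse,mid,low `pe_sequence` objects over the same frame range
#'   (coarse drives discovery; mid/low only provide children).
#' @return list of `discovered_activity` objects, each a list with `type`,
#'   `from`, `to`, `type_key`, `start_frame`, `end_frame`, `duration_s`,
#'   `children` (list of `pe_sequence` subsets `mid`, `low`), `descriptors`
#'   (NULL until [attach_descriptors()]).
#' @export
discover_activities <- function(coarse, mid, low) {
  stopifnot(inherits(coarse, "pe_sequence"))
  fps <- attr(coarse, "fps")
  rng <- function(pe) if (nrow(pe)) c(min(pe$start_frame), max(pe$end_frame))
                      else c(NA_integer_, NA_integer_)
  for (other in list(mid, low)) {
    stopifnot(inherits(other, "pe_sequence"))
    if (nrow(coarse) && nrow(other) &&
        !identical(rng(coarse), rng(other))) {
      stopf("event sequences cover different frame ranges (%s vs %s)",
            paste(rng(coarse), collapse = ".."),
            paste(rng(other), collapse = ".."))
    }
  }
  lapply(seq_len(nrow(coarse)), function(i) {
    sf <- coarse$start_frame[i]; ef <- coarse$end_frame[i]
    kid <- function(pe) {
      sel <- intervals_overlap(sf, ef, pe$start_frame, pe$end_frame)
      pe[sel, , drop = FALSE]
    }
    structure(list(type = coarse$type[i],
                   from = coarse$from[i], to = coarse$to[i],
                   type_key = type_key(coarse$type[i], coarse$from[i],
                                       coarse$to[i]),
                   start_frame = sf, end_frame = ef,
                   duration_s = (ef - sf) / fps,
                   fps = fps,
                   children = list(mid = kid(mid), low = kid(low)),
                   descriptors = NULL),
              class = "discovered_activity")
  })
}

#' @export
print.discovered_activity <- function(x, ...) {
  cat(sprintf("<discovered_activity> %s [%d, %d] (%.2f s), children: %d mid / %d low, %s\n",
              x$type_key, x$start_frame, x$end_frame, x$duration_s,
              nrow(x$children$mid), nrow(x$children$low),
              if (is.null(x$descriptors)) "no descriptors"
              else sprintf("%d descriptor rows", nrow(x$descriptors))))
  invisible(x)
}

#' Attach local descriptors to discovered activities
#'
#' Each DA receives the concatenated descriptor rows of every segment whose
#' interval overlaps its own (a segment straddling a boundary contributes to
#' both sides). DAs that receive no rows keep `descriptors = NULL` and are
#' treated as descriptor-less downstream.
#'
#' @param das list of `discovered_activity`.
#' @param segments list of [descriptor_segment()].
#' @return the enriched `das` list.
#' @export
attach_descriptors <- function(das, segments) {
  if (!length(segments)) return(das)
  dims <- vapply(segments, function(s) ncol(s$vectors), integer(1))
  if (length(unique(dims)) > 1L) {
    stopf("descriptor segments disagree on dimensionality: %s",
          paste(unique(dims), collapse = ", "))
  }
  ss <- vapply(segments, function(s) s$interval[["start_frame"]], integer(1))
  se <- vapply(segments, function(s) s$interval[["end_frame"]], integer(1))
  lapply(das, function(da) {
    sel <- which(intervals_overlap(da$start_frame, da$end_frame, ss, se))
    if (length(sel)) {
      da$descriptors <- do.call(rbind, lapply(segments[sel],
                                              function(s) s$vectors))
    }
    da
  })
}

#' Export discovered activities as an annotation track
#'
#' Labels are the DA type keys (`Stay_P` / `Change_P_Q`) unless explicit
#' labels are supplied (e.g. recognized model ids).
#'
#' @param das list of `discovered_activity`.
#' @param labels optional character vector of labels, one per DA.
#' @param scores optional numeric scores.
#' @return [annotation_track()].
#' @export
das_to_track <- function(das, labels = NULL, scores = NULL) {
  if (is.null(labels)) {
    labels <- vapply(das, function(d) d$type_key, character(1))
  }
  annotation_track(labels,
                   vapply(das, function(d) d$start_frame, integer(1)),
                   vapply(das, function(d) d$end_frame, integer(1)),
                   score = scores,
                   overlap_tolerance = 1L)
}
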