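# Shared test fixtures, built in code.

# Gaussian blob points around given centers.
blob_points <- function(centers, n_per, sd = 0.3, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1L], sd), rnorm(n_per, centers[i, 2L], sd))
  }))
}

# Trajectory visiting the rows of `centers` in order, n points per visit,
# consecutive frames, jitter sd.
visiting_sequence <- function(centers, n_per = 20L, sd = 0.05, seed = 1L,
                              subject = "A", fps = 25) {
  pts <- blob_points(centers, n_per, sd, seed)  # grouped per center, in order
  trajectory_sequence(subject,
                      data.frame(frame = seq_len(nrow(pts)) - 1L,
                                 x = pts[, 1L], y = pts[, 2L]),
                      fps = fps)
}

# Hand-built topology with unit sigmas at the given centers (ids 0-based).
toy_topology <- function(centers, level = "high") {
  k <- nrow(centers)
  structure(list(level = level, k = k,
                 regions = data.frame(id = seq_len(k) - 1L,
                                      mu_x = centers[, 1L],
                                      mu_y = centers[, 2L],
                                      sigma_x = rep(1, k),
                                      sigma_y = rep(1, k),
                                      n = rep(1L, k),
                                      weight = rep(1 / k, k)),
                 coords = c("x", "y")),
            class = "topology")
}

# Trajectory whose points follow an explicit region-label sequence, given a
# set of well-separated centers (one per region id).
labelled_sequence <- function(labels, centers, fps = 25, subject = "A") {
  pts <- centers[labels + 1L, , drop = FALSE]
  trajectory_sequence(subject,
                      data.frame(frame = seq_along(labels) - 1L,
                                 x = pts[, 1L], y = pts[, 2L]),
                      fps = fps)
}

# Standard three-region toy scene: centers far apart on a line.
TOY_CENTERS <- matrix(c(0, 0, 10, 0, 20, 0), ncol = 2L, byrow = TRUE)

# A small discovered-activity list from an explicit label path, using the
# same topology at all three levels (children mirror the coarse events).
toy_das <- function(labels, centers = TOY_CENTERS, fps = 25) {
  seq <- labelled_sequence(labels, centers, fps = fps)
  tp <- toy_topology(centers)
  pe <- encode_primitive_events(seq, tp)
  discover_activities(pe, pe, pe)
}

expect_annotation_invariants <- function(track) {
  expect_s3_class(track, "annotation_track")
  expect_true(all(track$start_frame <= track$end_frame))
  if (nrow(track) > 1L) {
    n <- nrow(track)
    expect_true(all(track$end_frame[-n] - track$start_frame[-1L] <= 0L))
  }
}
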