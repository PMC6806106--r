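test_that("consecutive points in different regions yield a change event", {
  # points in SR2 then SR4 of a five-region scene -> primitive event 2->4
  centers <- matrix(c(0, 0, 5, 0, 10, 0, 15, 0, 20, 0), 5L, byrow = TRUE)
  seq <- labelled_sequence(c(2L, 4L), centers)
  pe <- encode_primitive_events(seq, toy_topology(centers))
  expect_equal(nrow(pe), 1L)
  expect_equal(pe$type, "change")
  expect_equal(pe$from, 2L)
  expect_equal(pe$to, 4L)
})

test_that("same-region runs merge into maximal stay events", {
  centers <- TOY_CENTERS
  all_in <- labelled_sequence(rep(0L, 6L), centers)
  pe <- encode_primitive_events(all_in, toy_topology(centers))
  expect_equal(nrow(pe), 1L)
  expect_equal(pe$type, "stay")
  expect_equal(c(pe$start_frame, pe$end_frame), c(0L, 5L))

  # P,P,P,Q,Q -> Stay(P)[0..2], Change(P,Q)[2..3], Stay(Q)[3..4]
  pqs <- encode_primitive_events(labelled_sequence(c(0L, 0L, 0L, 1L, 1L),
                                                   centers),
                                 toy_topology(centers))
  expect_equal(pqs$type, c("stay", "change", "stay"))
  expect_equal(pqs$start_frame, c(0L, 2L, 3L))
  expect_equal(pqs$end_frame, c(2L, 3L, 4L))
  expect_equal(pqs$from, c(0L, 0L, 1L))
  expect_equal(pqs$to, c(0L, 1L, 1L))
  expect_equal(pqs$duration_s, c(2, 1, 1) / 25)
})

test_that("encoding reproduces the region labelling and tiles the range", {
  centers <- TOY_CENTERS
  set.seed(8)
  for (case in 1:20) {
    labels <- sample(0:2, sample(2:40, 1L), replace = TRUE)
    seq <- labelled_sequence(labels, centers)
    pe <- encode_primitive_events(seq, toy_topology(centers))
    # oracle: brute-force pairwise labelling then run merge
    lab <- assign_region(seq$points, toy_topology(centers))
    expect_identical(lab, labels)
    # reconstruction: per-frame region from stay events + change endpoints
    rec <- rep(NA_integer_, length(labels))
    for (i in seq_len(nrow(pe))) {
      if (pe$type[i] == "stay") {
        rec[(pe$start_frame[i]:pe$end_frame[i]) + 1L] <- pe$from[i]
      } else {
        rec[pe$start_frame[i] + 1L] <- pe$from[i]
        rec[pe$end_frame[i] + 1L] <- pe$to[i]
      }
    }
    expect_identical(rec, labels)
    # tiling: events cover the range, intersecting only at shared endpoints
    expect_equal(pe$start_frame[1L], 0L)
    expect_equal(pe$end_frame[nrow(pe)], length(labels) - 1L)
    if (nrow(pe) > 1L) {
      expect_true(all(pe$start_frame[-1L] == pe$end_frame[-nrow(pe)]))
    }
  }
})

test_that("short stay runs can be absorbed as border jitter", {
  centers <- TOY_CENTERS
  labels <- c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L)  # single-frame blip
  seq <- labelled_sequence(labels, centers)
  raw <- encode_primitive_events(seq, toy_topology(centers))
  expect_gt(nrow(raw), 1L)
  smooth <- encode_primitive_events(seq, toy_topology(centers),
                                    min_stay_frames = 3L)
  expect_equal(nrow(smooth), 1L)
  expect_equal(smooth$type, "stay")
})

test_that("a sub-two-point sequence encodes to an empty event list", {
  seq1 <- trajectory_sequence("A", data.frame(frame = 0L, x = 0, y = 0))
  expect_warning(pe <- encode_primitive_events(seq1, toy_topology(TOY_CENTERS)),
                 "fewer than 2")
  expect_equal(nrow(pe), 0L)
})

test_that("interval overlap equals frame-set intersection, exhaustively", {
  expect_true(intervals_overlap(10L, 20L, 10L, 20L))
  expect_false(intervals_overlap(10L, 20L, 21L, 30L))
  for (a1 in 0:12) for (a2 in a1:12) for (b1 in 0:12) for (b2 in b1:12) {
    oracle <- length(intersect(a1:a2, b1:b2)) > 0L
    expect_identical(intervals_overlap(a1, a2, b1, b2), oracle)
  }
})

test_that("discovery yields one DA per coarse event with overlapping children", {
  das1 <- toy_das(rep(0L, 8L))
  expect_length(das1, 1L)
  expect_equal(das1[[1]]$type_key, "Stay_0")
  expect_equal(nrow(das1[[1]]$children$mid), 1L)

  das3 <- toy_das(c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_length(das3, 3L)
  expect_equal(vapply(das3, function(d) d$type_key, character(1)),
               c("Stay_0", "Change_0_1", "Stay_1"))
  expect_equal(vapply(das3, function(d) d$start_frame, integer(1)),
               c(0L, 2L, 3L))
  expect_equal(vapply(das3, function(d) d$end_frame, integer(1)),
               c(2L, 3L, 5L))
})

test_that("DA intervals tile the timeline on random streams", {
  set.seed(31)
  for (case in 1:10) {
    labels <- unlist(lapply(sample(0:2, sample(3:8, 1L), replace = TRUE),
                            function(r) rep(r, sample(2:10, 1L))))
    das <- toy_das(labels)
    starts <- vapply(das, function(d) d$start_frame, integer(1))
    ends <- vapply(das, function(d) d$end_frame, integer(1))
    expect_equal(starts[1L], 0L)
    expect_equal(ends[length(ends)], length(labels) - 1L)
    if (length(das) > 1L) {
      expect_true(all(starts[-1L] == ends[-length(ends)]))
    }
    # children pass the overlap predicate
    for (d in das) {
      kid <- d$children$mid
      expect_true(all(intervals_overlap(d$start_frame, d$end_frame,
                                        kid$start_frame, kid$end_frame)))
    }
  }
})

test_that("discovery processed online matches batch for closed activities", {
  labels <- unlist(lapply(c(0L, 1L, 2L, 0L, 2L), function(r) rep(r, 8L)))
  centers <- TOY_CENTERS
  batch <- toy_das(labels)
  cut <- 25L  # inside the fourth run
  prefix <- toy_das(labels[seq_len(cut)])
  closed <- prefix[seq_len(length(prefix) - 1L)]  # last DA still open
  for (i in seq_along(closed)) {
    expect_equal(closed[[i]]$type_key, batch[[i]]$type_key)
    expect_equal(closed[[i]]$start_frame, batch[[i]]$start_frame)
    expect_equal(closed[[i]]$end_frame, batch[[i]]$end_frame)
  }
})

test_that("descriptor segments attach to every overlapped activity", {
  das <- toy_das(c(0L, 0L, 0L, 1L, 1L, 1L))  # Stay[0,2] Change[2,3] Stay[3,5]
  seg_exact <- descriptor_segment(0L, 2L, matrix(1:6, 2L, 3L))
  enriched <- attach_descriptors(das, list(seg_exact))
  expect_equal(nrow(enriched[[1]]$descriptors), 2L)
  expect_null(enriched[[3]]$descriptors)

  straddle <- descriptor_segment(2L, 4L, matrix(1, 1L, 3L))
  both <- attach_descriptors(das, list(straddle))
  expect_equal(nrow(both[[1]]$descriptors), 1L)
  expect_equal(nrow(both[[2]]$descriptors), 1L)
  expect_equal(nrow(both[[3]]$descriptors), 1L)

  none <- attach_descriptors(das, list())
  expect_true(all(vapply(none, function(d) is.null(d$descriptors), logical(1))))

  bad <- list(descriptor_segment(0L, 2L, matrix(1, 1L, 3L)),
              descriptor_segment(3L, 5L, matrix(1, 1L, 4L)))
  expect_error(attach_descriptors(das, bad), "dimensionality")
})

test_that("mismatched frame ranges across levels are rejected", {
  centers <- TOY_CENTERS
  a <- encode_primitive_events(labelled_sequence(c(0L, 0L, 1L, 1L), centers),
                               toy_topology(centers))
  b <- encode_primitive_events(labelled_sequence(c(0L, 0L, 1L), centers),
                               toy_topology(centers))
  expect_error(discover_activities(a, b, a), "frame ranges")
})
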