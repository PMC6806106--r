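# Brute-force per-frame label expansion used as the oracle.
frame_labels_oracle <- function(track, lo, hi) {
  lab <- rep(NA_character_, hi - lo + 1L)
  for (f in lo:hi) {
    for (i in seq_len(nrow(track))) {
      if (track$start_frame[i] <= f && f <= track$end_frame[i]) {
        lab[f - lo + 1L] <- track$label[i]
        break  # earlier interval owns shared boundary frames
      }
    }
  }
  lab
}

random_track <- function(n_entries, labels, hi = 100L, seed) {
  set.seed(seed)
  starts <- sort(sample(0:(hi - 5L), n_entries))
  ends <- pmin(starts + sample(1:8, n_entries, replace = TRUE), hi)
  ends <- pmin(ends, c(starts[-1L], hi))  # overlap at most at endpoints
  annotation_track(sample(labels, n_entries, replace = TRUE), starts, ends,
                   overlap_tolerance = 1L)
}

test_that("correspondence counts equal a per-frame double loop", {
  gt <- annotation_track(c("Drink", "Eat"), c(0L, 50L), c(49L, 99L))
  pred <- annotation_track(c("RA1", "RA2"), c(0L, 50L), c(49L, 99L))
  cor <- correspondence_matrix(pred, gt)
  expect_equal(unclass(cor)[, ],
               matrix(c(50L, 0L, 0L, 50L), 2L,
                      dimnames = list(c("RA1", "RA2"), c("Drink", "Eat"))))

  disj <- annotation_track("RA1", 200L, 250L)
  expect_true(all(correspondence_matrix(disj, gt) == 0L))

  for (seed in 1:10) {
    p <- random_track(6L, c("A", "B", "C"), seed = seed)
    g <- random_track(5L, c("X", "Y"), seed = seed + 100L)
    cor_r <- correspondence_matrix(p, g)
    pl <- frame_labels_oracle(p, 0L, 100L)
    gl <- frame_labels_oracle(g, 0L, 100L)
    for (ra in rownames(cor_r)) for (gtl in colnames(cor_r)) {
      expect_equal(cor_r[ra, gtl],
                   sum(!is.na(pl) & !is.na(gl) & pl == ra & gl == gtl))
    }
  }
})

test_that("label mapping maximizes co-occurrence one-to-one", {
  # renamed identity: recovers the permutation
  gt <- annotation_track(c("Drink", "Eat", "Read"), c(0L, 40L, 80L),
                         c(39L, 79L, 119L))
  pred <- annotation_track(c("Z9", "Z1", "Z5"), c(0L, 40L, 80L),
                           c(39L, 79L, 119L))
  mapping <- map_labels(correspondence_matrix(pred, gt))
  expect_equal(mapping[["Z9"]], "Drink")
  expect_equal(mapping[["Z1"]], "Eat")
  expect_equal(mapping[["Z5"]], "Read")

  # an activity co-occurring 80% with one label maps to that label
  cor <- matrix(c(80L, 20L, 10L, 90L), 2L, byrow = TRUE,
                dimnames = list(c("Activity 2 in Zone 1", "RA2"),
                                c("Prepare Drink", "Other")))
  class(cor) <- c("correspondence_matrix", class(cor))
  expect_equal(map_labels(cor)[["Activity 2 in Zone 1"]], "Prepare Drink")
})

test_that("mapping total equals brute-force permutation search up to 6x6", {
  brute_best <- brute_best_assignment
  set.seed(55)
  for (case in 1:30) {
    nr <- sample(1:6, 1L); nc <- sample(1:6, 1L)
    m <- matrix(sample(0:30, nr * nc, replace = TRUE), nr, nc,
                dimnames = list(paste0("RA", seq_len(nr)),
                                paste0("GT", seq_len(nc))))
    class(m) <- c("correspondence_matrix", class(m))
    mapping <- map_labels(m)
    total <- sum(vapply(seq_len(nr), function(i) {
      if (mapping[i] == "none") 0L else m[i, mapping[i]]
    }, integer(1)))
    expect_equal(total, brute_best(unclass(m)),
                 label = sprintf("case %d", case))
  }
})

test_that("detection requires strictly more than the overlap fraction", {
  gt <- annotation_track("Drink", 0L, 99L)
  # [0,79] overlaps exactly 80% of the 100-frame truth: not a detection
  pred_80 <- annotation_track("Drink", 0L, 79L)
  det <- detection_metrics(pred_80, gt, overlap_frac = 0.8)
  expect_equal(det$tp, 0L)
  expect_equal(det$fn, 1L)
  # one more frame crosses the threshold
  pred_81 <- annotation_track("Drink", 0L, 80L)
  det2 <- detection_metrics(pred_81, gt, overlap_frac = 0.8)
  expect_equal(det2$tp, 1L)
  expect_equal(det2$recall, 1)
})

test_that("detection metrics match hand-enumerated toy tracks", {
  # identical tracks: perfect per class
  gt <- annotation_track(c("A", "B", "A"), c(0L, 50L, 100L),
                         c(49L, 99L, 149L))
  det <- detection_metrics(gt, gt)
  expect_equal(det$precision, c(1, 1))
  expect_equal(det$recall, c(1, 1))
  expect_equal(det$f, c(1, 1))

  # 3-class fixture, hand-enumerated: A detected, B missed, C spurious
  gt3 <- annotation_track(c("A", "B"), c(0L, 100L), c(99L, 199L))
  pred3 <- annotation_track(c("A", "B", "C"), c(0L, 100L, 210L),
                            c(98L, 150L, 220L))
  det3 <- detection_metrics(pred3, gt3)
  expect_equal(det3[det3$label == "A", c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 0L, fn = 0L), ignore_attr = TRUE)
  # pred B covers 51 of 100 frames (51% < 80%): FN + FP
  expect_equal(det3[det3$label == "B", c("tp", "fp", "fn")],
               data.frame(tp = 0L, fp = 1L, fn = 1L), ignore_attr = TRUE)
  expect_equal(det3[det3$label == "B", "precision"], 0)

  # one long prediction cannot validate two ground-truth intervals
  gt_two <- annotation_track(c("A", "A"), c(0L, 10L), c(9L, 19L))
  pred_long <- annotation_track("A", 0L, 19L)
  det_long <- detection_metrics(pred_long, gt_two)
  expect_equal(det_long$tp, 1L)
  expect_equal(det_long$fn, 1L)
})

test_that("frame metrics reproduce a hand-computed 20-frame fixture", {
  # GT: A on [0,9], B on [10,19].  Pred: A on [0,7], B on [8,19].
  gt <- annotation_track(c("A", "B"), c(0L, 10L), c(9L, 19L))
  pred <- annotation_track(c("RA_A", "RA_B"), c(0L, 8L), c(7L, 19L))
  mapping <- map_labels(correspondence_matrix(pred, gt))
  expect_equal(mapping[["RA_A"]], "A")
  expect_equal(mapping[["RA_B"]], "B")
  fm <- frame_metrics(pred, gt, mapping)
  # hand counts: TP_A=8 FN_A=2 FP_A=0; TP_B=10 FP_B=2 FN_B=0
  expect_equal(fm$fa1, 18 / 20, tolerance = 1e-12)
  pc <- fm$per_class
  expect_equal(pc[pc$label == "A", "precision"], 1)
  expect_equal(pc[pc$label == "A", "recall"], 0.8)
  expect_equal(pc[pc$label == "A", "f"], 2 * 0.8 / 1.8, tolerance = 1e-12)
  expect_equal(pc[pc$label == "A", "iou"], 8 / 10, tolerance = 1e-12)
  expect_equal(pc[pc$label == "B", "precision"], 10 / 12, tolerance = 1e-12)
  expect_equal(pc[pc$label == "B", "recall"], 1)
  expect_equal(pc[pc$label == "B", "iou"], 10 / 12, tolerance = 1e-12)
  expect_equal(fm$mean_f, (2 * 0.8 / 1.8 + 2 * (10 / 12) / (1 + 10 / 12)) / 2,
               tolerance = 1e-12)
  expect_equal(fm$mean_iou, (0.8 + 10 / 12) / 2, tolerance = 1e-12)
})

test_that("degenerate frame metrics hit their bounds", {
  gt <- annotation_track(c("A", "B"), c(0L, 10L), c(9L, 19L))
  perfect <- frame_metrics(gt, gt)
  expect_equal(perfect$fa1, 1)
  expect_equal(perfect$mean_f, 1)
  expect_equal(perfect$mean_iou, 1)

  never <- annotation_track(c("B", "A"), c(0L, 10L), c(9L, 19L))
  fm0 <- frame_metrics(never, gt)
  expect_equal(fm0$fa1, 0)
  expect_equal(fm0$mean_iou, 0)
})

test_that("per-class IoU never exceeds precision or recall", {
  for (seed in 1:10) {
    p <- random_track(6L, c("A", "B", "C"), seed = 200L + seed)
    g <- random_track(6L, c("A", "B", "C"), seed = 300L + seed)
    fm <- frame_metrics(p, g)
    pc <- fm$per_class
    expect_true(all(pc$iou <= pc$recall + 1e-12))
    expect_true(all(pc$iou <= pc$precision + 1e-12))
    expect_true(all(pc$iou >= 0 & pc$iou <= 1))
  }
})

test_that("metrics are invariant under a common relabeling", {
  p <- random_track(6L, c("A", "B"), seed = 91L)
  g <- random_track(5L, c("A", "B"), seed = 92L)
  ren <- c(A = "Walk", B = "Sit")
  p2 <- annotation_track(unname(ren[p$label]), p$start_frame, p$end_frame,
                         overlap_tolerance = 1L)
  g2 <- annotation_track(unname(ren[g$label]), g$start_frame, g$end_frame,
                         overlap_tolerance = 1L)
  f1 <- frame_metrics(p, g)
  f2 <- frame_metrics(p2, g2)
  expect_equal(f1$fa1, f2$fa1)
  expect_equal(f1$mean_iou, f2$mean_iou)
  expect_equal(f1$mean_f, f2$mean_f)
})

test_that("neutral frames stay in FA1's denominator but out of averages", {
  gt <- annotation_track(c("A", "Neutral", "B"), c(0L, 10L, 15L),
                         c(9L, 14L, 24L))
  pred <- annotation_track(c("A", "B"), c(0L, 15L), c(9L, 24L))
  fm <- frame_metrics(pred, gt)
  expect_equal(fm$n_frames, 25L)
  expect_equal(fm$fa1, 20 / 25)
  expect_false("Neutral" %in% fm$per_class$label)
  fm2 <- frame_metrics(pred, gt, include_neutral = FALSE)
  expect_equal(fm2$fa1, 1)
})
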