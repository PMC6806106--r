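# Helpers: small DA streams with known structure, built through the real
# encoder on explicit label paths (same topology at all levels, so the
# child events mirror the coarse ones).

test_that("hierarchical neighborhoods respect the overlap predicate", {
  das <- toy_das(c(0L, 0L, 0L, 0L, 1L, 1L))
  nb <- build_neighborhood(das[[1]])
  expect_equal(nb$type_key, "Stay_0")
  expect_equal(nb$level, 1L)
  expect_gte(length(nb$children), 1L)
  expect_equal(nb$children[[1]]$level, 2L)
  expect_equal(nb$children[[1]]$children[[1]]$level, 3L)

  # every low event appears under exactly the mid events it overlaps
  das2 <- toy_das(unlist(lapply(c(0L, 1L, 0L, 2L), rep, times = 5L)))
  for (da in das2) {
    nb2 <- build_neighborhood(da)
    for (mid in nb2$children) {
      for (low in mid$children) {
        expect_true(intervals_overlap(mid$start_frame, mid$end_frame,
                                      low$start_frame, low$end_frame))
      }
    }
  }

  # childless DA -> leaf-only neighborhood
  da0 <- das[[1]]
  da0$children$mid <- da0$children$mid[0L, ]
  da0$children$low <- da0$children$low[0L, ]
  nb0 <- build_neighborhood(da0)
  expect_length(nb0$children, 0L)
})

test_that("node clustering groups primitive events by type key per level", {
  das <- toy_das(unlist(lapply(c(0L, 1L, 0L), rep, times = 4L)))
  stay0 <- Filter(function(d) d$type_key == "Stay_0", das)
  nbs <- lapply(stay0, build_neighborhood)
  nodes <- cluster_nodes(nbs)
  lv <- vapply(nodes, function(n) n$level, integer(1))
  expect_equal(sum(lv == 1L), 1L)
  # identical structures across instances -> tree isomorphic to one instance
  nodes_dup <- cluster_nodes(nbs[c(1L, 1L, 1L)])
  nodes1 <- cluster_nodes(nbs[1L])
  expect_setequal(names(nodes_dup), names(nodes1))

  # node count per level equals the number of distinct type keys observed
  set.seed(9)
  for (case in 1:10) {
    labels <- unlist(lapply(sample(0:2, sample(3:6, 1L), replace = TRUE),
                            rep, times = sample(3:6, 1L)))
    das_r <- toy_das(labels)
    root_keys <- vapply(das_r, function(d) d$type_key, character(1))
    pick <- which(root_keys == root_keys[1L])
    nbs_r <- lapply(das_r[pick], build_neighborhood)
    nodes_r <- cluster_nodes(nbs_r)
    mid_types <- unique(unlist(lapply(nbs_r, function(nb)
      vapply(nb$children, function(m) m$type_key, character(1)))))
    expect_equal(sum(vapply(nodes_r, function(n) n$level, integer(1)) == 2L),
                 length(mid_types))
  }

  # mixed root types are a caller error
  expect_error(cluster_nodes(lapply(das[1:2], build_neighborhood)),
               "mixed root types")
})

test_that("trees are well-formed: one root, acyclic, fully reachable", {
  das <- toy_das(unlist(lapply(c(0L, 1L, 2L, 1L, 0L), rep, times = 4L)))
  stay_das <- Filter(function(d) d$type_key == "Stay_1", das)
  nodes <- cluster_nodes(lapply(stay_das, build_neighborhood))
  roots <- names(nodes)[vapply(nodes, function(n) is.na(n$parent), logical(1))]
  expect_length(roots, 1L)
  # walk from the root; every node must be reached exactly once
  seen <- character(0)
  frontier <- roots
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- unlist(lapply(frontier, function(k) nodes[[k]]$children))
  }
  expect_setequal(seen, names(nodes))
  expect_equal(anyDuplicated(seen), 0L)
  for (k in names(nodes)) {
    p <- nodes[[k]]$parent
    if (!is.na(p)) expect_true(k %in% nodes[[p]]$children)
  }
})

test_that("duration attributes follow the population-variance form", {
  fps <- 25
  das <- toy_das(rep(c(0L, 1L, 0L), times = c(51L, 26L, 76L)), fps = fps)
  stay0 <- Filter(function(d) d$type_key == "Stay_0", das)
  nodes <- fit_attributes(cluster_nodes(lapply(stay0, build_neighborhood)),
                          fps)
  root <- nodes[["L1:Stay_0"]]
  durs <- vapply(stay0, function(d) d$duration_s, numeric(1))
  expect_equal(root$mu_d, mean(durs), tolerance = 1e-12)
  expect_equal(root$sigma2_d, max(mean((durs - mean(durs))^2), (1 / fps)^2),
               tolerance = 1e-12)

  # equal durations -> variance hits the floor; {1s, 3s} -> mu 2, var 1
  mk <- function(durs_s) {
    lapply(durs_s, function(d)
      list(type_key = "Stay_0", start_frame = 0L,
           end_frame = as.integer(d * fps), duration_s = d,
           level = 1L, children = list()))
  }
  n1 <- fit_attributes(cluster_nodes(mk(c(2, 2))), fps)
  expect_equal(n1[["L1:Stay_0"]]$mu_d, 2)
  expect_equal(n1[["L1:Stay_0"]]$sigma2_d, (1 / fps)^2)
  n2 <- fit_attributes(cluster_nodes(mk(c(1, 3))), fps)
  expect_equal(n2[["L1:Stay_0"]]$mu_d, 2)
  expect_equal(n2[["L1:Stay_0"]]$sigma2_d, 1)
})

test_that("attributes equal a brute-force recomputation from member spans", {
  set.seed(14)
  fps <- 25
  for (case in 1:5) {
    labels <- rep(sample(0:2, 6L, replace = TRUE),
                  times = sample(4:12, 6L, replace = TRUE))
    das <- toy_das(labels, fps = fps)
    keys <- vapply(das, function(d) d$type_key, character(1))
    pick <- which(keys == names(which.max(table(keys))))
    nodes <- fit_attributes(cluster_nodes(lapply(das[pick],
                                                 build_neighborhood)), fps)
    for (k in names(nodes)) {
      nd <- nodes[[k]]
      members <- do.call(rbind, nd$instances[!vapply(nd$instances, is.null,
                                                     logical(1))])
      durs <- (members$end_frame - members$start_frame) / fps
      expect_equal(nd$mu_d, mean(durs), tolerance = 1e-9)
      expect_equal(nd$sigma2_d,
                   max(mean((durs - mean(durs))^2), (1 / fps)^2),
                   tolerance = 1e-9)
      expect_equal(nd$n_members, length(durs))
    }
  }
})

test_that("model classes separate same-region activities by descriptors", {
  # two descriptor classes inside one region, auto k -> 2 classes
  das <- toy_das(unlist(lapply(rep(c(0L, 1L), 6L), rep, times = 6L)))
  stay0_idx <- which(vapply(das, function(d) d$type_key == "Stay_0",
                            logical(1)))
  set.seed(2)
  train_rows <- NULL
  for (j in seq_along(stay0_idx)) {
    mu <- if (j %% 2L == 0L) 0 else 10
    rows <- matrix(rnorm(30L * 2L, mu, 0.5), 30L, 2L)
    das[[stay0_idx[j]]]$descriptors <- rows
    train_rows <- rbind(train_rows, rows)
  }
  cb <- learn_codebook(train_rows, 8L, seed = 1L, region_id = 0L)
  cls <- discover_model_classes(das, list("0" = cb), per_region_k = "auto",
                                seed = 1L)
  got <- cls$class_id[stay0_idx]
  expect_length(unique(got), 2L)
  expect_equal(unique(got[seq(2, length(got), 2)]),
               setdiff(unique(got), unique(got[seq(1, length(got), 2)])))

  # no descriptors anywhere -> one class per region
  das_plain <- toy_das(unlist(lapply(c(0L, 1L, 0L, 1L), rep, times = 5L)))
  cls_plain <- discover_model_classes(das_plain, list(), seed = 1L)
  stays <- vapply(das_plain, function(d) d$type == "stay", logical(1))
  expect_length(unique(cls_plain$class_id[stays &
    vapply(das_plain, function(d) d$from == 0L, logical(1))]), 1L)

  # directed change pairs are distinct classes
  das_ch <- toy_das(c(0L, 0L, 1L, 1L, 0L, 0L))
  cls_ch <- discover_model_classes(das_ch, list(), seed = 1L)
  ch <- cls_ch$class_id[!vapply(das_ch, function(d) d$type == "stay",
                                logical(1))]
  expect_setequal(ch, c("Change 0 to 1", "Change 1 to 0"))
})

test_that("trained model priors are training class frequencies summing to 1", {
  das <- toy_das(unlist(lapply(c(0L, 1L, 0L, 1L, 0L), rep, times = 5L)))
  classes <- discover_model_classes(das, list(), seed = 1L)
  models <- train_models(das, classes, list(), fps = 25)
  priors <- vapply(models, function(m) m$prior, numeric(1))
  expect_equal(sum(priors), 1, tolerance = 1e-12)
  counts <- table(classes$class_id)
  for (m in models) {
    expect_equal(m$prior, as.numeric(counts[m$model_id]) / length(das))
  }

  # 3-vs-1 split -> priors 0.75 / 0.25
  das4 <- toy_das(unlist(lapply(c(0L, 1L, 0L, 1L, 0L, 1L, 0L),
                                rep, times = 5L)))
  keep <- vapply(das4, function(d) identical(d$type_key, "Stay_0"),
                 logical(1))
  das4 <- das4[keep]  # four Stay_0 instances
  cls4 <- list(class_id = c("A", "A", "A", "B"),
               histograms = vector("list", 4L))
  models4 <- train_models(das4, cls4, list(), fps = 25)
  expect_equal(models4[["A"]]$prior, 0.75)
  expect_equal(models4[["B"]]$prior, 0.25)
  expect_true(models4[["B"]]$degenerate)
})

test_that("training twice with the same inputs is byte-identical", {
  das <- toy_das(unlist(lapply(c(0L, 1L, 2L, 0L), rep, times = 5L)))
  classes <- discover_model_classes(das, list(), seed = 3L)
  m1 <- train_models(das, classes, list(), fps = 25)
  m2 <- train_models(das, classes, list(), fps = 25)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})
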