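# Synthetic smart-room scenarios: planted zones, activity schedules, noisy
# trajectories, skeletons and class-conditional descriptors, with ground
# truth, so the whole pipeline is testable without external recordings.
#
# Stay phases scatter points around the activity's home-zone center; walks
# between zones follow straight lines at constant speed plus Gaussian path
# noise.  Ground truth includes the planted zone of every frame (nearest
# zone to the noise-free planned position), whose flips mark the planted
# region transitions.

#' Build a scenario configuration
#'
#' @param room_size planar extent `c(width, height)` in scene units.
#' @param zones list of zones, each `list(center = c(x, y), sigma = s)`.
#' @param activity_classes list of classes, each `list(name, home_zone
#'   (1-based zone index), dur_mean, dur_sd (seconds), desc_mean (numeric
#'   vector, descriptor-space mean), desc_sd)`.
#' @param walk_speed walking speed between zones (units/second).
#' @param path_noise sd of Gaussian jitter around the walking line (units).
#' @param fps frames per second.
#' @param n_sequences number of sequences to generate.
#' @param n_activities activities per sequence.
#' @param descriptor_rate descriptor rows per second of a stay phase.
#' @param seed integer seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(room_size = c(10, 10),
                            zones,
                            activity_classes,
                            walk_speed = 10,
                            path_noise = 0.1,
                            fps = 25,
                            n_sequences = 5L,
                            n_activities = 6L,
                            descriptor_rate = 2,
                            seed = 1L) {
  for (z in zones) {
    if (any(z$center < 0) || z$center[1] > room_size[1] ||
        z$center[2] > room_size[2]) {
      stopf("zone center (%g, %g) outside the room", z$center[1], z$center[2])
    }
    if (z$sigma <= 0) stopf("zone sigma must be > 0")
  }
  for (a in activity_classes) {
    if (a$home_zone < 1L || a$home_zone > length(zones)) {
      stopf("class '%s' references unknown zone %d", a$name, a$home_zone)
    }
    if (a$dur_mean <= 0) stopf("class '%s' has non-positive duration", a$name)
  }
  centers <- do.call(rbind, lapply(zones, function(z) z$center))
  if (length(zones) > 1L) {
    dmin <- min(stats::dist(centers))
    smax <- max(vapply(zones, function(z) z$sigma, numeric(1)))
    if (dmin < 3 * smax) {
      warnf("zones closer than 3x their sigma; scenario may be unidentifiable")
    }
  }
  structure(list(room_size = room_size, zones = zones,
                 activity_classes = activity_classes,
                 walk_speed = walk_speed, path_noise = path_noise,
                 fps = fps, n_sequences = as.integer(n_sequences),
                 n_activities = as.integer(n_activities),
                 descriptor_rate = descriptor_rate,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Canned scenario fixtures
#'
#' * `"easy3"` — three well-separated zones, one activity class per zone,
#'   class-conditional descriptor means far apart.
#' * `"twin_zone"` — two activity classes sharing one zone (separable only
#'   by descriptors) plus a third class in a second zone.
#' * `"noisy"` — the easy3 geometry with wide zones and strong path noise
#'   (border jitter).
#'
#' @param name fixture name.
#' @param ... overrides passed on to [scenario_config()] (e.g. `seed`,
#'   `n_sequences`).
#' @return a `scenario_config`.
#' @export
scenario_fixtures <- function(name, ...) {
  base_zones <- list(list(center = c(2, 2), sigma = 0.35),
                     list(center = c(8, 2), sigma = 0.35),
                     list(center = c(5, 8), sigma = 0.35))
  d <- function(m) c(m, 0, 0)[1:3] * 8  # descriptor means 8 sd apart (sd 1)
  cls <- function(name, zone, mu, dmean)
    list(name = name, home_zone = zone, dur_mean = mu, dur_sd = mu / 6,
         desc_mean = dmean, desc_sd = 1)
  configs <- list(
    easy3 = list(
      zones = base_zones,
      activity_classes = list(
        cls("PrepareDrink", 1L, 25, c(0, 0, 0)),
        cls("EatMeal", 2L, 28, c(8, 0, 0)),
        cls("ReadBook", 3L, 22, c(0, 8, 0)))),
    twin_zone = list(
      zones = base_zones[1:2],
      activity_classes = list(
        cls("ReadBook", 1L, 25, c(0, 0, 0)),
        cls("WriteNotes", 1L, 25, c(8, 0, 0)),
        cls("Rest", 2L, 25, c(0, 8, 0)))),
    noisy = list(
      zones = lapply(base_zones, function(z) { z$sigma <- 0.8; z }),
      path_noise = 0.3,
      activity_classes = list(
        cls("PrepareDrink", 1L, 25, c(0, 0, 0)),
        cls("EatMeal", 2L, 28, c(8, 0, 0)),
        cls("ReadBook", 3L, 22, c(0, 8, 0)))))
  if (!name %in% names(configs)) {
    stopf("unknown fixture '%s' (have: %s)", name,
          paste(names(configs), collapse = ", "))
  }
  args <- utils::modifyList(configs[[name]], list(...))
  do.call(scenario_config, args)
}

# Fixed body-frame joint offsets (8 joints: head, shoulders, elbows, hips,
# knees collapsed to a planar stick figure around the trajectory point).
JOINT_OFFSETS <- matrix(c(0, 0.9,  -0.3, 0.6,  0.3, 0.6,  -0.45, 0.2,
                          0.45, 0.2,  -0.2, -0.3,  0.2, -0.3,  0, -0.7),
                        ncol = 2L, byrow = TRUE)

#' Simulate a complete scenario
#'
#' Generates, per sequence, a random activity schedule alternating Stay
#' phases (points jittered around the class's home zone) and walks between
#' zones (consecutive activities always sit in different zones so that
#' stays never merge), with descriptors per stay segment drawn from the
#' class-conditional Gaussian, an 8-joint skeleton, frame-accurate ground
#' truth and the planted zone of every frame. Deterministic given the
#' config seed.
#'
#' @param config a [scenario_config()].
#' @return list of class `scenario_truth`: per sequence a list with
#'   `sequence` ([trajectory_sequence()]), `annotations`
#'   ([annotation_track()]; walks carry the label `"Neutral"`), `segments`
#'   (list of [descriptor_segment()], one per stay), `skeleton`
#'   (`skeleton_frames`), `zone_by_frame` (1-based planted zone per frame),
#'   `transitions` (frames at which the planted zone flips), `schedule`
#'   (data frame of the planted activities). The config is attached as an
#'   attribute.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  zones <- config$zones
  classes <- config$activity_classes
  home <- vapply(classes, function(a) a$home_zone, integer(1))
  fps <- config$fps
  with_seed(config$seed, {
    out <- lapply(seq_len(config$n_sequences), function(s) {
      # schedule: consecutive activities live in different zones
      sched <- integer(config$n_activities)
      for (i in seq_len(config$n_activities)) {
        ok <- if (i == 1L) seq_along(classes)
              else which(home != home[sched[i - 1L]])
        if (!length(ok)) ok <- seq_along(classes)  # single-zone scenario
        sched[i] <- if (length(ok) == 1L) ok else sample(ok, 1L)
      }
      xs <- ys <- numeric(0)
      plan_x <- plan_y <- numeric(0)      # noise-free planned path
      labels <- character(0); seg_start <- seg_end <- integer(0)
      ann_lab <- character(0); ann_s <- ann_e <- integer(0)
      cls_osc <- stats::runif(length(classes), 0.8, 2.5)  # oscillation Hz
      frame0 <- 0L
      segments <- list()
      for (i in seq_along(sched)) {
        a <- classes[[sched[i]]]
        z <- zones[[a$home_zone]]
        dur <- max(a$dur_mean / 5, stats::rnorm(1, a$dur_mean, a$dur_sd))
        n <- max(10L, round(dur * fps))
        xs <- c(xs, z$center[1] + stats::rnorm(n, 0, z$sigma))
        ys <- c(ys, z$center[2] + stats::rnorm(n, 0, z$sigma))
        plan_x <- c(plan_x, rep(z$center[1], n))
        plan_y <- c(plan_y, rep(z$center[2], n))
        ann_lab <- c(ann_lab, a$name)
        ann_s <- c(ann_s, frame0)
        ann_e <- c(ann_e, frame0 + n - 1L)
        nrow_d <- max(5L, round(config$descriptor_rate * n / fps))
        D <- length(a$desc_mean)
        segments[[length(segments) + 1L]] <- descriptor_segment(
          frame0, frame0 + n - 1L,
          matrix(stats::rnorm(nrow_d * D, mean = rep(a$desc_mean,
                                                     each = nrow_d),
                              sd = a$desc_sd), nrow_d, D))
        frame0 <- frame0 + n
        if (i < length(sched)) {
          z2 <- zones[[classes[[sched[i + 1L]]]$home_zone]]
          dist <- sqrt(sum((z2$center - z$center)^2))
          nw <- max(2L, ceiling(dist / config$walk_speed * fps))
          tt <- seq_len(nw) / nw
          px <- z$center[1] + tt * (z2$center[1] - z$center[1])
          py <- z$center[2] + tt * (z2$center[2] - z$center[2])
          xs <- c(xs, px + stats::rnorm(nw, 0, config$path_noise))
          ys <- c(ys, py + stats::rnorm(nw, 0, config$path_noise))
          plan_x <- c(plan_x, px)
          plan_y <- c(plan_y, py)
          ann_lab <- c(ann_lab, "Neutral")
          ann_s <- c(ann_s, frame0)
          ann_e <- c(ann_e, frame0 + nw - 1L)
          frame0 <- frame0 + nw
        }
      }
      n_total <- frame0
      frames <- seq_len(n_total) - 1L
      seq_obj <- trajectory_sequence(sprintf("S%02d", s),
                                     data.frame(frame = frames, x = xs, y = ys),
                                     fps = fps)
      # planted zone per frame: nearest zone to the noise-free planned path
      centers <- do.call(rbind, lapply(zones, function(z) z$center))
      zone_by_frame <- nearest_row(cbind(plan_x, plan_y), centers)
      transitions <- frames[which(diff(zone_by_frame) != 0L) + 1L]
      # skeleton: offsets from the trajectory point + class oscillation
      osc_cls <- integer(n_total)
      for (j in seq_along(ann_lab)) {
        if (ann_lab[j] != "Neutral") {
          osc_cls[(ann_s[j]:ann_e[j]) + 1L] <-
            sched[sum(ann_lab[seq_len(j)] != "Neutral")]
        }
      }
      joints <- lapply(seq_len(n_total), function(t) {
        amp <- if (osc_cls[t] > 0L) 0.15 else 0.05
        freq <- if (osc_cls[t] > 0L) cls_osc[osc_cls[t]] else 1
        wob <- amp * sin(2 * pi * freq * (t - 1L) / fps +
                           seq_len(8L))
        cbind(xs[t] + JOINT_OFFSETS[, 1L] + wob,
              ys[t] + JOINT_OFFSETS[, 2L] + wob / 2)
      })
      list(sequence = seq_obj,
           annotations = annotation_track(ann_lab, ann_s, ann_e),
           segments = segments,
           skeleton = structure(list(frame = frames, joints = joints),
                                class = "skeleton_frames"),
           zone_by_frame = zone_by_frame,
           transitions = transitions,
           schedule = data.frame(class = vapply(sched, function(k)
             classes[[k]]$name, character(1)),
             zone = home[sched]))
    })
    names(out) <- vapply(out, function(o) o$sequence$subject_id, character(1))
    attr(out, "config") <- config
    class(out) <- "scenario_truth"
    out
  })
}

#' @export
print.scenario_truth <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<scenario_truth> %d sequence(s), %d zones, %d classes, fps %g\n",
              length(x), length(cfg$zones), length(cfg$activity_classes),
              cfg$fps))
  invisible(x)
}

#' Write a simulated scenario to disk
#'
#' Emits the standard CSV formats (trajectories, skeletons, descriptors,
#' ground-truth annotations) plus a truth JSON per sequence.
#'
#' @param truth a [simulate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(truth)) {
    tr <- truth[[nm]]
    write_trajectories(list(tr$sequence),
                       file.path(dir, paste0(nm, "_trajectory.csv")))
    write_predictions(tr$annotations, file.path(dir, paste0(nm, "_gt.csv")))
    write_descriptors(tr$segments,
                      file.path(dir, paste0(nm, "_descriptors.csv")))
    sk <- do.call(rbind, lapply(seq_along(tr$skeleton$frame), function(i)
      data.frame(frame = tr$skeleton$frame[i], joint_id = 1:8,
                 x = tr$skeleton$joints[[i]][, 1L],
                 y = tr$skeleton$joints[[i]][, 2L])))
    utils::write.csv(sk, file.path(dir, paste0(nm, "_skeleton.csv")),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(zone_by_frame = tr$zone_by_frame,
                              transitions = tr$transitions,
                              schedule = tr$schedule),
                         file.path(dir, paste0(nm, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
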