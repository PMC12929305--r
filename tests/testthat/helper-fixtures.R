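# Shared in-code fixtures: everything is generated, nothing lives on disk.

small_spec <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(image_size = c(64L, 64L), electrodes_per_catheter = c(3L, 5L),
         electrode_radius_px = c(1.5, 3), n_distractors = 1L,
         noise_sigma = 0, seed = seed),
    list(...))
  do.call(scene_spec, args)
}

# a hand-built scene with fully controlled annotations
manual_scene <- function(h = 64L, w = 64L, electrodes, sizes,
                         id = "scene_manual") {
  mask <- matrix(0L, h, w)
  for (i in seq_len(nrow(electrodes))) {
    mask[electrodes[i, 2] + 1L, electrodes[i, 1] + 1L] <- 1L
  }
  structure(list(image = matrix(0.5, h, w), mask = mask,
                 electrodes = matrix(as.numeric(electrodes), ncol = 2,
                                     dimnames = list(NULL, c("x", "y"))),
                 sizes = matrix(as.numeric(sizes), ncol = 2,
                                dimnames = list(NULL, c("w", "h"))),
                 scene_id = id),
            class = "annotated_scene")
}

# brute-force matching error over all permutations (n <= 6), mirroring the
# penalty convention: square matrix padded with the penalty distance
brute_force_mae <- function(pred, gt, penalty) {
  np <- nrow(pred); ng <- nrow(gt); m <- max(np, ng)
  cost <- matrix(penalty, m, m)
  if (np > 0 && ng > 0) {
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      cost[i, j] <- sqrt(sum((pred[i, ] - gt[j, ])^2))
    }
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    best <- min(best, sum(cost[cbind(seq_len(m), p)]))
  }
  best / m
}

# oracle predictions that reproduce the ground truth exactly
oracle_predictions <- function(scenes) {
  lapply(scenes, function(sc) {
    list(dets = data.frame(x = sc$electrodes[, 1], y = sc$electrodes[, 2],
                           w = sc$sizes[, 1], h = sc$sizes[, 2],
                           score = 1),
         mask = sc$mask)
  })
}

# independent greedy-matching AP evaluator (naive reimplementation used as
# the small-instance oracle)
naive_ap <- function(dets, gts, thresholds = seq(0.5, 0.95, by = 0.05)) {
  box_iou1 <- function(a, b) {
    ix <- max(0, min(a[1] + a[3] / 2, b[1] + b[3] / 2) - max(a[1] - a[3] / 2, b[1] - b[3] / 2))
    iy <- max(0, min(a[2] + a[4] / 2, b[2] + b[4] / 2) - max(a[2] - a[4] / 2, b[2] - b[4] / 2))
    inter <- ix * iy
    u <- a[3] * a[4] + b[3] * b[4] - inter
    if (u > 0) inter / u else 0
  }
  ngt <- sum(vapply(gts, function(g) nrow(g$electrodes), integer(1)))
  flat <- do.call(rbind, lapply(seq_along(dets), function(i) {
    d <- dets[[i]]
    if (nrow(d) == 0) return(NULL)
    cbind(img = i, as.matrix(d[, c("x", "y", "w", "h", "score")]))
  }))
  if (is.null(flat)) return(0)
  flat <- flat[order(-flat[, "score"], flat[, "img"]), , drop = FALSE]
  mean(vapply(thresholds, function(thr) {
    used <- lapply(gts, function(g) logical(nrow(g$electrodes)))
    tp <- fp <- numeric(nrow(flat))
    for (k in seq_len(nrow(flat))) {
      i <- flat[k, "img"]
      g <- gts[[i]]
      best <- 0; bi <- 0
      for (j in seq_len(nrow(g$electrodes))) {
        if (used[[i]][j]) next
        iou <- box_iou1(flat[k, c("x", "y", "w", "h")],
                        c(g$electrodes[j, ], g$sizes[j, ]))
        if (iou > best) { best <- iou; bi <- j }
      }
      if (best >= thr) { used[[i]][bi] <- TRUE; tp[k] <- 1 } else fp[k] <- 1
    }
    ctp <- cumsum(tp); cfp <- cumsum(fp)
    rec <- ctp / ngt; prec <- ctp / (ctp + cfp)
    for (k in rev(seq_along(prec))[-1]) prec[k] <- max(prec[k], prec[k + 1])
    mean(vapply(seq(0, 1, by = 0.01), function(r) {
      ok <- which(rec >= r - 1e-12)
      if (length(ok)) prec[ok[1]] else 0
    }, numeric(1)))
  }, numeric(1)))
}
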