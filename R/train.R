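#' Training configuration
#'
#' @param model a [model_config()].
#' @param lr AdamW learning rate (default 1e-4).
#' @param betas AdamW (beta1, beta2), default (0.9, 0.999).
#' @param weight_decay AdamW decoupled weight decay, default 0.01.
#' @param epochs number of passes over the dataset.
#' @param batch_size samples per iteration (>= 1).
#' @param seed RNG seed governing init, shuffling and augmentation.
#' @param alpha EMA discount of the prioritization state.
#' @param k_schedule top-k schedule `list(start, end, total)`; `total = NA`
#'   means "the run's total iteration count" and is resolved at train time.
#' @param assignment_mode sample-priority mode (see [sample_deltas()]).
#' @param eta hard-assignment binarization threshold.
#' @param kpi_metric_d,kpi_metric_s KPI metric choices.
#' @param augment list of toggles `scale`, `flip`, `rotate`.
#' @param baseline_mode `"dynamic"` (full prioritization),
#'   `"constant_weights"` (task weights fixed at the inverse of
#'   `constant_weights` while sample-level prioritization stays active — the
#'   task-weight ablation baseline), `"single_task_d"` or `"single_task_s"`
#'   (the other task's weight and availability are zeroed).
#' @param constant_weights the fixed (kappa_d, kappa_s) used by
#'   `"constant_weights"` (task weight is their inverse), default c(1, 1).
#' @param loss_normalize Eq-style `"batch"` (divide by N) or `"selected"`.
#' @param iters_per_epoch override the number of iterations per epoch
#'   (default: one pass over the dataset).
#' @return a `train_config` list.
#' @export
train_config <- function(model = model_config("tiny", input_size = c(96L, 96L)),
                         lr = 1e-4, betas = c(0.9, 0.999), weight_decay = 0.01,
                         epochs = 10L, batch_size = 8L, seed = 1L,
                         alpha = 0.9,
                         k_schedule = list(start = 0.7, end = 0.3, total = NA),
                         assignment_mode = "topk_hard", eta = 0.5,
                         kpi_metric_d = "mae", kpi_metric_s = "iou",
                         augment = list(scale = FALSE, flip = TRUE, rotate = TRUE),
                         baseline_mode = c("dynamic", "constant_weights",
                                           "single_task_d", "single_task_s"),
                         constant_weights = c(1, 1),
                         loss_normalize = "batch",
                         iters_per_epoch = NULL) {
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(model = model, lr = lr, betas = betas,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 alpha = alpha, k_schedule = k_schedule,
                 assignment_mode = assignment_mode, eta = eta,
                 kpi_metric_d = kpi_metric_d, kpi_metric_s = kpi_metric_s,
                 augment = augment, baseline_mode = match.arg(baseline_mode),
                 constant_weights = constant_weights,
                 loss_normalize = loss_normalize,
                 iters_per_epoch = iters_per_epoch),
            class = "train_config")
}

#' Desk-scale training preset (CPU, minutes)
#'
#' 96x96 inputs, tiny backbone, 10 epochs, batch size 4 with learning rate
#' 2e-3 — small batches buy twice the update count per epoch, which matters
#' far more than gradient noise on a schedule this short.
#' @param ... overrides passed to [train_config()].
#' @export
preset_desk <- function(...) {
  args <- list(model = model_config("tiny", input_size = c(96L, 96L)),
               lr = 2e-3, epochs = 10L, batch_size = 4L)
  do.call(train_config, utils::modifyList(args, list(...)))
}

#' Full-scale training preset (256x256, ResNet34 backbone, lr 1e-4)
#' @param ... overrides passed to [train_config()].
#' @export
preset_full <- function(...) {
  args <- list(model = model_config("resnet34", input_size = c(256L, 256L)),
               lr = 1e-4, epochs = 100L, batch_size = 8L)
  do.call(train_config, utils::modifyList(args, list(...)))
}

# ---- augmentation ---------------------------------------------------------

.flip_scene_h <- function(sc) {
  w <- ncol(sc$image)
  sc$image <- sc$image[, w:1]
  sc$mask <- sc$mask[, w:1]
  if (nrow(sc$electrodes)) sc$electrodes[, 1] <- w - 1 - sc$electrodes[, 1]
  sc
}

.flip_scene_v <- function(sc) {
  h <- nrow(sc$image)
  sc$image <- sc$image[h:1, ]
  sc$mask <- sc$mask[h:1, ]
  if (nrow(sc$electrodes)) sc$electrodes[, 2] <- h - 1 - sc$electrodes[, 2]
  sc
}

.rot180_scene <- function(sc) .flip_scene_v(.flip_scene_h(sc))

.rot90_scene <- function(sc) { # clockwise; square images only
  h <- nrow(sc$image)
  rot <- function(m) t(m[h:1, ])
  sc$image <- rot(sc$image)
  sc$mask <- rot(sc$mask)
  if (nrow(sc$electrodes)) {
    e <- sc$electrodes
    sc$electrodes <- cbind(x = h - 1 - e[, 2], y = e[, 1])
    sc$sizes <- sc$sizes[, 2:1, drop = FALSE]
    colnames(sc$sizes) <- c("w", "h")
  }
  sc
}

.resize_bilinear <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  ys <- pmin(pmax((seq_len(h2) - 0.5) * h / h2 - 0.5, 0), h - 1)
  xs <- pmin(pmax((seq_len(w2) - 0.5) * w / w2 - 0.5, 0), w - 1)
  y0 <- pmin(floor(ys), h - 2); x0 <- pmin(floor(xs), w - 2)
  ay <- ys - y0; ax <- xs - x0
  m00 <- m[cbind(rep(y0 + 1, w2), rep(x0 + 1, each = h2))]
  m10 <- m[cbind(rep(y0 + 2, w2), rep(x0 + 1, each = h2))]
  m01 <- m[cbind(rep(y0 + 1, w2), rep(x0 + 2, each = h2))]
  m11 <- m[cbind(rep(y0 + 2, w2), rep(x0 + 2, each = h2))]
  a <- rep(ay, w2); b <- rep(ax, each = h2)
  matrix((1 - a) * (1 - b) * m00 + a * (1 - b) * m10 +
           (1 - a) * b * m01 + a * b * m11, h2, w2)
}

# random zoom-in: crop a central window of fraction f then resize back
.scale_scene <- function(sc, f) {
  h <- nrow(sc$image); w <- ncol(sc$image)
  hh <- round(h * f); ww <- round(w * f)
  oy <- (h - hh) %/% 2L; ox <- (w - ww) %/% 2L
  img <- sc$image[oy + seq_len(hh), ox + seq_len(ww)]
  msk <- sc$mask[oy + seq_len(hh), ox + seq_len(ww)]
  sc$image <- .resize_bilinear(img, h, w)
  sc$mask <- matrix(as.integer(.resize_bilinear(msk, h, w) >= 0.5), h, w)
  if (nrow(sc$electrodes)) {
    ex <- (sc$electrodes[, 1] - ox + 0.5) * w / ww - 0.5
    ey <- (sc$electrodes[, 2] - oy + 0.5) * h / hh - 0.5
    keep <- ex >= 0 & ex <= w - 1 & ey >= 0 & ey <= h - 1
    sc$electrodes <- cbind(x = ex, y = ey)[keep, , drop = FALSE]
    sc$sizes <- cbind(w = sc$sizes[, 1] * w / ww, h = sc$sizes[, 2] * h / hh)[keep, , drop = FALSE]
  }
  sc
}

.augment_scene <- function(sc, aug) {
  if (isTRUE(aug$flip)) {
    if (stats::runif(1) < 0.5) sc <- .flip_scene_h(sc)
    if (stats::runif(1) < 0.5) sc <- .flip_scene_v(sc)
  }
  if (isTRUE(aug$rotate)) {
    if (nrow(sc$image) == ncol(sc$image)) {
      k <- sample(0:3, 1L)
      for (i in seq_len(k)) sc <- .rot90_scene(sc)
    } else if (stats::runif(1) < 0.5) {
      sc <- .rot180_scene(sc)
    }
  }
  if (isTRUE(aug$scale) && stats::runif(1) < 0.5) {
    sc <- .scale_scene(sc, stats::runif(1, 0.8, 0.95))
  }
  sc
}

# ---- optimizer ------------------------------------------------------------

.adamw_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamw_step <- function(opt, params, grads, lr, betas, wd, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * ((opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps) + wd * params[[nm]])
  }
  list(opt = opt, params = params)
}

# scale per-sample gradient slices of an (h, w, c, N) array by coef[n]
.scale_batch <- function(g, coef) {
  d <- dim(g)
  g * array(rep(coef, each = prod(d[1:3])), dim = d)
}

# ---- training loop --------------------------------------------------------

#' Train the multi-task model with dynamic resource prioritization
#'
#' Each iteration runs one forward pass serving both heads, computes
#' per-sample detection (focal + L1 size) and segmentation (BCE + IoU)
#' losses, measures per-sample KPIs from that same forward pass (decoded
#' electrode MAE, mask IoU), masks the per-sample losses with the
#' availability-times-priority weights delta, scales each task loss by the
#' inverse smoothed task KPI, backpropagates, and finally advances the EMA
#' state (task weights therefore lag the current batch by one step).
#'
#' @param config a [train_config()].
#' @param scenes list of `annotated_scene`s, or a dataset directory.
#' @param valid optional held-out scenes evaluated before and after training.
#' @param out optional output directory for `checkpoint.rds`,
#'   `priority_state.json` and `train_log.jsonl`.
#' @param verbose print a line per epoch.
#' @return list with `model`, `state`, `log` (one row per iteration),
#'   `config`, and `eval_before` / `eval_after` when `valid` is given.
#' @export
train <- function(config, scenes, valid = NULL, out = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (is.character(scenes)) scenes <- read_dataset(scenes)
  n <- length(scenes)
  stopifnot(n >= 1)
  set.seed(config$seed)
  model <- build_model(config$model)
  ipe <- config$iters_per_epoch %||% ceiling(n / config$batch_size)
  total_iters <- config$epochs * ipe
  ks <- config$k_schedule
  if (is.na(ks$total)) ks$total <- max(1L, total_iters)
  state <- priority_state(alpha = config$alpha, k_schedule = ks,
                          assignment_mode = config$assignment_mode,
                          eta = config$eta,
                          kpi_metric_d = config$kpi_metric_d,
                          kpi_metric_s = config$kpi_metric_s)
  opt <- .adamw_new(model$params)
  stride <- config$model$output_stride
  mode <- config$baseline_mode
  eval_before <- if (!is.null(valid)) evaluate(model, valid) else NULL
  log_rows <- vector("list", total_iters)
  it <- 0L
  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample.int(n)
    for (step in seq_len(ipe)) {
      off <- ((step - 1L) * config$batch_size) %% n
      pos <- ((off + seq_len(min(config$batch_size, n)) - 1L) %% n) + 1L
      pick <- order_idx[pos]
      batch <- lapply(scenes[pick], .augment_scene, aug = config$augment)
      ids <- vapply(batch, `[[`, character(1), "scene_id")
      N <- length(batch)
      d0 <- dim(batch[[1]]$image)
      imgs <- array(unlist(lapply(batch, `[[`, "image")), dim = c(d0, 1L, N))
      masks <- array(unlist(lapply(batch, `[[`, "mask")), dim = c(d0, N))
      targets <- lapply(batch, render_targets, stride = stride)
      theat <- array(unlist(lapply(targets, `[[`, "heatmap")),
                     dim = c(d0 %/% stride, N))
      fw <- model_forward(model, imgs, keep_tape = TRUE)
      foc <- .focal_vg(fw$heat_logits$value, theat)
      siz <- .size_vg(fw$size_map$value, targets)
      bce <- .bce_vg(fw$seg_logits$value, masks)
      iou <- .iou_vg(fw$seg_logits$value, masks)
      l_d_i <- foc$value + siz$value
      l_s_i <- bce$value + iou$value
      # per-sample KPIs from the same forward pass
      kd <- numeric(N); ks_i <- numeric(N)
      for (b in seq_len(N)) {
        hm <- fw$heat_logits$value[, , 1, b]
        sm <- array(fw$size_map$value[, , , b], dim = c(dim(hm), 2L))
        dets <- decode_detections(list(heatmap_logits = hm, size_map = sm,
                                       stride = stride),
                                  max_det = 2L * nrow(batch[[b]]$electrodes) + 5L,
                                  score_thresh = 0.25)
        kd[b] <- kpi_detection(as.matrix(dets[, c("x", "y")]),
                               batch[[b]]$electrodes, image_size = d0,
                               metric = config$kpi_metric_d)
        segp <- 1 / (1 + exp(-fw$seg_logits$value[, , 1, b]))
        ks_i[b] <- kpi_segmentation(segp, batch[[b]]$mask,
                                    metric = config$kpi_metric_s)
      }
      # priority weights; constant mode fixes only the task weights and keeps
      # the sample-level prioritization (the task-weight ablation baseline)
      if (mode %in% c("dynamic", "constant_weights")) {
        kf <- current_k_fraction(state)
        dd <- sample_deltas(sample_difficulties(state, "d", ids), kf,
                            state$assignment_mode, state$eta)
        ds <- sample_deltas(sample_difficulties(state, "s", ids), kf,
                            state$assignment_mode, state$eta)
        if (mode == "dynamic") {
          w_d <- 1 / state$kappa_bar[["d"]]
          w_s <- 1 / state$kappa_bar[["s"]]
        } else {
          w_d <- 1 / config$constant_weights[1]
          w_s <- 1 / config$constant_weights[2]
        }
      } else if (mode == "single_task_d") {
        kf <- 1; dd <- rep(1, N); ds <- rep(0, N); w_d <- 1; w_s <- 0
      } else {
        kf <- 1; dd <- rep(0, N); ds <- rep(1, N); w_d <- 0; w_s <- 1
      }
      l_d <- masked_task_loss(l_d_i, dd, config$loss_normalize)
      l_s <- masked_task_loss(l_s_i, ds, config$loss_normalize)
      lt <- w_d * l_d + w_s * l_s
      if (!is.finite(lt)) {
        stop(sprintf("training diverged (non-finite loss) at iteration %d", it + 1L))
      }
      # backprop: per-sample seed coefficients delta * task weight / N
      nd <- if (config$loss_normalize == "batch") N else max(1, sum(dd))
      ns <- if (config$loss_normalize == "batch") N else max(1, sum(ds))
      seeds <- list()
      if (w_d > 0 && any(dd > 0)) {
        cd <- w_d * dd / nd
        seeds <- c(seeds,
                   list(list(node = fw$heat_logits, grad = .scale_batch(foc$grad, cd)),
                        list(node = fw$size_map, grad = .scale_batch(siz$grad, cd))))
      }
      if (w_s > 0 && any(ds > 0)) {
        cs <- w_s * ds / ns
        seeds <- c(seeds,
                   list(list(node = fw$seg_logits,
                             grad = .scale_batch(bce$grad + iou$grad, cs))))
      }
      if (length(seeds)) ad_backward(fw$tape, seeds)
      grads <- lapply(fw$param_nodes, function(pnode) pnode$grad)
      stepped <- .adamw_step(opt, model$params, grads, config$lr, config$betas,
                             config$weight_decay)
      opt <- stepped$opt
      model$params <- stepped$params
      state <- update_state(state, list(d = stats::setNames(kd, ids),
                                        s = stats::setNames(ks_i, ids)))
      it <- it + 1L
      log_rows[[it]] <- data.frame(iter = it, epoch = epoch,
                                   l_d = l_d, l_s = l_s, l_total = lt,
                                   kappa_bar_d = state$kappa_bar[["d"]],
                                   kappa_bar_s = state$kappa_bar[["s"]],
                                   k_fraction = kf,
                                   sum_delta_d = sum(dd), sum_delta_s = sum(ds))
    }
    if (verbose) {
      message(sprintf("epoch %d/%d: L=%.4f (d %.4f, s %.4f) kbar=(%.3f, %.3f)",
                      epoch, config$epochs, lt, l_d, l_s,
                      state$kappa_bar[["d"]], state$kappa_bar[["s"]]))
    }
  }
  log <- do.call(rbind, log_rows)
  eval_after <- if (!is.null(valid)) evaluate(model, valid) else NULL
  res <- list(model = model, state = state, log = log, config = config,
              eval_before = eval_before, eval_after = eval_after)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    saveRDS(list(format = "cathmtl-checkpoint-v1", params = model$params,
                 config = config$model, train_config = config,
                 priority_state = state), file.path(out, "checkpoint.rds"))
    jsonlite::write_json(list(kappa_bar = as.list(state$kappa_bar),
                              tau = state$tau, alpha = state$alpha,
                              k_schedule = state$k_schedule,
                              assignment_mode = state$assignment_mode),
                         file.path(out, "priority_state.json"), auto_unbox = TRUE)
    writeLines(vapply(seq_len(nrow(log)), function(i) {
      jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1)), file.path(out, "train_log.jsonl"))
  }
  res
}

#' Load a checkpoint written by [train()]
#' @param path path to `checkpoint.rds`.
#' @return a list with the restored `model` and `priority_state`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(identical(ck$format, "cathmtl-checkpoint-v1"))
  model <- build_model(ck$config)
  model$params <- ck$params
  list(model = model, state = ck$priority_state)
}

#' Ablation harness: train variants and tabulate their evaluation
#'
#' @param variants named list of [train_config()] overrides (lists passed to
#'   `modifyList` on `base`'s fields).
#' @param base a [train_config()] serving as the shared baseline.
#' @param scenes training scenes.
#' @param valid held-out scenes for the reported metrics.
#' @param csv optional path for a CSV report.
#' @return data.frame with columns `variant`, `ap`, `mean_j`, `mean_kpi`.
#' @export
ablate <- function(variants, base, scenes, valid, csv = NULL) {
  rows <- lapply(names(variants), function(vn) {
    cfg <- base
    ov <- variants[[vn]]
    for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
    fit <- train(cfg, scenes, valid = valid)
    data.frame(variant = vn, ap = fit$eval_after$ap,
               mean_j = fit$eval_after$mean_j,
               mean_kpi = fit$eval_after$mean_kpi)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
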