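#' Decode detections from a center heatmap
#'
#' Sigmoid on the heatmap logits, 3x3 local-maximum suppression (a cell
#' survives iff it equals its 3x3 neighbourhood max; plateau ties broken by
#' raster order), then the top `max_det` surviving cells with score above
#' `score_thresh`. Centers are placed at `(cell + 0.5) * stride` to undo the
#' half-cell quantization bias; sizes are read from the size map at the cell.
#'
#' @param pred a `prediction_maps` object (single image: N = 1), or a list
#'   with `heatmap_logits` matrix, `size_map` (h x w x 2) and `stride`.
#' @param max_det maximum number of detections (default 50).
#' @param score_thresh minimum score (default 0.05).
#' @return data.frame with columns `x`, `y`, `w`, `h`, `score`, ordered by
#'   decreasing score.
#' @export
decode_detections <- function(pred, max_det = 50L, score_thresh = 0.05) {
  hm <- pred$heatmap_logits
  sm <- pred$size_map
  if (length(dim(hm)) == 4L) {
    stopifnot(dim(hm)[4] == 1L)
    hm <- hm[, , 1, 1]
    sm <- array(sm[, , , 1], dim = dim(sm)[1:3])
  }
  if (any(!is.finite(hm))) stop("decode_detections: non-finite heatmap")
  stride <- pred$stride
  score <- 1 / (1 + exp(-hm))
  h <- nrow(score); w <- ncol(score)
  # 3x3 neighbourhood max via padded shifts
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- score
  nb <- matrix(-Inf, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    nb <- pmax(nb, pad[dy + seq_len(h), dx + seq_len(w)])
  }
  keep <- which(score >= nb & score > score_thresh)
  if (length(keep) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), score = numeric(0)))
  }
  cy <- (keep - 1L) %% h       # 0-based row
  cx <- (keep - 1L) %/% h      # 0-based col
  raster <- cy * w + cx        # row-major raster order for tie-breaks
  ord <- order(-score[keep], raster)
  ord <- ord[seq_len(min(max_det, length(ord)))]
  data.frame(x = (cx[ord] + 0.5) * stride,
             y = (cy[ord] + 0.5) * stride,
             w = sm[cbind(cy[ord] + 1L, cx[ord] + 1L, 1L)],
             h = sm[cbind(cy[ord] + 1L, cx[ord] + 1L, 2L)],
             score = score[keep][ord])
}

.box_iou <- function(b1, b2) {
  # boxes as (x, y, w, h) centers+extents
  x1 <- pmax(b1[1] - b1[3] / 2, b2[, 1] - b2[, 3] / 2)
  x2 <- pmin(b1[1] + b1[3] / 2, b2[, 1] + b2[, 3] / 2)
  y1 <- pmax(b1[2] - b1[4] / 2, b2[, 2] - b2[, 4] / 2)
  y2 <- pmin(b1[2] + b1[4] / 2, b2[, 2] + b2[, 4] / 2)
  inter <- pmax(0, x2 - x1) * pmax(0, y2 - y1)
  union <- b1[3] * b1[4] + b2[, 3] * b2[, 4] - inter
  ifelse(union > 0, inter / union, 0)
}

#' COCO-style average precision over IoU thresholds 0.50:0.05:0.95
#'
#' Per threshold, detections are greedily matched in descending score order
#' to the unmatched ground-truth box of highest IoU at or above the
#' threshold; the precision-recall curve is integrated with 101-point
#' interpolation and the final AP is the mean over thresholds. Ground-truth
#' boxes are the annotated (w, h) extents centred at the electrode centers.
#'
#' @param dets list (one per image) of detection data.frames from
#'   [decode_detections()].
#' @param gts list (one per image) of `annotated_scene` objects or lists
#'   with `electrodes` and `sizes` matrices.
#' @param iou_thresholds defaults to `seq(0.5, 0.95, by = 0.05)`.
#' @return AP in [0, 1].
#' @export
average_precision <- function(dets, gts, iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(length(dets) == length(gts))
  gt_boxes <- lapply(gts, function(g) {
    if (nrow(g$electrodes) == 0L) {
      matrix(numeric(0), 0, 4)
    } else {
      cbind(g$electrodes[, 1], g$electrodes[, 2], g$sizes[, 1], g$sizes[, 2])
    }
  })
  n_gt <- sum(vapply(gt_boxes, nrow, integer(1)))
  if (n_gt == 0L) stop("average_precision: no ground truth in the dataset")
  # flatten detections with image index, globally sorted by descending score
  all_img <- integer(0); all_score <- numeric(0); all_box <- NULL
  for (i in seq_along(dets)) {
    d <- dets[[i]]
    if (nrow(d) == 0L) next
    all_img <- c(all_img, rep(i, nrow(d)))
    all_score <- c(all_score, d$score)
    all_box <- rbind(all_box, cbind(d$x, d$y, d$w, d$h))
  }
  if (length(all_score) == 0L) return(0)
  ord <- order(-all_score, all_img, seq_along(all_score))
  aps <- vapply(iou_thresholds, function(thr) {
    used <- lapply(gt_boxes, function(g) logical(nrow(g)))
    tp <- numeric(length(ord)); fp <- numeric(length(ord))
    for (k in seq_along(ord)) {
      j <- ord[k]
      img <- all_img[j]
      g <- gt_boxes[[img]]
      best <- 0; best_i <- 0L
      if (nrow(g) > 0L) {
        ious <- .box_iou(all_box[j, ], g)
        ious[used[[img]]] <- -1
        best_i <- which.max(ious)
        best <- ious[best_i]
      }
      if (best >= thr) {
        used[[img]][best_i] <- TRUE
        tp[k] <- 1
      } else {
        fp[k] <- 1
      }
    }
    ctp <- cumsum(tp); cfp <- cumsum(fp)
    recall <- ctp / n_gt
    precision <- ctp / (ctp + cfp)
    # precision envelope + 101-point interpolation
    for (k in rev(seq_along(precision))[-1]) {
      precision[k] <- max(precision[k], precision[k + 1])
    }
    rgrid <- seq(0, 1, by = 0.01)
    idx <- findInterval(rgrid, recall, left.open = TRUE) + 1L
    mean(ifelse(idx <= length(precision), precision[idx], 0))
  }, numeric(1))
  mean(aps)
}

#' Region similarity (IoU of predicted and ground-truth masks)
#'
#' Probabilities are binarized at 0.5. Two empty masks are identical and
#' score 1; disjoint masks score 0 (no smoothing).
#'
#' @param pred_mask predicted mask (binary or probabilities).
#' @param gt_mask binary ground truth of the same shape.
#' @return IoU in [0, 1].
#' @export
region_similarity <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask))) stop("region_similarity: shape mismatch")
  p <- pred_mask >= 0.5
  m <- gt_mask >= 0.5
  u <- sum(p | m)
  if (u == 0) return(1)
  sum(p & m) / u
}

#' Evaluate predictions against annotated scenes
#'
#' @param preds list (one per scene) of lists with `dets` (detection
#'   data.frame) and `mask` (H x W probability or binary mask).
#' @param scenes list of `annotated_scene` objects.
#' @return an `eval_report`: `ap`, `mean_j`, `mae_px`, `mean_kpi`
#'   (= (ap + mean_j) / 2) and `n`.
#' @export
evaluate_predictions <- function(preds, scenes) {
  stopifnot(length(preds) == length(scenes), length(scenes) > 0)
  js <- numeric(length(scenes))
  maes <- numeric(length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    js[i] <- region_similarity(preds[[i]]$mask, sc$mask)
    d <- preds[[i]]$dets
    maes[i] <- matching_error(as.matrix(d[, c("x", "y")]), sc$electrodes,
                              image_size = dim(sc$image))
  }
  ap <- average_precision(lapply(preds, `[[`, "dets"), scenes)
  mean_j <- mean(js)
  structure(list(ap = ap, mean_j = mean_j, mae_px = mean(maes),
                 mean_kpi = (ap + mean_j) / 2, n = length(scenes)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (n = %d)\n  AP        : %.4f\n  mean J    : %.4f\n  mean KPI  : %.4f\n  MAE (px)  : %.2f\n",
              x$n, x$ap, x$mean_j, x$mean_kpi, x$mae_px))
  invisible(x)
}

#' Run the model over a dataset and evaluate both tasks
#'
#' One forward pass per batch serves both heads; `mean_j` averages the
#' per-image mask IoU, AP pools detections over all images, and
#' `mean_kpi = (ap + mean_j) / 2`.
#'
#' @param model a `cath_model`.
#' @param scenes list of `annotated_scene` objects (or a dataset directory).
#' @param batch_size forward batch size (default 8).
#' @param max_det,score_thresh decoding parameters.
#' @return an `eval_report`.
#' @export
evaluate <- function(model, scenes, batch_size = 8L, max_det = 50L,
                     score_thresh = 0.05) {
  if (is.character(scenes)) scenes <- read_dataset(scenes)
  stopifnot(length(scenes) > 0)
  preds <- predict_scenes(model, scenes, batch_size = batch_size,
                          max_det = max_det, score_thresh = score_thresh)
  evaluate_predictions(preds, scenes)
}

#' Predict detections and masks for a list of scenes
#'
#' @inheritParams evaluate
#' @return list per scene of `dets` (data.frame) and `mask` (probability
#'   matrix).
#' @export
predict_scenes <- function(model, scenes, batch_size = 8L, max_det = 50L,
                           score_thresh = 0.05) {
  n <- length(scenes)
  preds <- vector("list", n)
  s <- model$config$output_stride
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    imgs <- array(unlist(lapply(scenes[idx], `[[`, "image")),
                  dim = c(dim(scenes[[idx[1]]]$image), 1L, length(idx)))
    pm <- model_forward(model, imgs)
    for (k in seq_along(idx)) {
      hm <- pm$heatmap_logits[, , 1, k]
      sm <- array(pm$size_map[, , , k], dim = dim(pm$size_map)[1:3])
      dets <- decode_detections(list(heatmap_logits = hm, size_map = sm, stride = s),
                                max_det = max_det, score_thresh = score_thresh)
      segp <- 1 / (1 + exp(-pm$seg_logits[, , 1, k]))
      preds[[idx[k]]] <- list(dets = dets, mask = segp)
    }
  }
  preds
}
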