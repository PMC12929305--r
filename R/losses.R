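#' Penalty-reduced keypoint focal loss
#'
#' For cells where the target heatmap equals 1 the loss is
#' `-(1-p)^2 log p`; elsewhere `-(1-t)^4 p^2 log(1-p)` where `t` is the
#' Gaussian-splatted target, down-weighting easy negatives near peaks. The
#' sum is normalized by the number of center cells (minimum 1).
#'
#' @param pred heatmap probabilities in (0,1) (clamped at `eps`), same shape
#'   as `target$heatmap`.
#' @param target a `target_maps` object (or a plain matrix heatmap).
#' @param eps probability clamp, default 1e-6.
#' @return scalar loss (>= 0).
#' @export
focal_loss <- function(pred, target, eps = 1e-6) {
  t <- if (inherits(target, "target_maps")) target$heatmap else target
  if (!all(dim(pred) == dim(t))) stop("focal_loss: shape mismatch")
  if (any(!is.finite(pred))) stop("focal_loss: non-finite prediction")
  p <- pmin(pmax(pred, eps), 1 - eps)
  pos <- t >= 1
  npos <- max(1, sum(pos))
  lpos <- -(1 - p[pos])^2 * log(p[pos])
  lneg <- -(1 - t[!pos])^4 * p[!pos]^2 * log(1 - p[!pos])
  (sum(lpos) + sum(lneg)) / npos
}

#' L1 size-regression loss at electrode center cells
#'
#' Mean over center cells of `|w - w_hat| + |h - h_hat|`; 0 when the scene
#' has no electrodes.
#'
#' @param pred_sizes (h x w x 2) predicted size map on the stride grid.
#' @param target a `target_maps` object.
#' @return scalar loss.
#' @export
size_l1_loss <- function(pred_sizes, target) {
  if (!all(dim(pred_sizes)[1:2] == dim(target$heatmap))) {
    stop("size_l1_loss: shape mismatch")
  }
  cells <- unique(target$center_index_list)
  if (is.null(cells) || nrow(cells) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(cells))) {
    cx <- cells[i, 1] + 1L; cy <- cells[i, 2] + 1L
    tot <- tot + sum(abs(pred_sizes[cy, cx, ] - target$size_map[cy, cx, ]))
  }
  tot / nrow(cells)
}

#' Pixel-wise binary cross-entropy on segmentation logits
#'
#' @param logits real-valued H x W logits.
#' @param mask binary H x W ground truth.
#' @return mean per-pixel cross-entropy.
#' @export
bce_loss <- function(logits, mask) {
  if (!all(dim(logits) == dim(mask))) stop("bce_loss: shape mismatch")
  z <- logits; m <- mask
  mean(pmax(z, 0) - z * m + log1p(exp(-abs(z))))
}

#' Soft IoU segmentation loss
#'
#' `1 - (sum(p*m) + eps) / (sum(p) + sum(m) - sum(p*m) + eps)` with `eps = 1`
#' so empty-vs-empty is a perfect 0 loss.
#'
#' @param probs H x W probabilities in [0,1].
#' @param mask binary H x W ground truth.
#' @param eps smoothing constant, default 1.
#' @return loss in [0, 1].
#' @export
iou_loss <- function(probs, mask, eps = 1) {
  if (!all(dim(probs) == dim(mask))) stop("iou_loss: shape mismatch")
  i <- sum(probs * mask)
  u <- sum(probs) + sum(mask) - i
  1 - (i + eps) / (u + eps)
}

#' Availability/priority-masked task loss
#'
#' `(1/N) * sum_i delta_i * L_i` with `N` the batch size — the literal
#' batch-normalized form; `normalize = "selected"` divides by `sum(delta)`
#' instead.
#'
#' @param per_sample_losses numeric vector of per-sample losses.
#' @param delta availability/priority weights in [0, 1], same length.
#' @param normalize `"batch"` (default, divide by N) or `"selected"`.
#' @return scalar masked loss.
#' @export
masked_task_loss <- function(per_sample_losses, delta, normalize = c("batch", "selected")) {
  normalize <- match.arg(normalize)
  if (length(per_sample_losses) != length(delta)) {
    stop("masked_task_loss: length mismatch")
  }
  s <- sum(delta * per_sample_losses)
  if (normalize == "batch") {
    s / length(per_sample_losses)
  } else {
    if (sum(delta) == 0) 0 else s / sum(delta)
  }
}

# ---- batched value+gradient forms used by the trainer ---------------------
# All operate on (h, w, 1|2, N) logit/size arrays; targets are lists per
# sample. Values match the exported single-sample losses; gradients are the
# exact analytic derivatives of those formulas.

.sigmoid <- function(z) 1 / (1 + exp(-z))

# z: (h,w,1,N) heatmap logits; theat: (h,w,N) array of Gaussian targets
.focal_vg <- function(z, theat, eps = 1e-6) {
  d <- dim(z)
  N <- d[4]
  p <- .sigmoid(z)
  p <- pmin(pmax(p, eps), 1 - eps)
  value <- numeric(N)
  grad <- array(0, dim = d)
  for (n in seq_len(N)) {
    pn <- p[, , 1, n]
    tn <- theat[, , n]
    pos <- tn >= 1
    npos <- max(1, sum(pos))
    lp <- -(1 - pn[pos])^2 * log(pn[pos])
    ln <- -(1 - tn[!pos])^4 * pn[!pos]^2 * log(1 - pn[!pos])
    value[n] <- (sum(lp) + sum(ln)) / npos
    g <- matrix(0, d[1], d[2])
    # d/dp then chain through the sigmoid: dp/dz = p (1 - p)
    g[pos] <- 2 * (1 - pn[pos]) * log(pn[pos]) - (1 - pn[pos])^2 / pn[pos]
    g[!pos] <- -(1 - tn[!pos])^4 *
      (2 * pn[!pos] * log(1 - pn[!pos]) - pn[!pos]^2 / (1 - pn[!pos]))
    grad[, , 1, n] <- g * pn * (1 - pn) / npos
  }
  list(value = value, grad = grad)
}

# size_pred: (h,w,2,N); targets: list of target_maps per sample
.size_vg <- function(size_pred, targets) {
  d <- dim(size_pred)
  N <- d[4]
  value <- numeric(N)
  grad <- array(0, dim = d)
  for (n in seq_len(N)) {
    tg <- targets[[n]]
    cells <- unique(tg$center_index_list)
    if (is.null(cells) || nrow(cells) == 0L) next
    tot <- 0
    for (i in seq_len(nrow(cells))) {
      cx <- cells[i, 1] + 1L; cy <- cells[i, 2] + 1L
      dlt <- size_pred[cy, cx, , n] - tg$size_map[cy, cx, ]
      tot <- tot + sum(abs(dlt))
      grad[cy, cx, , n] <- sign(dlt) / nrow(cells)
    }
    value[n] <- tot / nrow(cells)
  }
  list(value = value, grad = grad)
}

# z: (H,W,1,N) segmentation logits; masks: (H,W,N)
.bce_vg <- function(z, masks) {
  d <- dim(z)
  npix <- d[1] * d[2]
  m <- array(masks, dim = d)
  val <- pmax(z, 0) - z * m + log1p(exp(-abs(z)))
  value <- colSums(matrix(val, npix, d[4]))  / npix
  grad <- (.sigmoid(z) - m) / npix
  list(value = value, grad = grad)
}

.iou_vg <- function(z, masks, eps = 1) {
  d <- dim(z)
  N <- d[4]
  p <- .sigmoid(z)
  value <- numeric(N)
  grad <- array(0, dim = d)
  for (n in seq_len(N)) {
    pn <- p[, , 1, n]
    mn <- masks[, , n]
    i <- sum(pn * mn)
    u <- sum(pn) + sum(mn) - i
    value[n] <- 1 - (i + eps) / (u + eps)
    dldp <- -(mn * (u + eps) - (i + eps) * (1 - mn)) / (u + eps)^2
    grad[, , 1, n] <- dldp * pn * (1 - pn)
  }
  list(value = value, grad = grad)
}
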