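#' Create the dynamic resource prioritization state
#'
#' Tracks per-task key performance indicators (KPIs) smoothed by an
#' exponential moving average (EMA), per-sample smoothed KPIs whose inverses
#' are the sample difficulties, the iteration counter, and the top-k
#' selection schedule. Task difficulty is `1 / kappa_bar_t`, so tasks (and
#' samples) performing poorly receive more training resource.
#'
#' @param alpha EMA discount in [0, 1]; larger values weight recent
#'   iterations more. Default 0.9.
#' @param k_schedule list with `start`, `end` (fractions, 0 < end <= start
#'   <= 1) and `total` iterations; the retained-sample fraction interpolates
#'   linearly from `start` to `end` (default 0.7 -> 0.3).
#' @param assignment_mode one of `"topk_hard"`, `"topk_soft"`, `"soft"`,
#'   `"hard"` (see [sample_deltas()]).
#' @param eta threshold for the `"hard"` binarization mode, default 0.5.
#' @param kpi_metric_d detection KPI metric: `"mae"` or `"rmse"`.
#' @param kpi_metric_s segmentation KPI metric: `"iou"` or `"dice"`.
#' @return a `priority_state` list; task EMAs start at 1 so the first
#'   iteration's total loss is the plain unweighted sum.
#' @export
priority_state <- function(alpha = 0.9,
                           k_schedule = list(start = 0.7, end = 0.3, total = 1000L),
                           assignment_mode = c("topk_hard", "topk_soft", "soft", "hard"),
                           eta = 0.5,
                           kpi_metric_d = c("mae", "rmse"),
                           kpi_metric_s = c("iou", "dice")) {
  stopifnot(alpha >= 0, alpha <= 1)
  stopifnot(k_schedule$end > 0, k_schedule$end <= k_schedule$start,
            k_schedule$start <= 1, k_schedule$total >= 1)
  structure(list(kappa_bar = c(d = 1, s = 1),
                 alpha = alpha,
                 tau = 0L,
                 sample_kappa = list(d = numeric(0), s = numeric(0)),
                 k_schedule = k_schedule,
                 assignment_mode = match.arg(assignment_mode),
                 eta = eta,
                 kpi_metric_d = match.arg(kpi_metric_d),
                 kpi_metric_s = match.arg(kpi_metric_s)),
            class = "priority_state")
}

#' Detection KPI: clamped inverse mean localization error
#'
#' Predicted and ground-truth electrode centers are matched one-to-one by
#' minimum-cost assignment on the pairwise Euclidean distances (exact,
#' via [solve_assignment()]); unmatched ground truths and spurious
#' predictions each contribute a fixed `penalty` distance. The KPI is
#' `min(1, 1 / max(MAE, 1))`, keeping the inverse-error relation while
#' staying in (0, 1].
#'
#' @param pred_centers n_p x 2 matrix of predicted (x, y) centers (possibly
#'   0 rows).
#' @param gt_centers n_g x 2 matrix of ground-truth centers; must be
#'   non-empty (callers skip unavailable samples).
#' @param penalty distance charged per unmatched point; defaults to
#'   `diag(image)/8` when `image_size` is given.
#' @param image_size optional (H, W) used to derive the default penalty.
#' @param metric `"mae"` (mean distance) or `"rmse"` (root mean squared).
#' @return the KPI, a scalar in (0, 1].
#' @seealso [matching_error()] for the underlying localization error.
#' @export
kpi_detection <- function(pred_centers, gt_centers, penalty = NULL,
                          image_size = NULL, metric = c("mae", "rmse")) {
  err <- matching_error(pred_centers, gt_centers, penalty, image_size, metric)
  min(1, 1 / max(err, 1))
}

#' Mean localization error under optimal one-to-one matching
#'
#' @inheritParams kpi_detection
#' @return MAE (or RMSE) in pixels, including per-point penalties for
#'   unmatched ground truths and spurious predictions.
#' @export
matching_error <- function(pred_centers, gt_centers, penalty = NULL,
                           image_size = NULL, metric = c("mae", "rmse")) {
  metric <- match.arg(metric)
  gt_centers <- matrix(as.numeric(gt_centers), ncol = 2)
  pred_centers <- if (length(pred_centers)) matrix(as.numeric(pred_centers), ncol = 2)
  else matrix(numeric(0), 0, 2)
  ng <- nrow(gt_centers); np <- nrow(pred_centers)
  if (ng == 0L) stop("kpi_detection: ground truth is empty (skip this sample)")
  if (is.null(penalty)) {
    if (is.null(image_size)) {
      if (np != ng) stop("kpi_detection: penalty (or image_size) needed when counts differ")
      penalty <- Inf # unused
    } else {
      penalty <- sqrt(sum(as.numeric(image_size)^2)) / 8
    }
  }
  m <- max(np, ng)
  cost <- matrix(if (is.finite(penalty)) penalty else 0, m, m)
  if (np > 0) {
    d <- sqrt(outer(pred_centers[, 1], gt_centers[, 1], `-`)^2 +
                outer(pred_centers[, 2], gt_centers[, 2], `-`)^2)
    cost[seq_len(np), seq_len(ng)] <- if (metric == "mae") d else d^2
  }
  if (metric == "rmse" && is.finite(penalty)) {
    if (np < m) cost[(np + 1):m, ] <- penalty^2
    if (ng < m) cost[, (ng + 1):m] <- penalty^2
  }
  sol <- solve_assignment(cost)
  if (metric == "mae") sol$cost / m else sqrt(sol$cost / m)
}

#' Segmentation KPI: smoothed intersection-over-union (or Dice)
#'
#' @param pred_mask binary (or probability, thresholded at 0.5) grid.
#' @param gt_mask binary ground-truth grid.
#' @param metric `"iou"` or `"dice"`.
#' @param eps smoothing constant (default 1): two empty masks score 1.
#' @return KPI in [0, 1].
#' @export
kpi_segmentation <- function(pred_mask, gt_mask, metric = c("iou", "dice"), eps = 1) {
  metric <- match.arg(metric)
  if (!all(dim(pred_mask) == dim(gt_mask))) stop("kpi_segmentation: shape mismatch")
  p <- as.numeric(pred_mask >= 0.5)
  m <- as.numeric(gt_mask >= 0.5)
  i <- sum(p * m)
  if (metric == "iou") {
    (i + eps) / (sum(p) + sum(m) - i + eps)
  } else {
    (2 * i + eps) / (sum(p) + sum(m) + eps)
  }
}

#' Exponential moving average update of a KPI
#'
#' `kappa_bar <- alpha * kappa + (1 - alpha) * kappa_bar_prev`, clamped to
#' `[1e-3, 1]` so inverse-KPI task weights stay finite.
#'
#' @param kappa_bar_prev previous smoothed KPI in [0, 1].
#' @param kappa new KPI observation in [0, 1].
#' @param alpha discount factor in [0, 1]; `alpha = 1` keeps only the newest
#'   observation, `alpha = 0` ignores it.
#' @return updated smoothed KPI in (0, 1].
#' @export
ema_update <- function(kappa_bar_prev, kappa, alpha) {
  if (alpha < 0 || alpha > 1) stop("ema_update: alpha outside [0, 1]")
  stopifnot(kappa >= 0, kappa <= 1, kappa_bar_prev >= 0, kappa_bar_prev <= 1)
  v <- alpha * kappa + (1 - alpha) * kappa_bar_prev
  min(1, max(1e-3, v))
}

#' Current retained-sample fraction of the top-k schedule
#'
#' Linear interpolation from the schedule's start fraction to its end
#' fraction over `total` iterations, constant thereafter.
#'
#' @param state a `priority_state`.
#' @return fraction in (0, 1].
#' @export
current_k_fraction <- function(state) {
  ks <- state$k_schedule
  frac <- min(1, state$tau / ks$total)
  ks$start + (ks$end - ks$start) * frac
}

#' Per-sample priority weights from difficulties
#'
#' `K = ceiling(k_fraction * n)` samples are retained. Modes:
#' `"topk_hard"` gives weight 1 to the K most difficult samples and 0
#' otherwise; `"topk_soft"` gives `difficulty / max(difficulty)` inside the
#' top-K set and 0 outside; `"soft"` weights every sample by
#' `difficulty / max(difficulty)`; `"hard"` binarizes the soft weight at
#' `eta`. Ties at the K-th rank break toward the lower sample index.
#'
#' @param difficulties positive per-sample difficulties.
#' @param k_fraction fraction in (0, 1] of samples to retain.
#' @param mode assignment mode (see above).
#' @param eta binarization threshold for `"hard"`, default 0.5.
#' @return numeric weights delta in [0, 1], one per sample.
#' @export
sample_deltas <- function(difficulties, k_fraction,
                          mode = c("topk_hard", "topk_soft", "soft", "hard"),
                          eta = 0.5) {
  mode <- match.arg(mode)
  n <- length(difficulties)
  if (n == 0L) stop("sample_deltas: empty difficulty list")
  stopifnot(all(difficulties > 0), k_fraction > 0, k_fraction <= 1)
  soft <- difficulties / max(difficulties)
  if (mode == "soft") return(soft)
  if (mode == "hard") return(as.numeric(soft > eta))
  k <- as.integer(ceiling(k_fraction * n))
  ord <- order(-difficulties, seq_len(n))
  topk <- ord[seq_len(k)]
  delta <- numeric(n)
  delta[topk] <- if (mode == "topk_hard") 1 else soft[topk]
  delta
}

#' Inverse-KPI weighted multi-task total loss
#'
#' `L_total = L_d / kappa_bar_d + L_s / kappa_bar_s`; with both smoothed
#' KPIs at 1 this is the plain sum of task losses.
#'
#' @param l_d,l_s masked detection / segmentation task losses.
#' @param kappa_bar_d,kappa_bar_s smoothed task KPIs in (0, 1].
#' @return scalar total loss.
#' @export
total_loss <- function(l_d, l_s, kappa_bar_d, kappa_bar_s) {
  if (kappa_bar_d <= 0 || kappa_bar_s <= 0) stop("total_loss: nonpositive kappa_bar")
  stopifnot(kappa_bar_d <= 1, kappa_bar_s <= 1)
  l_d / kappa_bar_d + l_s / kappa_bar_s
}

#' Difficulties of a set of samples for one task
#'
#' `1 / kappa_bar_{t,i}` from the per-sample EMA; samples never seen before
#' default to difficulty 2 (smoothed KPI 0.5), neither favoured nor dropped.
#'
#' @param state a `priority_state`.
#' @param task `"d"` or `"s"`.
#' @param ids character sample ids.
#' @return positive difficulty vector.
#' @export
sample_difficulties <- function(state, task, ids) {
  kap <- state$sample_kappa[[task]]
  k <- kap[ids]
  k[is.na(k)] <- 0.5
  unname(1 / k)
}

#' Advance the prioritization state with a batch of KPI observations
#'
#' Per-task smoothed KPIs are EMA-updated with the batch mean KPI; each
#' sample's own smoothed KPI is EMA-updated with its KPI (momentum update of
#' the difficulty trajectory); the iteration counter advances by one.
#'
#' @param state a `priority_state`.
#' @param batch_kpis list with elements `d` and/or `s`, each a *named*
#'   numeric vector of per-sample KPIs in [0, 1] (names are sample ids).
#' @return the updated `priority_state`.
#' @export
update_state <- function(state, batch_kpis) {
  for (task in intersect(names(batch_kpis), c("d", "s"))) {
    k <- batch_kpis[[task]]
    if (length(k) == 0L) next
    if (any(k < 0 | k > 1)) stop("update_state: KPI outside [0, 1]")
    state$kappa_bar[[task]] <- ema_update(state$kappa_bar[[task]], mean(k), state$alpha)
    kap <- state$sample_kappa[[task]]
    for (id in names(k)) {
      prev <- if (id %in% names(kap)) kap[[id]] else 0.5
      kap[[id]] <- ema_update(prev, k[[id]], state$alpha)
    }
    state$sample_kappa[[task]] <- kap
  }
  state$tau <- state$tau + 1L
  state
}
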