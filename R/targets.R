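#' CenterNet-style Gaussian radius for a minimum box overlap
#'
#' Smallest Gaussian radius such that a box displaced by that radius still
#' overlaps the ground-truth box with IoU at least `min_overlap`; minimum of
#' the three quadratic-case roots.
#'
#' @param height,width box extent on the target grid (stride cells).
#' @param min_overlap required IoU (default 0.7).
#' @return positive radius in cells.
#' @export
gaussian_radius <- function(height, width, min_overlap = 0.7) {
  a1 <- 1; b1 <- height + width
  c1 <- width * height * (1 - min_overlap) / (1 + min_overlap)
  r1 <- (b1 - sqrt(b1^2 - 4 * a1 * c1)) / (2 * a1)
  a2 <- 4; b2 <- 2 * (height + width)
  c2 <- (1 - min_overlap) * width * height
  r2 <- (b2 - sqrt(b2^2 - 4 * a2 * c2)) / (2 * a2)
  a3 <- 4 * min_overlap
  b3 <- -2 * min_overlap * (height + width)
  c3 <- (min_overlap - 1) * width * height
  r3 <- (-b3 + sqrt(b3^2 - 4 * a3 * c3)) / (2 * a3)
  min(r1, r2, r3)
}

#' Render detection training targets from scene annotations
#'
#' Each electrode contributes an unnormalized Gaussian splat
#' `exp(-(dx^2 + dy^2) / (2 sigma^2))` on the stride-reduced heatmap, centred
#' at `floor(center / stride)`; overlapping splats are merged by elementwise
#' max so every electrode's own center cell is exactly 1. `sigma = radius/3`
#' with the radius from [gaussian_radius()] at min overlap 0.7 (box extent on
#' the stride grid), floored at 1 cell. The size map holds the (w, h) box
#' extent in input pixels at each center cell; when two electrodes land in
#' the same cell the later one wins (documented tie rule).
#'
#' @param scene an `annotated_scene`.
#' @param stride output stride (must divide both image dimensions).
#' @return a `target_maps` list: `heatmap` (h/s x w/s matrix in [0,1]),
#'   `size_map` (h/s x w/s x 2 array), `center_index_list` (n x 2 matrix of
#'   0-based stride-grid (x, y) cells, one row per electrode), `stride`.
#' @export
render_targets <- function(scene, stride = 4L) {
  stride <- as.integer(stride)
  h <- nrow(scene$image); w <- ncol(scene$image)
  if (h %% stride != 0L || w %% stride != 0L) {
    stop("stride must divide both image dimensions")
  }
  hs <- h %/% stride; ws <- w %/% stride
  heat <- matrix(0, hs, ws)
  size_map <- array(0, dim = c(hs, ws, 2L))
  n <- nrow(scene$electrodes)
  centers <- matrix(0L, n, 2L, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n)) {
    cx <- floor(scene$electrodes[i, 1] / stride)
    cy <- floor(scene$electrodes[i, 2] / stride)
    if (cx < 0 || cx >= ws || cy < 0 || cy >= hs) {
      stop("electrode maps outside the stride grid")
    }
    centers[i, ] <- c(cx, cy)
    bw <- scene$sizes[i, 1] / stride
    bh <- scene$sizes[i, 2] / stride
    radius <- max(1, gaussian_radius(bh, bw, 0.7))
    sigma <- radius / 3
    r <- ceiling(3 * sigma)
    xs <- max(0L, cx - r):min(ws - 1L, cx + r)
    ys <- max(0L, cy - r):min(hs - 1L, cy + r)
    splat <- exp(-(outer((ys - cy)^2, (xs - cx)^2, `+`)) / (2 * sigma^2))
    sub <- heat[ys + 1L, xs + 1L, drop = FALSE]
    heat[ys + 1L, xs + 1L] <- pmax(sub, splat)
    size_map[cy + 1L, cx + 1L, ] <- scene$sizes[i, ]
  }
  structure(list(heatmap = heat, size_map = size_map,
                 center_index_list = centers, stride = stride),
            class = "target_maps")
}
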