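#' Specification of a synthetic fluoroscopy scene family
#'
#' Describes the generative conditions for fluoroscopy-like test scenes: dark
#' curved catheter bodies carrying radio-opaque electrode blobs, wire-like
#' distractor curves that are drawn but never labelled (emulating unlabelled
#' ECG leads / sternal wires), smooth background texture, additive Gaussian
#' noise and optional collimation borders.
#'
#' @param image_size integer pair (H, W), both >= 64.
#' @param n_catheters number of labelled target catheters (>= 1).
#' @param electrodes_per_catheter inclusive integer range (lo, hi) of
#'   electrodes placed along each catheter.
#' @param electrode_radius_px positive real range (lo, hi) for electrode
#'   blob semi-axes, in pixels.
#' @param n_distractors number of unlabelled wire-like curves (>= 0).
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#'   (image scale is [0, 1]).
#' @param collimation if `TRUE`, scenes may receive dark collimator shutter
#'   borders (drawn in the image only, never in the mask).
#' @param seed integer RNG seed; together with the scene index it fully
#'   determines a scene.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(256L, 256L),
                       n_catheters = 1L,
                       electrodes_per_catheter = c(4L, 10L),
                       electrode_radius_px = c(2, 4),
                       n_distractors = 2L,
                       noise_sigma = 0.02,
                       collimation = FALSE,
                       seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 64L))
  stopifnot(n_catheters >= 1L, n_distractors >= 0L, noise_sigma >= 0)
  electrodes_per_catheter <- as.integer(electrodes_per_catheter)
  stopifnot(length(electrodes_per_catheter) == 2L,
            electrodes_per_catheter[1] >= 1L,
            electrodes_per_catheter[2] >= electrodes_per_catheter[1])
  stopifnot(length(electrode_radius_px) == 2L,
            electrode_radius_px[1] > 0,
            electrode_radius_px[2] >= electrode_radius_px[1])
  if (2 * ceiling(electrode_radius_px[2]) + 4 >= min(image_size)) {
    stop("electrode blobs cannot fit inside the image")
  }
  structure(list(image_size = image_size,
                 n_catheters = as.integer(n_catheters),
                 electrodes_per_catheter = electrodes_per_catheter,
                 electrode_radius_px = as.numeric(electrode_radius_px),
                 n_distractors = as.integer(n_distractors),
                 noise_sigma = as.numeric(noise_sigma),
                 collimation = isTRUE(collimation),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# run code under a deterministic local RNG without disturbing the caller's
.with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.scene_seed <- function(seed, index) {
  as.integer((as.double(seed %% 1000003L) * 2011L + as.double(index) * 7919L) %% 2147483629)
}

# smooth low-frequency background field in [-1, 1] via a coarse grid blown up
# with bilinear interpolation
.smooth_field <- function(h, w, cells = 6L) {
  g <- matrix(stats::runif((cells + 2L)^2, -1, 1), cells + 2L)
  ys <- seq(1, cells + 2L, length.out = h)
  xs <- seq(1, cells + 2L, length.out = w)
  y0 <- pmin(floor(ys), cells + 1L); x0 <- pmin(floor(xs), cells + 1L)
  ay <- ys - y0; ax <- xs - x0
  m00 <- g[cbind(rep(y0, w), rep(x0, each = h))]
  m10 <- g[cbind(rep(y0 + 1L, w), rep(x0, each = h))]
  m01 <- g[cbind(rep(y0, w), rep(x0 + 1L, each = h))]
  m11 <- g[cbind(rep(y0 + 1L, w), rep(x0 + 1L, each = h))]
  a <- rep(ay, w); b <- rep(ax, each = h)
  matrix((1 - a) * (1 - b) * m00 + a * (1 - b) * m10 +
           (1 - a) * b * m01 + a * b * m11, h, w)
}

# sample a smooth open curve through k random control points; returns densely
# sampled (x, y) in 0-based pixel coordinates
.random_curve <- function(h, w, margin, k = 5L) {
  cx <- stats::runif(k, margin, w - 1 - margin)
  cy <- stats::runif(k, margin, h - 1 - margin)
  tt <- seq_len(k)
  fx <- stats::splinefun(tt, cx, method = "natural")
  fy <- stats::splinefun(tt, cy, method = "natural")
  ts <- seq(1, k, length.out = 6L * max(h, w) %/% 2L)
  list(x = fx(ts), y = fy(ts))
}

# paint all pixels within `radius` of any curve sample; returns logical matrix
.paint_curve <- function(h, w, curve, radius) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, , drop = FALSE]
  px <- round(curve$x); py <- round(curve$y)
  keep <- !duplicated(cbind(px, py))
  px <- px[keep]; py <- py[keep]
  xx <- outer(px, off$dx, `+`); yy <- outer(py, off$dy, `+`)
  ok <- xx >= 0 & xx < w & yy >= 0 & yy < h
  idx <- (yy[ok] + 1L) + h * xx[ok]
  m <- matrix(FALSE, h, w)
  m[unique(idx)] <- TRUE
  m
}

# paint a rotated ellipse; returns logical matrix over the full image
.paint_ellipse <- function(h, w, cx, cy, a, b, theta) {
  r <- ceiling(max(a, b))
  xs <- max(0, floor(cx) - r - 1L):min(w - 1, ceiling(cx) + r + 1L)
  ys <- max(0, floor(cy) - r - 1L):min(h - 1, ceiling(cy) + r + 1L)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m <- matrix(FALSE, h, w)
  m[ys + 1L, xs + 1L][inside] <- TRUE
  m
}

#' Generate one annotated synthetic fluoroscopy scene
#'
#' Deterministic in `(spec$seed, index)`: the same pair always produces a
#' bit-identical scene. The target catheter(s) are smooth random spline curves
#' of 2-4 px width rendered dark on a textured bright background, with
#' elliptical electrode blobs centred on the curve; distractor curves are
#' drawn in the image but never enter the mask. Pixel values are quantized to
#' the 8-bit grid so PNG round-trips are exact.
#'
#' @param spec a [scene_spec()].
#' @param index non-negative scene index.
#' @param keep_layers if `TRUE`, attach the painted target/distractor pixel
#'   sets as attribute `"layers"` (construction bookkeeping for testing).
#' @return an `annotated_scene`: list with `image` (H x W matrix in [0,1]),
#'   `mask` (H x W 0/1 integer matrix), `electrodes` (n x 2 matrix of 0-based
#'   (x, y) centers, x = column), `sizes` (n x 2 matrix of (w, h) bounding-box
#'   extents in pixels) and `scene_id`.
#' @export
generate_scene <- function(spec, index, keep_layers = FALSE) {
  stopifnot(inherits(spec, "scene_spec"), index >= 0)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  .with_local_seed(.scene_seed(spec$seed, index), {
    base <- stats::runif(1, 0.72, 0.88)
    img <- base + 0.05 * .smooth_field(h, w) + 0.03 * .smooth_field(h, w, cells = 12L)
    mask <- matrix(FALSE, h, w)
    target_px <- matrix(FALSE, h, w)
    margin <- max(6, round(0.1 * min(h, w)))
    electrodes <- NULL
    sizes <- NULL
    for (ci in seq_len(spec$n_catheters)) {
      ne <- if (spec$electrodes_per_catheter[1] == spec$electrodes_per_catheter[2]) {
        spec$electrodes_per_catheter[1]
      } else {
        sample(spec$electrodes_per_catheter[1]:spec$electrodes_per_catheter[2], 1L)
      }
      # find a curve offering enough interior points for the electrodes
      for (attempt in 1:25) {
        curve <- .random_curve(h, w, margin)
        interior <- which(curve$x >= margin & curve$x <= w - 1 - margin &
                            curve$y >= margin & curve$y <= h - 1 - margin)
        if (length(interior) >= ne * 40L) break
      }
      width <- stats::runif(1, 2, 4)
      body <- .paint_curve(h, w, curve, width / 2)
      shade <- stats::runif(1, 0.25, 0.4)
      img[body] <- shade + 0.05 * stats::runif(sum(body), -1, 1)
      # electrodes at roughly equal spacing along the interior of the curve
      pos <- interior[round(seq(1, length(interior), length.out = ne + 2L))][2:(ne + 1L)]
      for (p in pos) {
        cx <- round(curve$x[p]); cy <- round(curve$y[p])
        a <- stats::runif(1, spec$electrode_radius_px[1], spec$electrode_radius_px[2])
        b <- stats::runif(1, spec$electrode_radius_px[1], min(a, spec$electrode_radius_px[2]))
        th <- atan2(curve$y[min(p + 5L, length(curve$y))] - curve$y[max(p - 5L, 1L)],
                    curve$x[min(p + 5L, length(curve$x))] - curve$x[max(p - 5L, 1L)])
        blob <- .paint_ellipse(h, w, cx, cy, a, b, th)
        blob[cy + 1L, cx + 1L] <- TRUE # center pixel always part of the blob
        img[blob] <- stats::runif(1, 0.04, 0.14)
        body <- body | blob
        bxs <- which(blob, arr.ind = TRUE)
        electrodes <- rbind(electrodes, c(cx, cy))
        sizes <- rbind(sizes, c(max(bxs[, 2]) - min(bxs[, 2]) + 1L,
                                max(bxs[, 1]) - min(bxs[, 1]) + 1L))
      }
      mask <- mask | body
      target_px <- target_px | body
    }
    distractor_px <- matrix(FALSE, h, w)
    for (di in seq_len(spec$n_distractors)) {
      curve <- .random_curve(h, w, margin = 2, k = 4L)
      dwidth <- stats::runif(1, 1, 2.5)
      dpx <- .paint_curve(h, w, curve, dwidth / 2)
      dpx <- dpx & !mask # target catheter occludes distractors
      img[dpx] <- stats::runif(1, 0.35, 0.55) + 0.05 * stats::runif(sum(dpx), -1, 1)
      distractor_px <- distractor_px | dpx
    }
    if (spec$collimation && stats::runif(1) < 0.5) {
      bw <- round(stats::runif(2, 0.02, 0.05) * c(h, w))
      sides <- sample(c(TRUE, FALSE), 4L, replace = TRUE)
      if (sides[1] && bw[1] > 0) img[seq_len(bw[1]), ] <- 0.1
      if (sides[2] && bw[1] > 0) img[(h - bw[1] + 1L):h, ] <- 0.1
      if (sides[3] && bw[2] > 0) img[, seq_len(bw[2])] <- 0.1
      if (sides[4] && bw[2] > 0) img[, (w - bw[2] + 1L):w] <- 0.1
    }
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(h * w, 0, spec$noise_sigma)
    }
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255
    sc <- structure(list(image = img,
                         mask = matrix(as.integer(mask), h, w),
                         electrodes = matrix(as.numeric(electrodes), ncol = 2,
                                             dimnames = list(NULL, c("x", "y"))),
                         sizes = matrix(as.numeric(sizes), ncol = 2,
                                        dimnames = list(NULL, c("w", "h"))),
                         scene_id = sprintf("scene_%05d", as.integer(index))),
                    class = "annotated_scene")
    if (keep_layers) {
      attr(sc, "layers") <- list(target = target_px, distractor = distractor_px)
    }
    sc
  })
}

#' @export
print.annotated_scene <- function(x, ...) {
  cat(sprintf("<annotated_scene %s: %dx%d, %d electrodes, %d mask px>\n",
              x$scene_id, nrow(x$image), ncol(x$image),
              nrow(x$electrodes), sum(x$mask)))
  invisible(x)
}

.validate_scene <- function(sc) {
  h <- nrow(sc$image); w <- ncol(sc$image)
  if (nrow(sc$electrodes) != nrow(sc$sizes)) {
    stop(sprintf("scene %s: electrodes/sizes length mismatch", sc$scene_id))
  }
  if (nrow(sc$electrodes) > 0) {
    ex <- sc$electrodes[, 1]; ey <- sc$electrodes[, 2]
    if (any(ex < 0 | ex > w - 1 | ey < 0 | ey > h - 1)) {
      stop(sprintf("scene %s: electrode center outside image bounds", sc$scene_id))
    }
  }
  invisible(sc)
}

#' Write an annotated scene dataset to disk
#'
#' Layout: `images/<id>.png` (8-bit grayscale), `masks/<id>.png` (0/255),
#' `annotations/<id>.json` and a top-level `manifest.json` listing all scenes.
#'
#' @param scenes list of `annotated_scene` objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly usable by [read_dataset()].
#' @export
write_dataset <- function(scenes, dir) {
  for (d in file.path(dir, c("images", "masks", "annotations"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  entries <- lapply(scenes, function(sc) {
    stopifnot(inherits(sc, "annotated_scene"))
    .validate_scene(sc)
    id <- sc$scene_id
    rel <- list(image = file.path("images", paste0(id, ".png")),
                mask = file.path("masks", paste0(id, ".png")),
                annotation = file.path("annotations", paste0(id, ".json")))
    png::writePNG(sc$image, file.path(dir, rel$image))
    png::writePNG(sc$mask + 0, file.path(dir, rel$mask))
    ann <- list(scene_id = id, image = rel$image, mask = rel$mask,
                electrodes = unname(split(sc$electrodes, row(sc$electrodes))),
                sizes = unname(split(sc$sizes, row(sc$sizes))))
    jsonlite::write_json(ann, file.path(dir, rel$annotation),
                         auto_unbox = TRUE, digits = NA)
    c(scene_id = id, rel)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n_scenes = length(entries), scenes = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read an annotated scene dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list of `annotated_scene` objects; invalid annotations (electrode
#'   centers outside the image) or missing files fail with the scene id named.
#' @export
read_dataset <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(manifest)
  lapply(mf$scenes, function(e) {
    id <- e$scene_id
    for (f in c(e$image, e$mask, e$annotation)) {
      if (!file.exists(file.path(dir, f))) {
        stop(sprintf("scene %s: missing file %s", id, f))
      }
    }
    img <- png::readPNG(file.path(dir, e$image))
    msk <- png::readPNG(file.path(dir, e$mask))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    ann <- jsonlite::read_json(file.path(dir, e$annotation), simplifyVector = FALSE)
    as_rows <- function(x, nms) {
      if (length(x) == 0L) {
        return(matrix(numeric(0), 0, 2, dimnames = list(NULL, nms)))
      }
      m <- do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
      dimnames(m) <- list(NULL, nms)
      m
    }
    el <- as_rows(ann$electrodes, c("x", "y"))
    sz <- as_rows(ann$sizes, c("w", "h"))
    sc <- structure(list(image = img,
                         mask = matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk)),
                         electrodes = el, sizes = sz, scene_id = id),
                    class = "annotated_scene")
    .validate_scene(sc)
  })
}

#' Generate a list of scenes from one spec
#'
#' @param spec a [scene_spec()].
#' @param n number of scenes; indices `offset + 0:(n-1)`.
#' @param offset starting index.
#' @export
generate_scenes <- function(spec, n, offset = 0L) {
  lapply(seq_len(n) - 1L + offset, function(i) generate_scene(spec, i))
}
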