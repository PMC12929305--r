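test_that("focal loss vanishes at exact targets and matches the closed form", {
  sc <- manual_scene(electrodes = rbind(c(20, 20)), sizes = rbind(c(5, 5)))
  tg <- render_targets(sc, 4)
  perfect <- ifelse(tg$heatmap >= 1, 1 - 1e-7, pmin(tg$heatmap, 1e-7))
  expect_lte(focal_loss(perfect, tg), 1e-4)

  # uniform 0.5 on a 2x2 map with one center: hand evaluation of both branches
  t22 <- matrix(c(1, 0, 0, 0), 2, 2)
  p22 <- matrix(0.5, 2, 2)
  hand <- (-(1 - 0.5)^2 * log(0.5)) + 3 * (-(1 - 0)^4 * 0.5^2 * log(0.5))
  expect_equal(focal_loss(p22, t22), hand, tolerance = 1e-12)

  # no centers, near-zero predictions
  expect_lte(focal_loss(matrix(1e-7, 4, 4), matrix(0, 4, 4)), 1e-4)
  expect_error(focal_loss(matrix(0.5, 2, 3), t22), "shape")
  expect_error(focal_loss(matrix(NaN, 2, 2), t22), "finite")
})

test_that("size L1 loss averages |dw| + |dh| over center cells", {
  sc <- manual_scene(electrodes = rbind(c(20, 20)), sizes = rbind(c(6, 4)))
  tg <- render_targets(sc, 4)
  pred <- tg$size_map
  expect_equal(size_l1_loss(pred, tg), 0)
  pred[5 + 1, 5 + 1, ] <- c(8, 5) # |8-6| + |5-4| = 3
  expect_equal(size_l1_loss(pred, tg), 3.0)
  none <- manual_scene(electrodes = matrix(numeric(0), 0, 2),
                       sizes = matrix(numeric(0), 0, 2))
  tg0 <- render_targets(none, 4)
  expect_equal(size_l1_loss(array(1, c(16, 16, 2)), tg0), 0)
})

test_that("IoU loss hits its degenerate and disjoint limits", {
  m <- matrix(0, 10, 10); m[1:5, 1:10] <- 1 # 50 ones
  expect_lte(iou_loss(m, m), 1e-3)
  expect_gte(iou_loss(1 - m, m), 0.98) # 1 - 1/101
  expect_equal(iou_loss(1 - m, m), 1 - 1 / 101, tolerance = 1e-12)
  z <- matrix(0, 4, 4)
  expect_equal(iou_loss(z, z), 0)
  expect_error(iou_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("BCE loss matches direct computation and masked task loss is Eq-literal", {
  set.seed(1)
  z <- matrix(rnorm(25), 5, 5)
  m <- matrix(rbinom(25, 1, 0.4), 5, 5)
  p <- 1 / (1 + exp(-z))
  expect_equal(bce_loss(z, m), -mean(m * log(p) + (1 - m) * log(1 - p)),
               tolerance = 1e-10)
  expect_equal(masked_task_loss(c(2, 4), c(1, 1)), 3.0)
  expect_equal(masked_task_loss(c(2, 4), c(0, 1)), 2.0) # divides by N, not sum(delta)
  expect_equal(masked_task_loss(c(2, 4), c(0, 1), normalize = "selected"), 4.0)
  expect_equal(masked_task_loss(c(2, 4), c(0, 0)), 0)
  expect_error(masked_task_loss(c(1, 2), c(1)), "length")
})

test_that("moving predictions toward the target never increases focal or IoU loss", {
  set.seed(42)
  for (rep in 1:20) {
    sc <- generate_scene(small_spec(seed = 100 + rep), rep)
    tg <- render_targets(sc, 4)
    pred <- matrix(runif(length(tg$heatmap)), nrow(tg$heatmap))
    ideal <- ifelse(tg$heatmap >= 1, 1, 0)
    closer <- pred + 0.5 * (ideal - pred)
    expect_lte(focal_loss(closer, tg), focal_loss(pred, tg) + 1e-12)
    pm <- matrix(runif(length(sc$mask)), nrow(sc$mask))
    pm_closer <- pm + 0.5 * (sc$mask - pm)
    expect_lte(iou_loss(pm_closer, sc$mask), iou_loss(pm, sc$mask) + 1e-12)
    expect_gte(focal_loss(pred, tg), 0)
    expect_true(iou_loss(pm, sc$mask) >= 0 && iou_loss(pm, sc$mask) <= 1)
  }
})

test_that("batched loss gradients agree with finite differences", {
  set.seed(7)
  h <- 8; N <- 2
  sc1 <- manual_scene(h = 32, w = 32, electrodes = rbind(c(10, 12), c(20, 8)),
                      sizes = rbind(c(4, 4), c(6, 5)))
  sc2 <- manual_scene(h = 32, w = 32, electrodes = rbind(c(16, 16)),
                      sizes = rbind(c(5, 5)))
  tgs <- lapply(list(sc1, sc2), render_targets, stride = 4)
  theat <- array(unlist(lapply(tgs, `[[`, "heatmap")), dim = c(8, 8, N))
  z <- array(rnorm(8 * 8 * N), dim = c(8, 8, 1, N))
  masks <- array(rbinom(32 * 32 * N, 1, 0.3), dim = c(32, 32, N))
  zs <- array(rnorm(32 * 32 * N, sd = 0.5), dim = c(32, 32, 1, N))
  sz <- array(rnorm(8 * 8 * 2 * N, mean = 4), dim = c(8, 8, 2, N))

  fd_check <- function(vg, x, ...) {
    r <- vg(x, ...)
    for (k in 1:5) {
      i <- sample(length(x), 1)
      eps <- 1e-5
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (sum(vg(xp, ...)$value) - sum(vg(xm, ...)$value)) / (2 * eps)
      expect_equal(r$grad[i], fd, tolerance = 1e-4)
    }
  }
  fd_check(cathmtl:::.focal_vg, z, theat)
  fd_check(cathmtl:::.bce_vg, zs, masks)
  fd_check(cathmtl:::.iou_vg, zs, masks)
  # size L1 is piecewise linear; check at a non-kink point
  r <- cathmtl:::.size_vg(sz, tgs)
  cell <- tgs[[2]]$center_index_list[1, ]
  i <- which(slice.index(sz, 4) == 2 &
               slice.index(sz, 1) == cell["y"] + 1 &
               slice.index(sz, 2) == cell["x"] + 1 &
               slice.index(sz, 3) == 1)
  eps <- 1e-5
  szp <- sz; szp[i] <- szp[i] + eps
  fd <- (sum(cathmtl:::.size_vg(szp, tgs)$value) - sum(r$value)) / eps
  expect_equal(r$grad[i], fd, tolerance = 1e-4)
})
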