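test_that("decoding places centers at (cell + 0.5) * stride and breaks plateaus by raster order", {
  hm <- matrix(-20, 16, 16)
  hm[10 + 1, 5 + 1] <- 20 # cell row 10, col 5
  sm <- array(0, dim = c(16, 16, 2)); sm[10 + 1, 5 + 1, ] <- c(6, 4)
  d <- decode_detections(list(heatmap_logits = hm, size_map = sm, stride = 4))
  expect_equal(nrow(d), 1)
  expect_equal(c(d$x, d$y), c(5 * 4 + 2, 10 * 4 + 2))
  expect_equal(c(d$w, d$h), c(6, 4))

  flat <- matrix(0, 8, 8) # uniform plateau: every cell is a local max
  smf <- array(1, dim = c(8, 8, 2))
  df <- decode_detections(list(heatmap_logits = flat, size_map = smf, stride = 4),
                          max_det = 5, score_thresh = 0.1)
  expect_equal(nrow(df), 5)
  expect_equal(c(df$x[1], df$y[1]), c(2, 2)) # raster order starts at cell (0, 0)
  expect_equal(c(df$x[2], df$y[2]), c(6, 2)) # then walks along the row
})

test_that("render -> decode round-trip recovers every electrode within stride/2 + 2 px", {
  for (i in 1:20) {
    sc <- generate_scene(small_spec(seed = 300 + i), i)
    tg <- render_targets(sc, 4)
    logits <- qlogis(pmin(pmax(tg$heatmap, 1e-6), 1 - 1e-6))
    d <- decode_detections(list(heatmap_logits = logits, size_map = tg$size_map,
                                stride = 4), score_thresh = 0.4)
    for (e in seq_len(nrow(sc$electrodes))) {
      dist <- sqrt((d$x - sc$electrodes[e, 1])^2 + (d$y - sc$electrodes[e, 2])^2)
      expect_lte(min(dist), 4 + 1e-9) # stride/2 + 2
    }
  }
})

test_that("average precision matches its limits and the naive oracle", {
  scenes <- generate_scenes(small_spec(seed = 41), 4)
  oracle <- oracle_predictions(scenes)
  expect_equal(average_precision(lapply(oracle, `[[`, "dets"), scenes), 1.0)
  empty <- replicate(4, data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                                   h = numeric(0), score = numeric(0)),
                     simplify = FALSE)
  expect_equal(average_precision(empty, scenes), 0.0)
  expect_error(average_precision(empty[1], list(manual_scene(
    electrodes = matrix(numeric(0), 0, 2), sizes = matrix(numeric(0), 0, 2)))),
    "ground truth")

  # small random instances incl. duplicate detections vs the oracle evaluator
  set.seed(6)
  for (rep in 1:40) {
    gt <- manual_scene(electrodes = cbind(sample(5:58, 2), sample(5:58, 2)),
                       sizes = matrix(runif(4, 4, 10), 2))
    base <- data.frame(x = gt$electrodes[, 1] + rnorm(2),
                       y = gt$electrodes[, 2] + rnorm(2),
                       w = gt$sizes[, 1] * runif(2, 0.8, 1.2),
                       h = gt$sizes[, 2] * runif(2, 0.8, 1.2),
                       score = runif(2))
    dup <- base[sample(2, 1), ]; dup$score <- runif(1)
    dets <- rbind(base, dup)[sample(3), ]
    expect_equal(average_precision(list(dets), list(gt)),
                 naive_ap(list(dets), list(gt)), tolerance = 1e-9)
  }
})

test_that("AP ignores appended zero-score false positives", {
  scenes <- generate_scenes(small_spec(seed = 77), 2)
  oracle <- lapply(oracle_predictions(scenes), `[[`, "dets")
  with_junk <- lapply(oracle, function(d) {
    rbind(d, data.frame(x = 1, y = 1, w = 3, h = 3, score = 0))
  })
  expect_equal(average_precision(with_junk, scenes),
               average_precision(oracle, scenes), tolerance = 1e-9)
})

test_that("region similarity counts pixels exactly", {
  m <- matrix(0, 3, 3)
  a <- m; a[1:2, ] <- 1 # rows 0-1
  b <- m; b[2:3, ] <- 1 # rows 1-2
  expect_equal(region_similarity(a, b), 1 / 3) # inter 3, union 9
  expect_equal(region_similarity(a, a), 1)
  expect_equal(region_similarity(a, 1 - a), 0)
  expect_equal(region_similarity(m, m), 1) # both empty
  expect_error(region_similarity(matrix(0, 2, 2), m), "shape")
})

test_that("evaluation reports satisfy the mean-KPI identity in both extremes", {
  scenes <- generate_scenes(small_spec(seed = 55), 5)
  rep_perfect <- evaluate_predictions(oracle_predictions(scenes), scenes)
  expect_equal(rep_perfect$ap, 1)
  expect_equal(rep_perfect$mean_j, 1)
  expect_equal(rep_perfect$mean_kpi, 1)
  expect_equal(rep_perfect$mae_px, 0)
  background <- lapply(scenes, function(sc) {
    list(dets = data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                           h = numeric(0), score = numeric(0)),
         mask = matrix(0, nrow(sc$image), ncol(sc$image)))
  })
  rep_bg <- evaluate_predictions(background, scenes)
  expect_equal(rep_bg$mean_kpi, 0)
  expect_equal(rep_bg$mean_kpi, (rep_bg$ap + rep_bg$mean_j) / 2)
  expect_equal(rep_perfect$mean_kpi, (rep_perfect$ap + rep_perfect$mean_j) / 2)
})
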