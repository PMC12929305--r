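tiny_cfg <- function(...) {
  args <- list(model = model_config("tiny", embed_dim = 16L, head_channels = 8L,
                                    input_size = c(64L, 64L)),
               lr = 1e-3, epochs = 1L, batch_size = 4L, seed = 13L,
               augment = list(scale = FALSE, flip = FALSE, rotate = FALSE))
  do.call(train_config, utils::modifyList(args, list(...)))
}

test_that("the first dynamic iteration weights both tasks by exactly 1", {
  scenes <- generate_scenes(small_spec(seed = 61), 8)
  fit <- train(tiny_cfg(), scenes)
  r1 <- fit$log[1, ]
  expect_equal(r1$l_total, r1$l_d + r1$l_s, tolerance = 1e-12)
})

test_that("single-task segmentation training leaves the detection heads untouched", {
  scenes <- generate_scenes(small_spec(seed = 62), 8)
  cfg <- tiny_cfg(baseline_mode = "single_task_s")
  set.seed(cfg$seed)
  init <- build_model(cfg$model)$params
  fit <- train(cfg, scenes)
  for (nm in grep("^(heat|size)\\.", names(init), value = TRUE)) {
    expect_identical(fit$model$params[[nm]], init[[nm]])
  }
  expect_false(identical(fit$model$params[["seg.out.w"]], init[["seg.out.w"]]))
  expect_false(identical(fit$model$params[["stem.w"]], init[["stem.w"]]))
})

test_that("training is reproducible under a fixed seed", {
  scenes <- generate_scenes(small_spec(seed = 63), 8)
  f1 <- train(tiny_cfg(epochs = 2L), scenes)
  f2 <- train(tiny_cfg(epochs = 2L), scenes)
  expect_identical(f1$log$l_total, f2$log$l_total)
  expect_identical(f1$model$params[["stem.w"]], f2$model$params[["stem.w"]])
})

test_that("one forward pass per batch serves both tasks", {
  scenes <- generate_scenes(small_spec(seed = 64), 10)
  set.seed(1)
  m <- build_model(model_config("tiny", embed_dim = 16L, head_channels = 8L,
                                input_size = c(64L, 64L)))
  before <- m$n_forward
  rep <- evaluate(m, scenes, batch_size = 4)
  expect_equal(m$n_forward - before, ceiling(10 / 4)) # no second inference
  expect_true(is.finite(rep$mean_kpi))
})

test_that("training logs, checkpoints and priority state land on disk", {
  dir <- withr::local_tempdir()
  scenes <- generate_scenes(small_spec(seed = 65), 6)
  fit <- train(tiny_cfg(batch_size = 3L), scenes, out = dir)
  expect_true(file.exists(file.path(dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(dir, "priority_state.json")))
  lines <- readLines(file.path(dir, "train_log.jsonl"))
  expect_length(lines, nrow(fit$log))
  row1 <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("l_d", "l_s", "kappa_bar_d", "k_fraction", "sum_delta_d")
                  %in% names(row1)))
  ck <- load_checkpoint(file.path(dir, "checkpoint.rds"))
  expect_identical(ck$model$params[["stem.w"]], fit$model$params[["stem.w"]])
  expect_equal(ck$state$tau, fit$state$tau)
})

test_that("the ablation harness tabulates every variant", {
  scenes <- generate_scenes(small_spec(seed = 66), 8)
  valid <- generate_scenes(small_spec(seed = 66), 2, offset = 100)
  res <- ablate(list(dynamic = list(baseline_mode = "dynamic"),
                     constant = list(baseline_mode = "constant_weights")),
                tiny_cfg(), scenes, valid)
  expect_equal(nrow(res), 2)
  expect_setequal(res$variant, c("dynamic", "constant"))
  expect_true(all(is.finite(res$ap)) && all(is.finite(res$mean_kpi)))
})

test_that("augmentations preserve annotation geometry", {
  sc <- generate_scene(small_spec(seed = 67), 0)
  fh <- cathmtl:::.flip_scene_h(sc)
  idx <- cbind(round(fh$electrodes[, 2]) + 1, round(fh$electrodes[, 1]) + 1)
  expect_true(all(fh$mask[idx] == 1L))
  r90 <- cathmtl:::.rot90_scene(sc)
  idx90 <- cbind(round(r90$electrodes[, 2]) + 1, round(r90$electrodes[, 1]) + 1)
  expect_true(all(r90$mask[idx90] == 1L))
  expect_equal(sum(r90$mask), sum(sc$mask))
  zoom <- cathmtl:::.scale_scene(sc, 0.85)
  expect_equal(dim(zoom$image), dim(sc$image))
  expect_true(all(zoom$electrodes[, 1] >= 0 & zoom$electrodes[, 1] <= ncol(sc$image) - 1))
})
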