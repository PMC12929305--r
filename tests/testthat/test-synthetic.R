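test_that("scene generation is deterministic in (seed, index) and distinct across indices", {
  spec <- small_spec()
  a <- generate_scene(spec, 3)
  b <- generate_scene(spec, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$electrodes, b$electrodes)
  expect_identical(a$sizes, b$sizes)
  d <- generate_scene(spec, 4)
  expect_false(identical(a$image, d$image))
})

test_that("electrode counting and annotation invariants hold across scenes", {
  spec <- small_spec(electrodes_per_catheter = c(4L, 4L), n_catheters = 2L)
  sc <- generate_scene(spec, 0)
  expect_equal(nrow(sc$electrodes), 8L)
  expect_equal(nrow(sc$sizes), 8L)
  for (i in 0:9) {
    sc <- generate_scene(small_spec(seed = 20L + i), i)
    h <- nrow(sc$image); w <- ncol(sc$image)
    expect_true(all(sc$electrodes[, 1] >= 0 & sc$electrodes[, 1] <= w - 1))
    expect_true(all(sc$electrodes[, 2] >= 0 & sc$electrodes[, 2] <= h - 1))
    # mask covers every rounded electrode center
    idx <- cbind(round(sc$electrodes[, 2]) + 1, round(sc$electrodes[, 1]) + 1)
    expect_true(all(sc$mask[idx] == 1L))
    expect_true(all(sc$image >= 0 & sc$image <= 1))
  }
})

test_that("mask equals the painted target pixels; distractors never enter the mask", {
  spec <- small_spec(n_distractors = 0L, noise_sigma = 0)
  sc <- generate_scene(spec, 1, keep_layers = TRUE)
  layers <- attr(sc, "layers")
  expect_identical(sc$mask, matrix(as.integer(layers$target), nrow(sc$mask)))
  spec2 <- small_spec(n_distractors = 4L)
  sc2 <- generate_scene(spec2, 1, keep_layers = TRUE)
  layers2 <- attr(sc2, "layers")
  expect_true(sum(layers2$distractor) > 0)
  expect_equal(sum(layers2$distractor & sc2$mask == 1L), 0L)
})

test_that("impossible scene specs are rejected", {
  expect_error(scene_spec(image_size = c(32, 32)), "image_size")
  expect_error(scene_spec(image_size = c(64, 64), electrode_radius_px = c(10, 40)),
               "cannot fit")
  expect_error(scene_spec(electrode_radius_px = c(-1, 2)))
  expect_error(scene_spec(electrodes_per_catheter = c(5, 3)))
})

test_that("dataset write/read round-trips images, masks and coordinates", {
  dir <- withr::local_tempdir()
  spec <- small_spec(noise_sigma = 0.03)
  scenes <- generate_scenes(spec, 3)
  manifest <- write_dataset(scenes, dir)
  expect_true(file.exists(manifest))
  back <- read_dataset(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$image, scenes[[i]]$image)
    expect_identical(back[[i]]$mask, scenes[[i]]$mask)
    expect_lt(max(abs(back[[i]]$electrodes - scenes[[i]]$electrodes)), 1e-6)
    expect_lt(max(abs(back[[i]]$sizes - scenes[[i]]$sizes)), 1e-6)
    expect_identical(back[[i]]$scene_id, scenes[[i]]$scene_id)
  }
})

test_that("empty dataset round-trips and corrupt annotations fail with the scene id", {
  dir <- withr::local_tempdir()
  write_dataset(list(), dir)
  expect_length(read_dataset(dir), 0)

  dir2 <- withr::local_tempdir()
  scenes <- generate_scenes(small_spec(), 1)
  write_dataset(scenes, dir2)
  annf <- file.path(dir2, "annotations", paste0(scenes[[1]]$scene_id, ".json"))
  ann <- jsonlite::read_json(annf, simplifyVector = FALSE)
  ann$electrodes[[1]] <- list(9999, 9999) # outside the image
  jsonlite::write_json(ann, annf, auto_unbox = TRUE, digits = NA)
  expect_error(read_dataset(dir2), "scene_00000")

  file.remove(file.path(dir2, "masks", paste0(scenes[[1]]$scene_id, ".png")))
  expect_error(read_dataset(dir2), "scene_00000")
})
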