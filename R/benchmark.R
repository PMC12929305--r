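#' Canonical synthetic benchmark conditions
#'
#' Fixed scene-generator settings used by the package's own evaluation
#' harness so results are comparable across runs. Two sizes are provided:
#' the desk profile (96 x 96, used for single training runs) and the sweep
#' profile (64 x 64, used for multi-seed strategy comparisons where many
#' runs are needed). Electrode radii are kept at 2-4 px — the physical scale
#' of catheter electrodes in cropped fluoroscopy views — rather than scaled
#' down with the image, so detection targets stay resolvable at stride 4.
#'
#' @param profile `"desk"` (96 x 96) or `"sweep"` (64 x 64).
#' @param noise_free drop pixel noise (the noise-free profile used for the
#'   learning smoke test); otherwise sigma 0.02.
#' @param seed generator seed.
#' @return a [scene_spec()].
#' @export
benchmark_spec <- function(profile = c("desk", "sweep"), noise_free = FALSE,
                           seed = 101L) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    scene_spec(image_size = c(96L, 96L),
               electrodes_per_catheter = c(3L, 6L),
               electrode_radius_px = c(2, 4),
               n_distractors = 2L,
               noise_sigma = if (noise_free) 0 else 0.02,
               seed = seed)
  } else {
    scene_spec(image_size = c(64L, 64L),
               electrodes_per_catheter = c(3L, 6L),
               electrode_radius_px = c(2, 3.5),
               n_distractors = 2L,
               noise_sigma = if (noise_free) 0 else 0.02,
               seed = seed)
  }
}
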