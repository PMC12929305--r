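#' Network configuration
#'
#' Encoder truncated at stride 16, a 3x3 linear projection into the latent
#' embedding, a channel-then-spatial attention block, a top-down decoder with
#' encoder skip connections down to the output stride, and three prediction
#' heads (segmentation, center heatmap, box size). The `tiny` backbone
#' (4 stages, widths 16/32/64/128) exists for CPU-scale training; `resnet18`
#' and `resnet34` are normalization-free basic-block ResNets truncated after
#' their stride-16 stage.
#'
#' @param backbone `"tiny"`, `"resnet18"` or `"resnet34"`.
#' @param embed_dim latent embedding width (default 512 for ResNets, 64 for
#'   tiny; must be >= 8).
#' @param head_channels channels of the two 3x3 convolutions in each head
#'   (default 64; 32 for tiny).
#' @param output_stride 2, 4 (default) or 8.
#' @param input_size (H, W), both divisible by 16.
#' @return a `model_config` list.
#' @export
model_config <- function(backbone = c("tiny", "resnet18", "resnet34"),
                         embed_dim = NULL, head_channels = NULL,
                         output_stride = 4L, input_size = c(256L, 256L)) {
  backbone <- match.arg(backbone)
  if (is.null(embed_dim)) embed_dim <- if (backbone == "tiny") 64L else 512L
  if (is.null(head_channels)) head_channels <- if (backbone == "tiny") 32L else 64L
  output_stride <- as.integer(output_stride)
  input_size <- as.integer(input_size)
  stopifnot(output_stride %in% c(2L, 4L, 8L), embed_dim >= 8L)
  if (any(input_size %% 16L != 0L)) stop("input size must be divisible by 16")
  structure(list(backbone = backbone, embed_dim = as.integer(embed_dim),
                 head_channels = as.integer(head_channels),
                 output_stride = output_stride, input_size = input_size),
            class = "model_config")
}

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

.add_conv <- function(model, name, k, cin, cout, gain = 1) {
  model$params[[paste0(name, ".w")]] <- .he_init(c(k, k, cin, cout), k * k * cin) * gain
  model$params[[paste0(name, ".b")]] <- numeric(cout)
  invisible(model)
}

.add_dense <- function(model, name, cin, cout) {
  model$params[[paste0(name, ".w")]] <-
    matrix(stats::rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin)
  model$params[[paste0(name, ".b")]] <- numeric(cout)
  invisible(model)
}

.backbone_plan <- function(config) {
  switch(config$backbone,
    tiny = list(widths = c(16L, 32L, 64L, 128L), blocks = NULL,
                dec_blocks = 0L,
                dec_channels = c(`8` = 48L, `4` = 32L, `2` = 24L)),
    resnet18 = list(widths = c(64L, 64L, 128L, 256L), blocks = c(2L, 2L, 2L),
                    dec_blocks = 1L,
                    dec_channels = c(`8` = config$embed_dim, `4` = config$embed_dim,
                                     `2` = config$embed_dim %/% 2L)),
    resnet34 = list(widths = c(64L, 64L, 128L, 256L), blocks = c(3L, 4L, 6L),
                    dec_blocks = 2L,
                    dec_channels = c(`8` = config$embed_dim, `4` = config$embed_dim,
                                     `2` = config$embed_dim %/% 2L))
  )
}

#' Build a model with freshly initialized weights
#'
#' He-normal initialization (seeded by the caller's RNG state); the final
#' 1x1 heatmap head bias starts at -2.19 so the initial heatmap probability
#' is ~0.1, the usual stabilization for penalty-reduced focal losses.
#'
#' @param config a [model_config()].
#' @return a `cath_model` environment holding `params`, `config` and a
#'   forward counter.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  plan <- .backbone_plan(config)
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$plan <- plan
  model$params <- list()
  model$n_forward <- 0L
  wd <- plan$widths
  if (config$backbone == "tiny") {
    .add_conv(model, "stem", 3L, 1L, wd[1])
    for (s in 2:4) {
      .add_conv(model, sprintf("s%d.conv1", s), 3L, wd[s - 1], wd[s])
      .add_conv(model, sprintf("s%d.conv2", s), 3L, wd[s], wd[s])
    }
    cback <- wd[4]
  } else {
    .add_conv(model, "stem", 7L, 1L, wd[1])
    for (st in 1:3) {
      cin <- if (st == 1) wd[1] else wd[st]
      cout <- wd[st + 1]
      for (b in seq_len(plan$blocks[st])) {
        bcin <- if (b == 1) cin else cout
        .add_conv(model, sprintf("l%d.b%d.conv1", st, b), 3L, bcin, cout)
        .add_conv(model, sprintf("l%d.b%d.conv2", st, b), 3L, cout, cout)
        if (b == 1 && bcin != cout) {
          .add_conv(model, sprintf("l%d.b%d.down", st, b), 1L, bcin, cout)
        }
      }
    }
    cback <- wd[4]
  }
  .add_conv(model, "proj", 3L, cback, config$embed_dim)
  rr <- max(4L, config$embed_dim %/% 16L)
  .add_dense(model, "att.fc1", config$embed_dim, rr)
  .add_dense(model, "att.fc2", rr, config$embed_dim)
  .add_conv(model, "att.sp", 7L, 2L, 1L)
  # decoder: one stage per doubling from stride 16 down to the output stride
  strides <- 16L
  while (strides[length(strides)] > config$output_stride) {
    strides <- c(strides, strides[length(strides)] %/% 2L)
  }
  skip_ch <- c(`8` = if (config$backbone == "tiny") wd[3] else wd[3],
               `4` = if (config$backbone == "tiny") wd[2] else wd[2],
               `2` = wd[1])
  cprev <- config$embed_dim
  for (s in strides[-1]) {
    key <- as.character(s)
    cdec <- plan$dec_channels[[key]]
    .add_conv(model, sprintf("dec%s.conv", key), 3L, cprev, cdec)
    .add_conv(model, sprintf("dec%s.skip", key), 1L, skip_ch[[key]], cdec)
    for (b in seq_len(plan$dec_blocks)) {
      .add_conv(model, sprintf("dec%s.r%d.conv1", key, b), 3L, cdec, cdec)
      .add_conv(model, sprintf("dec%s.r%d.conv2", key, b), 3L, cdec, cdec, gain = 0.5)
    }
    cprev <- cdec
  }
  hc <- config$head_channels
  for (hd in c("seg", "heat", "size")) {
    .add_conv(model, paste0(hd, ".conv1"), 3L, cprev, hc)
    .add_conv(model, paste0(hd, ".conv2"), 3L, hc, hc)
    .add_conv(model, paste0(hd, ".out"), 1L, hc, if (hd == "size") 2L else 1L)
  }
  model$params[["heat.out.b"]] <- -2.19 # sigmoid ~= 0.1 at init
  class(model) <- "cath_model"
  model
}

#' Number of trainable parameters
#' @param model a `cath_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.cath_model <- function(x, ...) {
  cat(sprintf("<cath_model %s: embed %d, stride %d, %.2fM params>\n",
              x$config$backbone, x$config$embed_dim, x$config$output_stride,
              n_parameters(x) / 1e6))
  invisible(x)
}

# forward pass on the tape; returns output nodes + the parameter leaf nodes
.model_forward_tape <- function(model, images) {
  cfg <- model$config
  plan <- model$plan
  tape <- ad_tape()
  pn <- lapply(model$params, function(p) ad_input(tape, p))
  cv <- function(x, name, stride = 1L) {
    ad_conv2d(tape, x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]], stride)
  }
  x <- ad_input(tape, images)
  skips <- list()
  if (cfg$backbone == "tiny") {
    f <- ad_relu(tape, cv(x, "stem", 2L))
    skips[["2"]] <- f
    for (s in 2:4) {
      f <- ad_relu(tape, cv(f, sprintf("s%d.conv1", s), 2L))
      f <- ad_relu(tape, cv(f, sprintf("s%d.conv2", s)))
      if (s < 4) skips[[as.character(2^s)]] <- f
    }
  } else {
    f <- ad_relu(tape, cv(x, "stem", 2L))
    skips[["2"]] <- f
    f <- ad_maxpool(tape, f)
    for (st in 1:3) {
      for (b in seq_len(plan$blocks[st])) {
        stride <- if (st > 1 && b == 1) 2L else 1L
        idn <- if (!is.null(model$params[[sprintf("l%d.b%d.down.w", st, b)]])) {
          dn <- cv(f, sprintf("l%d.b%d.down", st, b), stride)
          dn
        } else if (stride == 2L) {
          NULL # never happens: downsampling blocks always project
        } else f
        h <- ad_relu(tape, cv(f, sprintf("l%d.b%d.conv1", st, b), stride))
        h <- cv(h, sprintf("l%d.b%d.conv2", st, b))
        f <- ad_relu(tape, ad_add(tape, h, idn))
      }
      if (st < 3) skips[[as.character(2^(st + 1))]] <- f
    }
  }
  f <- cv(f, "proj") # linear projection into the embedding
  # channel attention: shared MLP over global average- and max-pooled vectors
  ca <- function(v) {
    h <- ad_relu(tape, ad_dense(tape, v, pn[["att.fc1.w"]], pn[["att.fc1.b"]]))
    ad_dense(tape, h, pn[["att.fc2.w"]], pn[["att.fc2.b"]])
  }
  gate_c <- ad_sigmoid(tape, ad_add(tape, ca(ad_gap(tape, f)), ca(ad_gmp(tape, f))))
  f <- ad_scale_channels(tape, f, gate_c)
  # spatial attention: 7x7 conv over channelwise mean/max maps
  sp <- ad_concat_c(tape, ad_channel_mean(tape, f), ad_channel_max(tape, f))
  gate_s <- ad_sigmoid(tape, cv(sp, "att.sp"))
  f <- ad_scale_spatial(tape, f, gate_s)
  # top-down decoder with skip fusion by 1x1 projection + addition
  strides <- 16L
  while (strides[length(strides)] > cfg$output_stride) {
    strides <- c(strides, strides[length(strides)] %/% 2L)
  }
  for (s in strides[-1]) {
    key <- as.character(s)
    u <- ad_upsample(tape, f, 2L)
    fused <- ad_add(tape, cv(u, sprintf("dec%s.conv", key)),
                    cv(skips[[key]], sprintf("dec%s.skip", key)))
    f <- ad_relu(tape, fused)
    for (b in seq_len(plan$dec_blocks)) {
      h <- ad_relu(tape, cv(f, sprintf("dec%s.r%d.conv1", key, b)))
      h <- cv(h, sprintf("dec%s.r%d.conv2", key, b))
      f <- ad_relu(tape, ad_add(tape, f, h))
    }
  }
  head <- function(hd) {
    h <- ad_relu(tape, cv(f, paste0(hd, ".conv1")))
    h <- ad_relu(tape, cv(h, paste0(hd, ".conv2")))
    cv(h, paste0(hd, ".out"))
  }
  seg <- ad_upsample(tape, head("seg"), cfg$output_stride)
  list(tape = tape, param_nodes = pn,
       seg_logits = seg, heat_logits = head("heat"), size_map = head("size"))
}

#' Run the network on a batch of images
#'
#' A single forward pass serves all three heads; the model's forward counter
#' increments once per call.
#'
#' @param model a `cath_model`.
#' @param images (H, W, 1, N) array in [0, 1], or a list of H x W matrices,
#'   or one matrix.
#' @param keep_tape if `TRUE` return the tape and output nodes (for
#'   training); otherwise plain prediction arrays.
#' @return with `keep_tape = FALSE`, a `prediction_maps` list:
#'   `seg_logits` (H, W, 1, N), `heatmap_logits` (H/s, W/s, 1, N),
#'   `size_map` (H/s, W/s, 2, N) and `stride`.
#' @export
model_forward <- function(model, images, keep_tape = FALSE) {
  if (is.list(images)) {
    images <- array(unlist(images), dim = c(dim(images[[1]]), 1L, length(images)))
  } else if (length(dim(images)) == 2L) {
    images <- array(images, dim = c(dim(images), 1L, 1L))
  }
  if (any(!is.finite(images))) stop("model_forward: NaN in input")
  model$n_forward <- model$n_forward + 1L
  out <- .model_forward_tape(model, images)
  if (keep_tape) return(out)
  structure(list(seg_logits = out$seg_logits$value,
                 heatmap_logits = out$heat_logits$value,
                 size_map = out$size_map$value,
                 stride = model$config$output_stride),
            class = "prediction_maps")
}
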