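# Minimal reverse-mode tape over (H, W, C, N) arrays. Nodes are environments
# holding value/grad; ops append to the tape so backward runs in reverse
# creation order. Heavy kernels (conv, pooling, resize) live in src/.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# seeds: list of list(node =, grad =). Runs the whole tape backwards.
ad_backward <- function(tape, seeds) {
  for (s in seeds) ad_accum(s$node, s$grad)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

ad_input <- function(tape, value) ad_node(tape, value)

ad_conv2d <- function(tape, x, w, b, stride = 1L, pad = NULL) {
  kd <- dim(w$value)
  if (is.null(pad)) pad <- (kd[1] - 1L) %/% 2L
  y <- .cpp_conv2d_fwd(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  ad_node(tape, y, list(x, w, b), local({
    stride <- as.integer(stride); pad <- as.integer(pad)
    function(nd) {
      g <- .cpp_conv2d_bwd(nd$parents[[1]]$value, nd$parents[[2]]$value, nd$grad,
                           stride, pad)
      ad_accum(nd$parents[[1]], g$gx)
      ad_accum(nd$parents[[2]], g$gw)
      ad_accum(nd$parents[[3]], g$gb)
    }
  }))
}

ad_relu <- function(tape, x) {
  y <- x$value
  y[y < 0] <- 0
  ad_node(tape, y, list(x), function(nd) {
    g <- nd$grad
    g[nd$value <= 0] <- 0
    ad_accum(nd$parents[[1]], g)
  })
}

ad_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  ad_node(tape, y, list(x), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * nd$value * (1 - nd$value))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1]], nd$grad)
    ad_accum(nd$parents[[2]], nd$grad)
  })
}

ad_maxpool <- function(tape, x) {
  r <- .cpp_maxpool_fwd(x$value)
  ad_node(tape, r$y, list(x), local({
    idx <- r$idx
    xdim <- dim(x$value)
    function(nd) ad_accum(nd$parents[[1]], .cpp_maxpool_bwd(nd$grad, idx, xdim))
  }))
}

ad_upsample <- function(tape, x, factor) {
  y <- .cpp_upsample_fwd(x$value, as.integer(factor))
  ad_node(tape, y, list(x), local({
    f <- as.integer(factor); xdim <- dim(x$value)
    function(nd) ad_accum(nd$parents[[1]], .cpp_upsample_bwd(nd$grad, f, xdim))
  }))
}

# ---- pooled statistics used by the attention block ------------------------

# global average pool over H, W -> [C, N]
ad_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- matrix(x$value, hw, d[3] * d[4])
  ad_node(tape, matrix(colMeans(m), d[3], d[4]), list(x), local({
    d <- d; hw <- hw
    function(nd) {
      g <- array(rep(as.vector(nd$grad) / hw, each = hw), dim = d)
      ad_accum(nd$parents[[1]], g)
    }
  }))
}

# global max pool over H, W -> [C, N]
ad_gmp <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- matrix(x$value, hw, d[3] * d[4])
  idx <- apply(m, 2L, which.max)
  y <- matrix(m[cbind(idx, seq_along(idx))], d[3], d[4])
  ad_node(tape, y, list(x), local({
    d <- d; hw <- hw; idx <- idx
    function(nd) {
      g <- array(0, dim = d)
      flat <- idx + (seq_along(idx) - 1L) * hw
      g[flat] <- as.vector(nd$grad)
      ad_accum(nd$parents[[1]], g)
    }
  }))
}

# dense layer on [Cin, N]: w [Cout, Cin], b [Cout]
ad_dense <- function(tape, x, w, b) {
  y <- w$value %*% x$value + b$value
  ad_node(tape, y, list(x, w, b), function(nd) {
    ad_accum(nd$parents[[1]], crossprod(nd$parents[[2]]$value, nd$grad))
    ad_accum(nd$parents[[2]], tcrossprod(nd$grad, nd$parents[[1]]$value))
    ad_accum(nd$parents[[3]], rowSums(nd$grad))
  })
}

# multiply feature map [H,W,C,N] by per-channel gate s [C,N]
ad_scale_channels <- function(tape, x, s) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  bc <- array(rep(as.vector(s$value), each = hw), dim = d)
  ad_node(tape, x$value * bc, list(x, s), local({
    d <- d; hw <- hw; bc <- bc
    function(nd) {
      ad_accum(nd$parents[[1]], nd$grad * bc)
      gs <- colSums(matrix(nd$grad * nd$parents[[1]]$value, hw, d[3] * d[4]))
      ad_accum(nd$parents[[2]], matrix(gs, d[3], d[4]))
    }
  }))
}

.spatial_bcast <- function(s, C) {
  d <- dim(s) # (H, W, 1, N)
  m <- matrix(s, d[1] * d[2], d[4])
  array(m[, rep(seq_len(d[4]), each = C), drop = FALSE], dim = c(d[1], d[2], C, d[4]))
}

# multiply feature map [H,W,C,N] by spatial gate s [H,W,1,N]
ad_scale_spatial <- function(tape, x, s) {
  d <- dim(x$value)
  bc <- .spatial_bcast(s$value, d[3])
  ad_node(tape, x$value * bc, list(x, s), local({
    d <- d; bc <- bc
    function(nd) {
      ad_accum(nd$parents[[1]], nd$grad * bc)
      gxs <- nd$grad * nd$parents[[1]]$value
      hw <- d[1] * d[2]
      m <- matrix(gxs, hw, d[3] * d[4])
      gs <- matrix(0, hw, d[4])
      for (n in seq_len(d[4])) {
        cols <- ((n - 1L) * d[3] + 1L):(n * d[3])
        gs[, n] <- rowSums(m[, cols, drop = FALSE])
      }
      ad_accum(nd$parents[[2]], array(gs, dim = c(d[1], d[2], 1L, d[4])))
    }
  }))
}

# mean over channels -> [H,W,1,N]
ad_channel_mean <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- matrix(x$value, hw, d[3] * d[4])
  y <- matrix(0, hw, d[4])
  for (n in seq_len(d[4])) {
    cols <- ((n - 1L) * d[3] + 1L):(n * d[3])
    y[, n] <- rowMeans(m[, cols, drop = FALSE])
  }
  ad_node(tape, array(y, dim = c(d[1], d[2], 1L, d[4])), list(x), local({
    d <- d
    function(nd) ad_accum(nd$parents[[1]], .spatial_bcast(nd$grad, d[3]) / d[3])
  }))
}

# max over channels -> [H,W,1,N]
ad_channel_max <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  y <- array(-Inf, dim = c(d[1], d[2], 1L, d[4]))
  arg <- array(1L, dim = c(d[1], d[2], 1L, d[4]))
  for (cc in seq_len(d[3])) {
    sl <- x$value[, , cc, , drop = FALSE]
    upd <- sl > y
    y[upd] <- sl[upd]
    arg[upd] <- cc
  }
  ad_node(tape, y, list(x), local({
    d <- d; arg <- arg
    function(nd) {
      g <- array(0, dim = d)
      for (cc in seq_len(d[3])) {
        sel <- arg == cc
        gc <- array(0, dim = dim(nd$grad))
        gc[sel] <- nd$grad[sel]
        g[, , cc, ] <- gc
      }
      ad_accum(nd$parents[[1]], g)
    }
  }))
}

# concatenate along channel axis
ad_concat_c <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  ad_node(tape, y, list(a, b), local({
    ca <- da[3]; cb <- db[3]
    function(nd) {
      ad_accum(nd$parents[[1]], nd$grad[, , seq_len(ca), , drop = FALSE])
      ad_accum(nd$parents[[2]], nd$grad[, , ca + seq_len(cb), , drop = FALSE])
    }
  }))
}
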