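# Differentiable operations on the tape. Feature maps are [h, w, c] arrays;
# channel descriptors are plain numeric vectors. Convolution weights are the
# flattened [k*k*c_in, c_out] matrices expected by the C++ kernels.

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# -- convolution ------------------------------------------------------------

op_conv <- function(tp, x, W, k, b = NULL) {
  xv <- x$value
  Wv <- W$value
  bv <- if (is.null(b)) numeric(ncol(Wv)) else b$value
  y <- cpp_conv2d_fwd(xv, Wv, bv, k)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  tp_push(tp, y, parents, function(g) {
    bw <- cpp_conv2d_bwd(xv, Wv, g, k)
    if (is.null(b)) list(bw$gx, bw$gW) else list(bw$gx, bw$gW, as.numeric(bw$gb))
  })
}

# -- elementwise ------------------------------------------------------------

op_relu <- function(tp, x) {
  v <- x$value
  tp_push(tp, pmax(v, 0), list(x), function(g) list(g * (v > 0)))
}

op_sigmoid <- function(tp, x) {
  y <- 1 / (1 + exp(-x$value))
  tp_push(tp, y, list(x), function(g) list(g * y * (1 - y)))
}

op_add <- function(tp, a, b) {
  tp_push(tp, a$value + b$value, list(a, b), function(g) list(g, g))
}

# -- resampling -------------------------------------------------------------

op_avgpool2 <- function(tp, x) {
  d <- dim(x$value)
  tp_push(tp, cpp_avgpool2_fwd(x$value), list(x),
          function(g) list(cpp_avgpool2_bwd(g, d[1], d[2])))
}

op_upsample2 <- function(tp, x, mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  if (mode == "nearest") {
    tp_push(tp, cpp_upnn_fwd(x$value), list(x), function(g) list(cpp_upnn_bwd(g)))
  } else {
    tp_push(tp, cpp_upbl_fwd(x$value), list(x), function(g) list(cpp_upbl_bwd(g)))
  }
}

# -- channel plumbing -------------------------------------------------------

op_concat <- function(tp, xs) {
  xs <- xs[!vapply(xs, is.null, logical(1))]
  if (length(xs) == 1L) return(xs[[1]])
  dims <- lapply(xs, function(x) dim(x$value))
  nc <- vapply(dims, function(d) d[3], numeric(1))
  h <- dims[[1]][1]
  w <- dims[[1]][2]
  val <- array(unlist(lapply(xs, function(x) x$value), use.names = FALSE),
               c(h, w, sum(nc)))
  ends <- cumsum(nc)
  starts <- c(1, utils::head(ends, -1) + 1)
  tp_push(tp, val, xs, function(g) {
    lapply(seq_along(xs), function(j) {
      g[, , starts[j]:ends[j], drop = FALSE]
    })
  })
}

# Multiply each channel slice by a scalar gate (channel attention).
op_scale_channels <- function(tp, x, wnode) {
  xv <- x$value
  d <- dim(xv)
  wv <- wnode$value
  wb <- array(rep(wv, each = d[1] * d[2]), d)
  tp_push(tp, xv * wb, list(x, wnode), function(g) {
    gw <- colSums(matrix(g * xv, d[1] * d[2], d[3]))
    list(g * wb, gw)
  })
}

# Multiply every channel by one spatial gate map [h, w, 1] (spatial attention).
op_scale_spatial <- function(tp, x, mnode) {
  xv <- x$value
  mv <- as.vector(mnode$value) # h*w, recycled across slices
  tp_push(tp, xv * mv, list(x, mnode), function(g) {
    d <- dim(xv)
    gm <- array(rowSums(matrix(g * xv, d[1] * d[2], d[3])), c(d[1], d[2], 1L))
    list(g * mv, gm)
  })
}

# -- pooled descriptors -----------------------------------------------------

op_global_avgpool <- function(tp, x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  v <- colMeans(matrix(x$value, n, d[3]))
  tp_push(tp, v, list(x), function(g) {
    list(array(rep(g / n, each = n), d))
  })
}

op_global_maxpool <- function(tp, x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  m <- matrix(x$value, n, d[3])
  idx <- apply(m, 2, which.max)
  v <- m[cbind(idx, seq_len(d[3]))]
  tp_push(tp, v, list(x), function(g) {
    gm <- matrix(0, n, d[3])
    gm[cbind(idx, seq_len(d[3]))] <- g
    list(array(gm, d))
  })
}

op_channel_mean <- function(tp, x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  v <- array(rowMeans(matrix(x$value, n, d[3])), c(d[1], d[2], 1L))
  tp_push(tp, v, list(x), function(g) {
    list(array(rep(as.vector(g) / d[3], d[3]), d))
  })
}

op_channel_max <- function(tp, x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  m <- matrix(x$value, n, d[3])
  idx <- max.col(m, ties.method = "first")
  v <- array(m[cbind(seq_len(n), idx)], c(d[1], d[2], 1L))
  tp_push(tp, v, list(x), function(g) {
    gm <- matrix(0, n, d[3])
    gm[cbind(seq_len(n), idx)] <- as.vector(g)
    list(array(gm, d))
  })
}

# -- dense (vector) layer ---------------------------------------------------

op_dense <- function(tp, x, W, b) {
  xv <- x$value
  Wv <- W$value
  y <- as.numeric(Wv %*% xv + b$value)
  tp_push(tp, y, list(x, W, b), function(g) {
    list(as.numeric(crossprod(Wv, g)), outer(g, xv), g)
  })
}

# -- per-channel spatial normalization --------------------------------------

# BatchNorm evaluated at batch size one: per-channel mean/variance over the
# spatial extent, learnable scale gamma and shift beta, running statistics
# (momentum 0.1) used in evaluation mode. Backward implements the full
# normalization Jacobian.
op_instance_norm <- function(tp, x, gamma, beta, state, training,
                             eps = 1e-5, momentum = 0.1) {
  xv <- x$value
  d <- dim(xv)
  n <- d[1] * d[2]
  xm <- matrix(xv, n, d[3])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    va[va < 0] <- 0
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  sdv <- sqrt(va + eps)
  xhat <- (xm - matrix(mu, n, d[3], byrow = TRUE)) /
    matrix(sdv, n, d[3], byrow = TRUE)
  gv <- gamma$value
  bv <- beta$value
  y <- xhat * matrix(gv, n, d[3], byrow = TRUE) + matrix(bv, n, d[3], byrow = TRUE)
  tp_push(tp, array(y, d), list(x, tp_leaf(tp, gamma), tp_leaf(tp, beta)),
          function(g) {
            gm <- matrix(g, n, d[3])
            ggamma <- colSums(gm * xhat)
            gbeta <- colSums(gm)
            if (training) {
              gx <- (gm -
                       matrix(gbeta / n, n, d[3], byrow = TRUE) -
                       xhat * matrix(ggamma / n, n, d[3], byrow = TRUE)) *
                matrix(gv / sdv, n, d[3], byrow = TRUE)
            } else {
              gx <- gm * matrix(gv / sdv, n, d[3], byrow = TRUE)
            }
            list(array(gx, d), ggamma, gbeta)
          })
}

# -- losses -----------------------------------------------------------------

# Soft Tversky index of a probability map against a crisp truth mask.
# truth enters as plain numeric (no gradient).
op_tversky_index <- function(tp, pred, truth, alpha, beta, smooth = 1) {
  y <- pred$value
  x <- as.numeric(truth)
  s <- sum(x * y)
  fn <- sum(x * (1 - y))
  fp <- sum((1 - x) * y)
  num <- s + smooth
  den <- s + alpha * fn + beta * fp + smooth
  ti <- num / den
  tp_push(tp, ti, list(pred), function(g) {
    dnum <- x
    dden <- x - alpha * x + beta * (1 - x)
    gy <- g * (dnum * den - num * dden) / (den * den)
    list(array(gy, dim(y)))
  })
}

# (1 - TI)^gamma for the single foreground class.
op_focal_from_ti <- function(tp, ti, gamma) {
  t0 <- ti$value
  val <- (1 - t0)^gamma
  tp_push(tp, val, list(ti), function(g) {
    list(-g * gamma * (1 - t0)^(gamma - 1))
  })
}

# Mean binary cross-entropy with probability clipping; the clipped region is
# treated as constant (zero gradient), which is the usual safeguard.
op_bce <- function(tp, pred, truth, clip = 1e-7) {
  y <- pred$value
  x <- as.numeric(truth)
  yc <- pmin(pmax(y, clip), 1 - clip)
  n <- length(x)
  val <- -mean(x * log(yc) + (1 - x) * log(1 - yc))
  tp_push(tp, val, list(pred), function(g) {
    gy <- g * (-(x / yc) + (1 - x) / (1 - yc)) / n
    gy[y < clip | y > 1 - clip] <- 0
    list(array(gy, dim(y)))
  })
}
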