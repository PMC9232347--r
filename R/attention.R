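#' Parameters for the CBAM attention module
#'
#' CBAM gates a feature map twice in series: a channel gate built from
#' globally pooled descriptors passed through a shared two-layer perceptron
#' (hidden width `max(1, floor(C/r))`, ReLU in between), and a spatial gate
#' built from channel-wise mean and max maps passed through a same-padded
#' 7x7 convolution. Both gates end in a sigmoid, so every weight lies
#' strictly in (0, 1).
#'
#' @param channels Number of channels `C` of the gated feature map.
#' @param r Reduction ratio of the MLP bottleneck (default 16).
#' @param k Spatial-attention kernel size (default 7, odd).
#' @param init `"he"` for random He-initialized weights from the current RNG,
#'   or `"zeros"` for all-zero weights and biases (both gates then equal 0.5
#'   everywhere, a useful reference point).
#' @return An object of class `cbam_params` with elements `W1`, `b1`, `W2`,
#'   `b2` (shared MLP) and `Ws` (`[k, k, 2, 1]` spatial conv weights), `bs`.
#' @export
cbam_params <- function(channels, r = 16, k = 7, init = c("he", "zeros")) {
  init <- match.arg(init)
  hidden <- max(1L, as.integer(floor(channels / r)))
  if (init == "zeros") {
    W1 <- matrix(0, hidden, channels)
    W2 <- matrix(0, channels, hidden)
    Ws <- array(0, c(k, k, 2, 1))
  } else {
    W1 <- matrix(stats::rnorm(hidden * channels, sd = sqrt(2 / channels)),
                 hidden, channels)
    W2 <- matrix(stats::rnorm(channels * hidden, sd = sqrt(2 / hidden)),
                 channels, hidden)
    Ws <- array(stats::rnorm(k * k * 2, sd = sqrt(2 / (k * k * 2))), c(k, k, 2, 1))
  }
  structure(list(channels = as.integer(channels), r = r, hidden = hidden, k = k,
                 W1 = W1, b1 = numeric(hidden), W2 = W2, b2 = numeric(channels),
                 Ws = Ws, bs = 0),
            class = "cbam_params")
}

check_finite_feature <- function(f) {
  if (!all(is.finite(f))) stop("feature map contains non-finite values")
  invisible(f)
}

#' Channel attention gate
#'
#' `M_c = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))` with global spatial
#' pooling and a shared MLP; the refined feature is `F' = M_c * F`,
#' broadcast over space.
#'
#' @param f `[h, w, C]` feature array.
#' @param params A [cbam_params()] with matching `channels`.
#' @return List with `weights` (length-`C` gate in (0,1)) and `feature`
#'   (the gated map, same shape as `f`).
#' @export
channel_attention <- function(f, params) {
  f <- as_cube(f)
  check_finite_feature(f)
  d <- dim(f)
  if (d[3] != params$channels) stop("channel count does not match params")
  m <- matrix(f, d[1] * d[2], d[3])
  mlp <- function(v) {
    h <- pmax(as.numeric(params$W1 %*% v + params$b1), 0)
    as.numeric(params$W2 %*% h + params$b2)
  }
  mc <- 1 / (1 + exp(-(mlp(colMeans(m)) + mlp(apply(m, 2, max)))))
  fp <- f * array(rep(mc, each = d[1] * d[2]), d)
  list(weights = mc, feature = fp)
}

#' Spatial attention gate
#'
#' Channel-wise mean and max maps are stacked to a two-channel image, passed
#' through a same-padded `k x k` convolution (default 7x7) and a sigmoid to
#' give `M_s`; the refined feature is `F'' = M_s * F'`, broadcast over
#' channels.
#'
#' @param f `[h, w, C]` feature array (typically the channel-gated `F'`).
#' @param params A [cbam_params()] providing the convolution weights `Ws`,
#'   `bs`.
#' @return List with `weights` (`[h, w]` gate in (0,1)) and `feature`.
#' @export
spatial_attention <- function(f, params) {
  f <- as_cube(f)
  check_finite_feature(f)
  d <- dim(f)
  m <- matrix(f, d[1] * d[2], d[3])
  desc <- array(c(rowMeans(m), m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]),
                c(d[1], d[2], 2))
  z <- conv_same(desc, params$Ws, params$bs)[, , 1]
  ms <- 1 / (1 + exp(-z))
  list(weights = ms, feature = f * as.vector(ms))
}

#' Convolutional block attention module (channel then spatial, in series)
#'
#' @param f `[h, w, C]` feature array.
#' @param params A [cbam_params()].
#' @return List with `channel_weights`, `spatial_weights` and `feature`
#'   (`F''`, same shape as `f`).
#' @export
cbam <- function(f, params) {
  ca <- channel_attention(f, params)
  sa <- spatial_attention(ca$feature, params)
  list(channel_weights = ca$weights, spatial_weights = sa$weights,
       feature = sa$feature)
}
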