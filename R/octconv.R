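#' Pair of high- and low-frequency feature streams
#'
#' An octave feature splits the channels of a conventional feature map into a
#' full-resolution high-frequency stream and a half-resolution low-frequency
#' stream. The low stream stores the smooth, slowly varying content at half
#' the spatial cost, which is where octave convolution saves computation.
#'
#' @param high `[h, w, c_H]` array (a matrix is promoted to one channel).
#' @param low `[h/2, w/2, c_L]` array, or `NULL` when the low fraction is 0.
#' @param alpha Fraction of channels held by the low-frequency stream.
#' @return An object of class `frequency_feature`.
#' @export
frequency_feature <- function(high, low = NULL, alpha = NULL) {
  high <- as_cube(high)
  if (!is.null(low)) {
    low <- as_cube(low)
    dh <- dim(high)
    dl <- dim(low)
    if (dh[1] %% 2L != 0L || dh[2] %% 2L != 0L) {
      stop("high stream must have even spatial dimensions when a low stream is present")
    }
    if (dl[1] != dh[1] / 2L || dl[2] != dh[2] / 2L) {
      stop("low stream must be exactly half the spatial size of the high stream")
    }
  }
  ctot <- dim(high)[3] + if (is.null(low)) 0L else dim(low)[3]
  if (is.null(alpha)) {
    alpha <- if (is.null(low)) 0 else dim(low)[3] / ctot
  }
  structure(list(high = high, low = low, alpha = alpha), class = "frequency_feature")
}

#' Split a channel count into high/low parts
#'
#' `c_L = round(alpha * c)`, `c_H = c - c_L`.
#'
#' @param channels Total channel count.
#' @param alpha Low-frequency fraction in `[0, 1)`.
#' @return Named integer vector with elements `high` and `low`.
#' @export
split_channels <- function(channels, alpha) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  low <- as.integer(round(alpha * channels))
  c(high = as.integer(channels) - low, low = low)
}

#' Construct an octave-convolution kernel
#'
#' Holds the four cross-frequency sub-kernels `W^{H->H}`, `W^{H->L}`,
#' `W^{L->H}`, `W^{L->L}`, each a `[k, k, c_in_path, c_out_path]` array, plus
#' optional per-stream biases. Paths with zero channels on either side are
#' absent (`NULL`). Weights default to He-initialized random draws from the
#' current RNG; pass `weights`/`bias` to set them explicitly (e.g. unit 1x1
#' kernels in worked examples).
#'
#' @param c_in,c_out Total input/output channel counts.
#' @param alpha_in,alpha_out Low-frequency channel fractions on input/output.
#' @param k Odd spatial kernel size.
#' @param weights Optional list with elements `hh`, `hl`, `lh`, `ll`.
#' @param bias Optional list with numeric vectors `h`, `l`; `NULL` entries
#'   mean zero bias.
#' @return An object of class `oct_kernel`.
#' @export
oct_kernel <- function(c_in, c_out, alpha_in = 0.5, alpha_out = 0.5, k = 3,
                       weights = NULL, bias = NULL) {
  if (k %% 2L != 1L) stop("kernel size k must be odd")
  cin <- split_channels(c_in, alpha_in)
  cout <- split_channels(c_out, alpha_out)
  he <- function(ci, co) {
    if (ci == 0L || co == 0L) return(NULL)
    sd <- sqrt(2 / (k * k * c_in))
    array(stats::rnorm(k * k * ci * co, sd = sd), c(k, k, ci, co))
  }
  w <- list(
    hh = he(cin["high"], cout["high"]),
    hl = he(cin["high"], cout["low"]),
    lh = he(cin["low"], cout["high"]),
    ll = he(cin["low"], cout["low"])
  )
  if (!is.null(weights)) {
    for (nm in names(weights)) w[[nm]] <- weights[[nm]]
  }
  b <- list(h = numeric(cout["high"]),
            l = if (cout["low"] > 0L) numeric(cout["low"]) else NULL)
  if (!is.null(bias)) {
    for (nm in names(bias)) b[[nm]] <- bias[[nm]]
  }
  structure(list(W = w, b = b, k = k, c_in = cin, c_out = cout,
                 alpha_in = alpha_in, alpha_out = alpha_out),
            class = "oct_kernel")
}

# Flatten a [k, k, ci, co] spatial kernel to the [k*k*ci, co] matrix layout
# used by the C++ convolution.
flatten_kernel <- function(W4) {
  d <- dim(W4)
  matrix(W4, d[1] * d[2] * d[3], d[4])
}

conv_same <- function(x, W4, b = NULL) {
  x <- as_cube(x)
  k <- dim(W4)[1]
  if (is.null(b)) b <- numeric(dim(W4)[4])
  cpp_conv2d_fwd(x, flatten_kernel(W4), b, k)
}

#' 2x2 average-pool downsampling
#'
#' @param x Matrix or `[h, w, c]` array with even spatial dimensions.
#' @return Half-resolution object of the same kind.
#' @export
avg_downsample <- function(x) {
  was_mat <- is.matrix(x)
  x <- as_cube(x)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("avg_downsample requires even spatial dimensions")
  }
  y <- cpp_avgpool2_fwd(x)
  if (was_mat) matrix(y[, , 1], dim(y)[1], dim(y)[2]) else y
}

#' Factor-2 bilinear upsampling (half-pixel centers)
#'
#' @param x Matrix or `[h, w, c]` array.
#' @return Object of the same kind at twice the spatial size.
#' @export
bilinear_upsample <- function(x) {
  was_mat <- is.matrix(x)
  x <- as_cube(x)
  y <- cpp_upbl_fwd(x)
  if (was_mat) matrix(y[, , 1], dim(y)[1], dim(y)[2]) else y
}

#' Factor-2 nearest-neighbor upsampling
#'
#' @param x Matrix or `[h, w, c]` array.
#' @return Object of the same kind at twice the spatial size.
#' @export
nearest_upsample <- function(x) {
  was_mat <- is.matrix(x)
  x <- as_cube(x)
  y <- cpp_upnn_fwd(x)
  if (was_mat) matrix(y[, , 1], dim(y)[1], dim(y)[2]) else y
}

#' Octave convolution
#'
#' The four-path information exchange between the high- and low-frequency
#' streams: `Y^H = Conv(X^H, W^{HH}) + Up(Conv(X^L, W^{LH}))` and
#' `Y^L = Conv(AvgPool(X^H, 2), W^{HL}) + Conv(X^L, W^{LL})`, all convolutions
#' stride-1 same-padded. At `alpha = 0` this reduces exactly to an ordinary
#' convolution of the high stream.
#'
#' @param x A [frequency_feature()].
#' @param kern An [oct_kernel()] whose input split matches `x`.
#' @param upsample Interpolation used on the low-to-high path, `"nearest"`
#'   (the convention of the octave-convolution literature, default) or
#'   `"bilinear"`.
#' @return A [frequency_feature()] with the kernel's output split.
#' @export
oct_conv <- function(x, kern, upsample = c("nearest", "bilinear")) {
  upsample <- match.arg(upsample)
  stopifnot(inherits(x, "frequency_feature"), inherits(kern, "oct_kernel"))
  dh <- dim(x$high)
  if (dh[3] != kern$c_in["high"]) {
    stop("high-stream channel count does not match the kernel's input split")
  }
  cl <- if (is.null(x$low)) 0L else dim(x$low)[3]
  if (cl != kern$c_in["low"]) {
    stop("low-stream channel count does not match the kernel's input split")
  }
  if (kern$c_in["low"] > 0L && (dh[1] %% 2L != 0L || dh[2] %% 2L != 0L)) {
    stop("odd spatial size: the high stream must be even-sized when alpha > 0")
  }
  up <- if (upsample == "nearest") cpp_upnn_fwd else cpp_upbl_fwd
  yh <- NULL
  yl <- NULL
  if (kern$c_out["high"] > 0L) {
    yh <- conv_same(x$high, kern$W$hh, kern$b$h)
    if (!is.null(kern$W$lh)) yh <- yh + up(conv_same(x$low, kern$W$lh))
  }
  if (kern$c_out["low"] > 0L) {
    yl <- conv_same(cpp_avgpool2_fwd(x$high), kern$W$hl, kern$b$l)
    if (!is.null(kern$W$ll)) yl <- yl + conv_same(x$low, kern$W$ll)
  }
  frequency_feature(yh, yl, alpha = kern$alpha_out)
}

#' Initial octave convolution (single stream in, dual stream out)
#'
#' Establishes the frequency split at the network stem: the high output is an
#' ordinary convolution of the input and the low output is a convolution of
#' its 2x2 average-pooled version.
#'
#' @param x Matrix or `[h, w, c]` array (all-high input).
#' @param kern An [oct_kernel()] with `alpha_in = 0`.
#' @return A [frequency_feature()].
#' @export
init_oct_conv <- function(x, kern) {
  stopifnot(inherits(kern, "oct_kernel"))
  if (kern$c_in["low"] != 0L) stop("init_oct_conv expects a kernel with alpha_in = 0")
  oct_conv(frequency_feature(as_cube(x), NULL, alpha = 0), kern)
}

#' Final octave convolution (dual stream in, single stream out)
#'
#' Merges the two streams back to full resolution: the low stream is
#' convolved, upsampled by 2 and added to the convolved high stream.
#'
#' @param x A [frequency_feature()].
#' @param kern An [oct_kernel()] with `alpha_out = 0`.
#' @param upsample Interpolation for the low-to-high merge.
#' @return `[h, w, c_out]` array at the high stream's resolution.
#' @export
fin_oct_conv <- function(x, kern, upsample = c("nearest", "bilinear")) {
  stopifnot(inherits(kern, "oct_kernel"))
  if (kern$c_out["low"] != 0L) stop("fin_oct_conv expects a kernel with alpha_out = 0")
  y <- oct_conv(x, kern, upsample = match.arg(upsample))
  y$high
}

#' Multiply-accumulate cost ratio of octave vs ordinary convolution
#'
#' For a kernel with low-frequency fraction `alpha` on both sides, the MAC
#' count relative to a dense convolution at full resolution is
#' `(1-alpha)^2 + alpha*(1-alpha)/2 + alpha^2/4`: low-resolution paths run on
#' quarter-area maps. At `alpha = 0.5` this is 7/16; it approaches 1/4 only
#' as `alpha` tends to 1.
#'
#' @param alpha Low-frequency channel fraction.
#' @return Numeric cost ratio in `(0, 1]`.
#' @export
oct_conv_cost_ratio <- function(alpha) {
  (1 - alpha)^2 + alpha * (1 - alpha) / 2 + alpha^2 / 4
}
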