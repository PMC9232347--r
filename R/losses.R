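#' Soft Tversky index
#'
#' Asymmetric overlap between a probability map and a crisp reference:
#' `TI = (|X∩Y| + s) / (|X∩Y| + alpha |X−Y| + beta |Y−X| + s)` with the soft
#' set operations `|X∩Y| = Σ x·y`, `|X−Y| = Σ x·(1−y)` (missed foreground,
#' false negatives) and `|Y−X| = Σ (1−x)·y` (spurious foreground, false
#' positives). `alpha = beta = 0.5` reduces to the Dice coefficient and
#' `alpha = beta = 1` to Jaccard. The smoothing term `s` keeps the index
#' defined (and equal to 1) when both masks are empty.
#'
#' @param pred Probability raster in `[0, 1]` (the prediction `Y`).
#' @param truth Binary raster (the reference `X`); logical or 0/1 numeric.
#' @param alpha Weight of missed foreground (false negatives).
#' @param beta Weight of spurious foreground (false positives).
#' @param smooth Smoothing constant `s` (default 1).
#' @return Scalar in `[0, 1]`.
#' @export
tversky_index <- function(pred, truth, alpha = 0.7, beta = 0.3, smooth = 1) {
  check_loss_pair(pred, truth)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  y <- as.numeric(pred)
  x <- as.numeric(truth)
  s <- sum(x * y)
  (s + smooth) / (s + alpha * sum(x * (1 - y)) + beta * sum((1 - x) * y) + smooth)
}

#' Focal Tversky loss
#'
#' `FTL = (1 − TI)^gamma` for the foreground class; `gamma > 1` up-weights
#' hard, low-overlap examples and `gamma = 1` recovers the plain Tversky
#' loss. `gamma` is restricted to `[1, 3]`.
#'
#' @inheritParams tversky_index
#' @param gamma Focal exponent in `[1, 3]`.
#' @return Scalar loss, 0 at a perfect prediction.
#' @export
focal_tversky_loss <- function(pred, truth, alpha = 0.7, beta = 0.3,
                               gamma = 2, smooth = 1) {
  if (gamma < 1 || gamma > 3) stop("gamma must lie in [1, 3]")
  ti <- tversky_index(pred, truth, alpha, beta, smooth)
  (1 - ti)^gamma
}

#' Dice loss
#'
#' `1 − TI` at `alpha = beta = 0.5`, i.e. one minus the (soft) Dice
#' coefficient — a standard baseline objective in medical segmentation.
#'
#' @inheritParams tversky_index
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, smooth = 1) {
  1 - tversky_index(pred, truth, alpha = 0.5, beta = 0.5, smooth = smooth)
}

#' Mean binary cross-entropy loss
#'
#' Per-pixel binary cross-entropy of a probability map against a crisp mask,
#' averaged over pixels. Probabilities are clipped to `(clip, 1 − clip)`
#' before taking logarithms.
#'
#' @inheritParams tversky_index
#' @param clip Clipping constant (default `1e-7`).
#' @return Scalar loss (non-negative).
#' @export
cross_entropy_loss <- function(pred, truth, clip = 1e-7) {
  check_loss_pair(pred, truth)
  y <- pmin(pmax(as.numeric(pred), clip), 1 - clip)
  x <- as.numeric(truth)
  -mean(x * log(y) + (1 - x) * log(1 - y))
}

check_loss_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) &&
      length(pred) != length(truth)) {
    stop("prediction and truth must have identical shape")
  }
  if (!is.null(dim(pred)) && !is.null(dim(truth)) &&
      !identical(as.integer(dim(pred)), as.integer(dim(truth)))) {
    stop("prediction and truth must have identical shape")
  }
  pv <- as.numeric(pred)
  if (any(!is.finite(pv)) || any(pv < 0) || any(pv > 1)) {
    stop("prediction must be a finite probability raster in [0, 1]")
  }
  invisible(NULL)
}
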