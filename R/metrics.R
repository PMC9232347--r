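# Pixel-overlap evaluation suite. A is the reference annotation (expert
# mask), B the algorithm's segmentation. All metrics are computed with exact
# integer pixel counts before any division.

as_mask <- function(m, name = "mask") {
  if (is.logical(m)) return(m)
  if (is.numeric(m)) return(m != 0)
  stop(sprintf("%s must be a logical or 0/1 numeric raster", name))
}

check_same_shape <- function(a, b) {
  if (!identical(as.integer(dim(a)), as.integer(dim(b)))) {
    stop("masks must have identical shape")
  }
  invisible(NULL)
}

#' Area-overlap metrics between an annotation and a segmentation
#'
#' Computes, from exact pixel counts:
#' * `AOM = |A∩B| / |A∪B|` — area overlap (Jaccard index);
#' * `AVM = |A−B| / |A|` — fraction of the annotation missed;
#' * `AUM = |B−A| / |B|` — fraction of the segmentation outside the annotation;
#' * `CM  = (AOM + (1−AVM) + (1−AUM)) / 3` — combined measure;
#' * `sen = TP/(TP+FN)` and `spe = TP/(TP+FP)` (the latter is the precision
#'   form; the conventional specificity `TN/(TN+FP)` is also reported as
#'   `spe_conventional`).
#'
#' An empty annotation leaves `AVM` undefined and is an error. An empty
#' segmentation against a non-empty annotation yields `AOM = 0`, `AVM = 1`
#' and, by convention, `AUM = 1` (maximal under-coverage penalty) with a
#' warning, so that `CM` stays defined.
#'
#' @param A Annotation mask (logical/0-1 matrix).
#' @param B Predicted mask, same shape.
#' @return A list of class `metrics_report` with the six metrics and the
#'   confusion `counts`.
#' @export
overlap_metrics <- function(A, B) {
  A <- as_mask(A, "A")
  B <- as_mask(B, "B")
  check_same_shape(A, B)
  na <- sum(A)
  nb <- sum(B)
  if (na == 0L) stop("annotation mask A is empty: AVM is undefined")
  inter <- sum(A & B)
  uni <- sum(A | B)
  cnt <- confusion_counts(A, B)
  if (nb == 0L) {
    warning("empty segmentation B: AUM set to 1 by convention")
    aom <- 0
    avm <- 1
    aum <- 1
    spe <- NA_real_
  } else {
    aom <- inter / uni
    avm <- (na - inter) / na
    aum <- (nb - inter) / nb
    spe <- cnt$TP / (cnt$TP + cnt$FP)
  }
  cm <- (aom + (1 - avm) + (1 - aum)) / 3
  sen <- cnt$TP / (cnt$TP + cnt$FN)
  spe_conv <- if (cnt$TN + cnt$FP > 0) cnt$TN / (cnt$TN + cnt$FP) else NA_real_
  structure(list(AOM = aom, AVM = avm, AUM = aum, CM = cm,
                 sen = sen, spe = spe, spe_conventional = spe_conv,
                 counts = cnt),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "AOM %.4f  AVM %.4f  AUM %.4f  CM %.4f  Sen %.4f  Spe %.4f\n",
    x$AOM, x$AVM, x$AUM, x$CM, x$sen, x$spe))
  invisible(x)
}

#' Pixel confusion counts
#'
#' `TP = |A∩B|`, `FP = |B−A|`, `FN = |A−B|`, `TN` the remainder; the four
#' counts always sum to the pixel total.
#'
#' @inheritParams overlap_metrics
#' @return List with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(A, B) {
  A <- as_mask(A, "A")
  B <- as_mask(B, "B")
  check_same_shape(A, B)
  tp <- sum(A & B)
  fp <- sum(B & !A)
  fn <- sum(A & !B)
  tn <- length(A) - tp - fp - fn
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Sensitivity and Spe from confusion counts
#'
#' `Sen = TP/(TP+FN)`; `Spe = TP/(TP+FP)` — note this is the precision form,
#' kept for comparability with the reporting convention this package follows;
#' use `TN/(TN+FP)` (reported by [overlap_metrics()] as `spe_conventional`)
#' for the textbook specificity.
#'
#' @param counts List with `TP`, `FP`, `TN`, `FN` (see [confusion_counts()]).
#' @return Named numeric vector `c(sen, spe)`.
#' @export
sen_spe <- function(counts) {
  if (counts$TP + counts$FN == 0) {
    stop("Sen undefined: annotation has no foreground pixels (TP + FN = 0)")
  }
  if (counts$TP + counts$FP == 0) {
    stop("Spe undefined: prediction has no foreground pixels (TP + FP = 0)")
  }
  c(sen = counts$TP / (counts$TP + counts$FN),
    spe = counts$TP / (counts$TP + counts$FP))
}

#' Pixel-pooled ROC curve of a probability map
#'
#' Sweeps the decision threshold over the unique probability values of `p`
#' (pixels with `p >= t` predicted foreground), returning one
#' (FPR, TPR) point per threshold plus the (0, 0) endpoint, and the
#' trapezoidal area under the curve. A constant map yields the chance
#' diagonal (area 0.5).
#'
#' @param p Probability raster in `[0, 1]`.
#' @param A Annotation mask, same shape, containing both classes.
#' @return A `data.frame` with columns `threshold`, `fpr`, `tpr`, with the
#'   area under the curve in attribute `"auc"`.
#' @export
roc_curve <- function(p, A) {
  A <- as_mask(A, "A")
  check_same_shape(p, A)
  npos <- sum(A)
  nneg <- sum(!A)
  if (npos == 0L || nneg == 0L) {
    stop("ROC undefined: annotation must contain both classes")
  }
  pv <- as.numeric(p)
  av <- as.logical(A)
  ord <- order(pv, decreasing = TRUE)
  pv <- pv[ord]
  av <- av[ord]
  ctp <- cumsum(av)
  cfp <- cumsum(!av)
  last <- c(pv[-1] != pv[-length(pv)], TRUE) # last index of each tied block
  tpr <- ctp[last] / npos
  fpr <- cfp[last] / nneg
  thr <- pv[last]
  df <- data.frame(threshold = c(Inf, thr),
                   fpr = c(0, fpr),
                   tpr = c(0, tpr))
  auc <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) + utils::tail(df$tpr, -1)) / 2)
  attr(df, "auc") <- auc
  df
}
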