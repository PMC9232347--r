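# Sequence-level preprocessing: collapse a video into a maximum-intensity
# projection, then extract the ultrasound sector (the fan-shaped field of
# view) by automatic thresholding and morphological refinement.

#' Construct an echocardiography video sequence
#'
#' Wraps an ordered list of equally sized grayscale frames. By default the
#' frames are jointly min-max rescaled to `[0, 1]` over the whole sequence,
#' which preserves inter-frame intensity relations (per-frame scaling would
#' not).
#'
#' @param frames List of numeric matrices, all of identical dimension.
#' @param frame_period Optional seconds per frame.
#' @param normalize Min-max rescale over the sequence (default `TRUE`).
#' @return Object of class `echo_sequence`.
#' @export
echo_sequence <- function(frames, frame_period = NULL, normalize = TRUE) {
  if (length(frames) < 1L) stop("a sequence needs at least one frame")
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("all frames must be numeric matrices")
  }
  d0 <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d0), logical(1))
  if (!all(ok)) stop("all frames must share the same height x width")
  vals <- unlist(frames, use.names = FALSE)
  if (any(!is.finite(vals))) stop("frame intensities must be finite")
  if (normalize) {
    lo <- min(vals)
    hi <- max(vals)
    frames <- if (hi > lo) {
      lapply(frames, function(f) (f - lo) / (hi - lo))
    } else {
      lapply(frames, function(f) f - lo)
    }
  } else if (min(vals) < 0 || max(vals) > 1) {
    stop("intensities outside [0, 1]; use normalize = TRUE")
  }
  structure(list(frames = frames, frame_period = frame_period),
            class = "echo_sequence")
}

#' Maximum-intensity projection of a video sequence
#'
#' Per-pixel maximum over all frames: `M(x, y) = max_k I_k(x, y)`. Every
#' pixel ever insonified over the cardiac cycle stays bright, which reveals
#' the full sector even though single frames only light up part of it.
#'
#' @param seq An [echo_sequence()] or a plain list of matrices.
#' @return Numeric matrix of the same size as the frames.
#' @export
max_intensity_projection <- function(seq) {
  frames <- if (is.list(seq) && !is.null(seq$frames)) seq$frames else seq
  if (length(frames) < 1L) stop("cannot project an empty sequence")
  d0 <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d0), logical(1))
  if (!all(ok)) stop("all frames must share the same height x width")
  Reduce(pmax, frames)
}

#' Automatic global thresholding of a projection image
#'
#' Foreground is every pixel at or above a global threshold chosen by Otsu's
#' method (256-bin histogram over `[0, 1]`, maximizing the between-class
#' variance), or a fixed fraction of the intensity range if
#' `method = "fixed"`. A constant image has no two-class separation and is
#' returned fully foreground with a warning.
#'
#' @param proj Numeric matrix (the projection), finite values.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed Threshold used when `method = "fixed"`.
#' @return Logical matrix; the chosen threshold is attached as attribute
#'   `"threshold"`.
#' @export
threshold_projection <- function(proj, method = c("otsu", "fixed"), fixed = 0.5) {
  method <- match.arg(method)
  if (any(!is.finite(proj))) stop("projection must be finite")
  rng <- range(proj)
  if (rng[1] == rng[2]) {
    warning("constant image: no two-class separation, returning all-foreground")
    out <- matrix(TRUE, nrow(proj), ncol(proj))
    attr(out, "threshold") <- rng[1]
    return(out)
  }
  th <- if (method == "otsu") {
    as.numeric(EBImage::otsu(EBImage::Image(proj), range = c(0, 1), levels = 256))
  } else {
    fixed
  }
  out <- proj >= th
  attr(out, "threshold") <- th
  out
}

#' Refine a raw threshold mask into a single sector region
#'
#' Morphological closing then opening with a disk structuring element, then
#' retention of the largest 8-connected component; interior holes of the
#' surviving component (for instance the persistently dark chamber in the
#' projection) are filled by default since the sector is a solid region.
#'
#' @param raw Logical matrix from [threshold_projection()].
#' @param radius Disk radius in pixels for both closing and opening
#'   (default 5).
#' @param fill_holes Fill interior holes of the final component
#'   (default `TRUE`).
#' @return Object of class `sector_mask`: list with logical `mask` and the
#'   pixel count `area_px`.
#' @export
refine_sector <- function(raw, radius = 5, fill_holes = TRUE) {
  raw <- as_mask(raw, "raw")
  if (!any(raw)) stop("no foreground pixels to refine")
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  img <- EBImage::Image(raw * 1)
  img <- EBImage::opening(EBImage::closing(img, brush), brush)
  m <- EBImage::imageData(img) > 0.5
  if (!any(m)) stop("morphological opening removed all foreground")
  lab <- cpp_label8(matrix(as.integer(m), nrow(m)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  m <- lab == keep
  if (fill_holes) {
    m <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0.5
  }
  area <- sum(m)
  if (area == 0L || area >= length(m)) {
    stop("degenerate sector: foreground area must satisfy 0 < area < total")
  }
  structure(list(mask = m, area_px = area), class = "sector_mask")
}

#' Count 8-connected foreground components
#'
#' @param mask Logical matrix.
#' @return Integer component count.
#' @export
count_components <- function(mask) {
  mask <- as_mask(mask)
  max(cpp_label8(matrix(as.integer(mask), nrow(mask))))
}

#' Restrict a frame to the detected sector
#'
#' Pixels outside the sector are set to 0; pixels inside are unchanged.
#'
#' @param frame Numeric matrix.
#' @param sector A [refine_sector()] result (or logical matrix).
#' @return Numeric matrix, same shape as `frame`.
#' @export
apply_sector <- function(frame, sector) {
  m <- if (inherits(sector, "sector_mask")) sector$mask else as_mask(sector)
  if (!identical(dim(frame), dim(m))) stop("frame and sector shapes differ")
  frame * m
}

#' Full sector-detection pipeline for one sequence
#'
#' Convenience wrapper: projection, thresholding, refinement.
#'
#' @param seq An [echo_sequence()] or list of frames.
#' @param radius Morphology disk radius.
#' @return List with `projection`, `raw` threshold mask and `sector`.
#' @export
detect_sector <- function(seq, radius = 5) {
  proj <- max_intensity_projection(seq)
  raw <- threshold_projection(proj)
  sector <- refine_sector(raw, radius = radius)
  list(projection = proj, raw = raw, sector = sector)
}
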