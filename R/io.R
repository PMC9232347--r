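# PNG frame-stack I/O and dataset manifests. Frames are written as 8-bit
# grayscale PNGs named frame_%03d.png (masks mask_%03d.png) so lexicographic
# order is frame order.

#' Write a phantom or sequence as a PNG frame stack
#'
#' @param seq An `echo_phantom` or [echo_sequence()].
#' @param dir Output directory (created if missing).
#' @param masks Also write ground-truth masks if present.
#' @return The directory, invisibly.
#' @export
write_sequence_png <- function(seq, dir, masks = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[t]], file.path(dir, sprintf("frame_%03d.png", t)))
  }
  if (masks && !is.null(seq$masks)) {
    for (t in seq_along(seq$masks)) {
      png::writePNG(seq$masks[[t]] * 1, file.path(dir, sprintf("mask_%03d.png", t)))
    }
  }
  if (!is.null(seq$sector)) {
    png::writePNG(seq$sector * 1, file.path(dir, "sector_true.png"))
  }
  invisible(dir)
}

#' Read a PNG frame stack as an echo sequence
#'
#' Frames are read in lexicographic order of `frame_*.png`; `mask_*.png`
#' files, when present, are attached as logical masks.
#'
#' @param dir Directory containing the stack.
#' @param normalize Min-max normalize intensities over the sequence.
#' @return An [echo_sequence()]; masks (if any) in the `masks` field.
#' @export
read_sequence_png <- function(dir, normalize = TRUE) {
  ff <- sort(list.files(dir, pattern = "^frame_.*\\.png$", full.names = TRUE))
  if (length(ff) == 0L) stop("no frame_*.png files in ", dir)
  frames <- lapply(ff, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  seq <- echo_sequence(frames, normalize = normalize)
  mf <- sort(list.files(dir, pattern = "^mask_.*\\.png$", full.names = TRUE))
  if (length(mf) > 0L) {
    seq$masks <- lapply(mf, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img > 0.5
    })
  }
  sf <- file.path(dir, "sector_true.png")
  if (file.exists(sf)) seq$sector <- png::readPNG(sf) > 0.5
  seq
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
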