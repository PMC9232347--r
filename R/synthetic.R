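# Seeded synthetic echocardiography phantom: a fan-shaped field of view
# containing a bright myocardial band around a dark chamber whose area
# modulates periodically (diastole/systole), degraded by multiplicative
# speckle. Emulates the data regime of a dynamic ultrasound study (sector
# geometry, periodic contraction, heavy multiplicative noise) without
# attempting anatomical realism.

#' Phantom configuration
#'
#' Geometry is expressed in pixels of an `height x width` frame. The chamber
#' is an ellipse whose semi-axes scale by `1 − a (1 − cos(2 pi t / T)) / 2`
#' over the cycle (`a = contraction`, `T = cycle_frames`), so frame 0 is full
#' dilation and mid-cycle is maximal contraction (`1 − a`). The myocardial
#' wall is the band between the current chamber and a fixed outer ellipse
#' (`wall_scale` times the base axes). Speckle is multiplicative: two
#' unit-variance Gaussian fields (optionally PSF-smoothed and
#' re-standardized) are squared and averaged — a Rayleigh-power-like field
#' with unit mean — and blended as `(1 − w) + w n` with
#' `w = speckle_weight`.
#'
#' @param height,width Frame size in pixels (default 128 x 128; 600 x 800
#'   scale is supported but slow on one CPU).
#' @param n_frames Frames per sequence.
#' @param cycle_frames Cardiac cycle length in frames (>= 2).
#' @param apex `(y, x)` of the sector apex.
#' @param sector_angle Full opening angle of the sector, degrees.
#' @param sector_radius Sector radius in pixels.
#' @param chamber_center `(y, x)` of the chamber ellipse center.
#' @param chamber_axes `(a_y, a_x)` base (fully dilated) semi-axes.
#' @param contraction Relative semi-axis contraction amplitude in `[0, 1)`.
#' @param wall_scale Outer wall ellipse axes as a multiple of the base axes.
#' @param chamber_intensity,tissue_intensity,wall_intensity Noise-free
#'   intensities of chamber blood pool, surrounding tissue, and myocardium.
#' @param speckle_weight Blend weight `w` of the multiplicative speckle
#'   field in `[0, 1]`; 0 disables noise.
#' @param speckle_smooth Gaussian sigma (pixels) of the point-spread
#'   smoothing applied to the underlying Gaussian fields; 0 for white
#'   speckle.
#' @param jitter_center,jitter_axes Relative per-sequence geometry jitter
#'   used by [generate_dataset()] (uniform, e.g. 0.04 means +/-4%).
#' @param random_phase Draw a random cycle phase per sequence in
#'   [generate_dataset()].
#' @param seed Seed for the speckle fields of [generate_sequence()].
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(height = 128, width = 128,
                           n_frames = 8, cycle_frames = 8,
                           apex = c(0.03 * height, 0.5 * width),
                           sector_angle = 70,
                           sector_radius = 0.92 * height,
                           chamber_center = c(0.55 * height, 0.5 * width),
                           chamber_axes = c(0.22 * height, 0.16 * width),
                           contraction = 0.3,
                           wall_scale = 1.35,
                           chamber_intensity = 0.12,
                           tissue_intensity = 0.40,
                           wall_intensity = 0.85,
                           speckle_weight = 0.5,
                           speckle_smooth = 1,
                           jitter_center = 0.04,
                           jitter_axes = 0.10,
                           random_phase = TRUE,
                           seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_frames = as.integer(n_frames),
              cycle_frames = as.integer(cycle_frames),
              apex = as.numeric(apex), sector_angle = sector_angle,
              sector_radius = sector_radius,
              chamber_center = as.numeric(chamber_center),
              chamber_axes = as.numeric(chamber_axes),
              contraction = contraction, wall_scale = wall_scale,
              chamber_intensity = chamber_intensity,
              tissue_intensity = tissue_intensity,
              wall_intensity = wall_intensity,
              speckle_weight = speckle_weight,
              speckle_smooth = speckle_smooth,
              jitter_center = jitter_center, jitter_axes = jitter_axes,
              random_phase = random_phase,
              phase = 0,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

sector_mask_for <- function(cfg) {
  yy <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  xx <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  dy <- yy - cfg$apex[1]
  dx <- xx - cfg$apex[2]
  dist <- sqrt(dy^2 + dx^2)
  ang <- atan2(abs(dx), dy) # angle from the downward probe axis
  (dy >= 0) & (dist <= cfg$sector_radius) &
    (ang <= (cfg$sector_angle / 2) * pi / 180)
}

ellipse_mask <- function(cfg, ay, ax) {
  yy <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  xx <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  ((yy - cfg$chamber_center[1]) / ay)^2 + ((xx - cfg$chamber_center[2]) / ax)^2 <= 1
}

validate_phantom_config <- function(cfg) {
  if (cfg$cycle_frames < 2L) stop("cycle_frames must be >= 2")
  if (cfg$contraction < 0 || cfg$contraction >= 1) {
    stop("contraction amplitude must lie in [0, 1)")
  }
  if (cfg$n_frames < 1L) stop("n_frames must be >= 1")
  sec <- sector_mask_for(cfg)
  outer <- ellipse_mask(cfg, cfg$chamber_axes[1] * cfg$wall_scale,
                        cfg$chamber_axes[2] * cfg$wall_scale)
  if (any(outer & !sec)) {
    stop("chamber (with wall) escapes the sector at maximal dilation")
  }
  invisible(cfg)
}

speckle_field <- function(cfg) {
  n <- cfg$height * cfg$width
  g1 <- matrix(stats::rnorm(n), cfg$height, cfg$width)
  g2 <- matrix(stats::rnorm(n), cfg$height, cfg$width)
  if (cfg$speckle_smooth > 0) {
    g1 <- EBImage::imageData(EBImage::gblur(EBImage::Image(g1), sigma = cfg$speckle_smooth))
    g2 <- EBImage::imageData(EBImage::gblur(EBImage::Image(g2), sigma = cfg$speckle_smooth))
    g1 <- g1 / stats::sd(as.numeric(g1))
    g2 <- g2 / stats::sd(as.numeric(g2))
  }
  (g1^2 + g2^2) / 2
}

#' Generate one synthetic echocardiography sequence
#'
#' Geometry (sector, chamber, wall) is deterministic from the configuration;
#' only the speckle fields consume randomness, seeded by `cfg$seed`, so the
#' same configuration always yields a bit-identical phantom.
#'
#' @param cfg A [phantom_config()].
#' @return Object of class `echo_phantom`: list with `frames` (speckled
#'   intensity matrices in `[0, 1]`), `clean` (noise-free frames), `masks`
#'   (logical chamber ground truth per frame), `sector` (the true sector
#'   mask) and `config`.
#' @export
generate_sequence <- function(cfg) {
  validate_phantom_config(cfg)
  sec <- sector_mask_for(cfg)
  frames <- vector("list", cfg$n_frames)
  clean <- vector("list", cfg$n_frames)
  masks <- vector("list", cfg$n_frames)
  outer <- ellipse_mask(cfg, cfg$chamber_axes[1] * cfg$wall_scale,
                        cfg$chamber_axes[2] * cfg$wall_scale)
  with_seed(cfg$seed, {
    for (t in seq_len(cfg$n_frames)) {
      ph <- (t - 1 + cfg$phase) / cfg$cycle_frames
      s <- 1 - cfg$contraction * (1 - cos(2 * pi * ph)) / 2
      chamber <- ellipse_mask(cfg, cfg$chamber_axes[1] * s, cfg$chamber_axes[2] * s)
      img <- matrix(0, cfg$height, cfg$width)
      img[sec] <- cfg$tissue_intensity
      img[outer & sec] <- cfg$wall_intensity
      img[chamber & sec] <- cfg$chamber_intensity
      clean[[t]] <- img
      if (cfg$speckle_weight > 0) {
        mult <- (1 - cfg$speckle_weight) + cfg$speckle_weight * speckle_field(cfg)
        img <- pmin(pmax(img * mult, 0), 1)
      }
      frames[[t]] <- img
      masks[[t]] <- chamber & sec
    }
  })
  structure(list(frames = frames, clean = clean, masks = masks,
                 sector = sec, config = cfg),
            class = "echo_phantom")
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + i * 7919) %% 2147483629)
}

#' Generate a train/test phantom dataset
#'
#' Draws independent per-sequence sub-seeds and per-sequence geometry jitter
#' (chamber center and axes, cycle phase) from the master seed, then splits
#' the sequences — never individual frames, which would leak a sequence's
#' speckle and geometry across the split — into disjoint train and test sets.
#'
#' @param cfg A [phantom_config()] used as the template for every sequence.
#' @param n_sequences Number of sequences (>= 2); the study regime this
#'   emulates used 50.
#' @param split_ratio Fraction of sequences assigned to training
#'   (default 0.5, a 1:1 split).
#' @param seed Master seed controlling sub-seeds, jitter, and the split.
#' @return List with `train` and `test`, each a list of `echo_phantom`
#'   objects carrying an `id` field.
#' @export
generate_dataset <- function(cfg, n_sequences, split_ratio = 0.5, seed = 1L) {
  if (n_sequences < 2L) stop("need at least 2 sequences to split")
  phantoms <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    sub <- derive_seed(seed, i)
    cfg_i <- with_seed(sub, {
      ci <- cfg
      jc <- cfg$jitter_center
      ja <- cfg$jitter_axes
      ci$chamber_center <- cfg$chamber_center *
        (1 + stats::runif(2, -jc, jc))
      ci$chamber_axes <- cfg$chamber_axes * (1 + stats::runif(2, -ja, ja))
      if (isTRUE(cfg$random_phase)) {
        ci$phase <- stats::runif(1, 0, cfg$cycle_frames)
      }
      ci$seed <- derive_seed(sub, 1L)
      ci
    })
    ph <- generate_sequence(cfg_i)
    ph$id <- i
    phantoms[[i]] <- ph
  }
  n_train <- round(n_sequences * split_ratio)
  ids <- with_seed(seed, sample.int(n_sequences))
  train_ids <- sort(ids[seq_len(n_train)])
  test_ids <- sort(ids[-seq_len(n_train)])
  list(train = phantoms[train_ids], test = phantoms[test_ids])
}

#' Directional motion blur degradation
#'
#' Applies a vertical box blur of odd length along the dominant wall-motion
#' axis to every frame — a stress model for the motion blur that fast cardiac
#' phases produce in ultrasound. Edge rows are handled by replication, so a
#' constant image is unchanged.
#'
#' @param seq An `echo_phantom`, [echo_sequence()] or list of frames.
#' @param length Odd kernel length (1 = identity).
#' @return Same class as the input with blurred frames.
#' @export
degrade_motion_blur <- function(seq, length = 5) {
  if (length < 1 || length %% 2 != 1) stop("kernel length must be odd and >= 1")
  blur1 <- function(m) {
    if (length == 1) return(m)
    pad <- (length - 1) / 2
    mp <- rbind(m[rep(1L, pad), , drop = FALSE], m,
                m[rep(nrow(m), pad), , drop = FALSE])
    out <- apply(mp, 2, function(col) {
      as.numeric(stats::filter(col, rep(1 / length, length), sides = 2))
    })
    out[(pad + 1):(pad + nrow(m)), , drop = FALSE]
  }
  if (inherits(seq, "echo_phantom") || inherits(seq, "echo_sequence")) {
    seq$frames <- lapply(seq$frames, blur1)
    seq
  } else {
    lapply(seq, blur1)
  }
}
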