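# The segmentation model: a nested U-Net++ grid whose every node carries a
# dual-frequency (octave) feature pair. Encoder column j = 0 starts with an
# initial octave convolution establishing the split and downsamples between
# levels by 2x2 average pooling per stream; each decoder node bilinearly
# upsamples its lower-level predecessor, concatenates all same-level
# same-scale predecessors, applies CBAM to the fused high-frequency stream,
# and runs a block of octave convolutions. The head merges the two streams
# (final octave convolution) into one channel followed by a sigmoid.

#' Network configuration
#'
#' @param depth Number of resolution levels (default 5; >= 2). Input spatial
#'   dimensions must be divisible by `2^depth` (the deepest low-frequency
#'   stream lives at `1/2^depth` scale); inputs that are not are letterbox
#'   zero-padded and the output cropped back.
#' @param base_channels Channels at the top level, doubling per level
#'   (default 32).
#' @param alpha Octave low-frequency channel fraction for all interior
#'   layers (default 0.5); the stem enters all-high and the head leaves
#'   all-high.
#' @param cbam_r CBAM reduction ratio (default 16, hidden width clamped to
#'   >= 1).
#' @param kernel Odd convolution kernel size (default 3).
#' @param block_convs Octave convolutions per grid node (default 2).
#' @param upsample Decoder interpolation, `"bilinear"` (default) or
#'   `"nearest"`.
#' @param octconv_upsample Interpolation on the low-to-high path inside each
#'   octave convolution (default `"nearest"`).
#' @param cbam_streams Apply CBAM to the `"high"` stream only (default) or
#'   to `"both"` streams at skip fusions.
#' @param in_channels Input image channels (default 1, grayscale).
#' @return Object of class `network_config`.
#' @export
network_config <- function(depth = 5, base_channels = 32, alpha = 0.5,
                           cbam_r = 16, kernel = 3, block_convs = 2,
                           upsample = c("bilinear", "nearest"),
                           octconv_upsample = c("nearest", "bilinear"),
                           cbam_streams = c("high", "both"),
                           in_channels = 1) {
  if (depth < 2) stop("depth must be >= 2")
  if (base_channels < 1) stop("base_channels must be >= 1")
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (kernel %% 2 != 1) stop("kernel size must be odd")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 alpha = alpha, cbam_r = cbam_r, kernel = as.integer(kernel),
                 block_convs = as.integer(block_convs),
                 upsample = match.arg(upsample),
                 octconv_upsample = match.arg(octconv_upsample),
                 cbam_streams = match.arg(cbam_streams),
                 in_channels = as.integer(in_channels)),
            class = "network_config")
}

# ---- parameter construction ------------------------------------------------

new_oct_layer <- function(cin_h, cin_l, cout_h, cout_l, k, norm = TRUE,
                          bias = !norm) {
  fan_in <- k * k * (cin_h + cin_l)
  he <- function(ci, co) {
    if (ci == 0L || co == 0L) return(NULL)
    ad_param(matrix(stats::rnorm(k * k * ci * co, sd = sqrt(2 / fan_in)),
                    k * k * ci, co))
  }
  ly <- list(type = "oct", k = k,
             cin_h = cin_h, cin_l = cin_l, cout_h = cout_h, cout_l = cout_l,
             Whh = he(cin_h, cout_h), Whl = he(cin_h, cout_l),
             Wlh = he(cin_l, cout_h), Wll = he(cin_l, cout_l),
             norm = norm, bias = NULL)
  if (bias) {
    ly$bias_h <- ad_param(numeric(cout_h))
    if (cout_l > 0L) ly$bias_l <- ad_param(numeric(cout_l))
  }
  if (norm) {
    mknorm <- function(c) {
      st <- new.env(parent = emptyenv())
      st$mean <- numeric(c)
      st$var <- rep(1, c)
      list(gamma = ad_param(rep(1, c)), beta = ad_param(numeric(c)), state = st)
    }
    ly$norm_h <- mknorm(cout_h)
    if (cout_l > 0L) ly$norm_l <- mknorm(cout_l)
  }
  ly
}

new_cbam_layer <- function(channels, r, k = 7) {
  hidden <- max(1L, as.integer(floor(channels / r)))
  list(type = "cbam", channels = channels, hidden = hidden, k = k,
       W1 = ad_param(matrix(stats::rnorm(hidden * channels, sd = sqrt(2 / channels)),
                            hidden, channels)),
       b1 = ad_param(numeric(hidden)),
       W2 = ad_param(matrix(stats::rnorm(channels * hidden, sd = sqrt(2 / hidden)),
                            channels, hidden)),
       b2 = ad_param(numeric(channels)),
       Ws = ad_param(matrix(stats::rnorm(k * k * 2, sd = sqrt(2 / (k * k * 2))),
                            k * k * 2, 1)),
       bs = ad_param(0))
}

collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "ad_param")) {
    out[[prefix]] <- x
  } else if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (is.null(nms) || nms[i] == "") as.character(i) else nms[i]
      if (nm == "state") next
      out <- c(out, collect_params(x[[i]], paste0(prefix, ".", nm)))
    }
  }
  out
}

#' Build the segmentation model
#'
#' Constructs the nested grid `X^{i,j}` for `i + j < depth` (`depth(depth+1)/2`
#' nodes), with seeded, reproducible parameter initialization.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `echo_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  d <- cfg$depth
  ch <- cfg$base_channels * 2^(0:(d - 1))
  sp <- lapply(ch, split_channels, alpha = cfg$alpha)
  model <- with_seed(seed, {
    nodes <- list()
    for (j in 0:(d - 1)) {
      for (i in 0:(d - 1 - j)) {
        key <- node_key(i, j)
        blocks <- vector("list", cfg$block_convs)
        if (j == 0 && i == 0) {
          # stem: all-high input, establish the split
          blocks[[1]] <- new_oct_layer(cfg$in_channels, 0L,
                                       sp[[1]]["high"], sp[[1]]["low"],
                                       cfg$kernel)
        } else if (j == 0) {
          blocks[[1]] <- new_oct_layer(sp[[i]]["high"], sp[[i]]["low"],
                                       sp[[i + 1]]["high"], sp[[i + 1]]["low"],
                                       cfg$kernel)
        } else {
          # skip fusion: j same-level predecessors plus the upsampled
          # lower-level node
          cat_h <- j * sp[[i + 1]]["high"] + sp[[i + 2]]["high"]
          cat_l <- j * sp[[i + 1]]["low"] + sp[[i + 2]]["low"]
          blocks[[1]] <- new_oct_layer(cat_h, cat_l,
                                       sp[[i + 1]]["high"], sp[[i + 1]]["low"],
                                       cfg$kernel)
        }
        if (cfg$block_convs > 1) {
          for (bidx in 2:cfg$block_convs) {
            blocks[[bidx]] <- new_oct_layer(sp[[i + 1]]["high"], sp[[i + 1]]["low"],
                                            sp[[i + 1]]["high"], sp[[i + 1]]["low"],
                                            cfg$kernel)
          }
        }
        nd <- list(blocks = blocks)
        if (j > 0) {
          cat_h <- j * sp[[i + 1]]["high"] + sp[[i + 2]]["high"]
          cat_l <- j * sp[[i + 1]]["low"] + sp[[i + 2]]["low"]
          nd$cbam <- new_cbam_layer(cat_h, cfg$cbam_r)
          if (cfg$cbam_streams == "both" && cat_l > 0L) {
            nd$cbam_low <- new_cbam_layer(cat_l, cfg$cbam_r)
          }
        }
        nodes[[key]] <- nd
      }
    }
    head <- new_oct_layer(sp[[1]]["high"], sp[[1]]["low"], 1L, 0L,
                          cfg$kernel, norm = FALSE, bias = TRUE)
    list(cfg = cfg, nodes = nodes, head = head, seed = as.integer(seed))
  })
  model$params <- collect_params(list(nodes = model$nodes, head = model$head),
                                 "model")
  model$opt <- new.env(parent = emptyenv())
  model$opt$t <- 0L
  class(model) <- "echo_model"
  model
}

node_key <- function(i, j) sprintf("x%d.%d", i, j)

#' Number of grid nodes of the nested topology
#'
#' `depth (depth + 1) / 2` — one encoder column plus the dense triangle of
#' decoder nodes.
#'
#' @param model An `echo_model`.
#' @return Integer node count.
#' @export
model_node_count <- function(model) length(model$nodes)

#' Per-layer channel inventory
#'
#' One row per octave convolution with its high/low input and output channel
#' counts; useful for checking channel conservation
#' (`c_out_high + c_out_low = c_out`) and the `alpha = 0` degeneracy to a
#' plain-convolution network (all low counts zero).
#'
#' @param model An `echo_model`.
#' @return A `data.frame`.
#' @export
model_layer_table <- function(model) {
  rows <- list()
  add <- function(name, ly) {
    rows[[length(rows) + 1]] <<- data.frame(
      layer = name,
      cin_high = as.integer(ly$cin_h), cin_low = as.integer(ly$cin_l),
      cout_high = as.integer(ly$cout_h), cout_low = as.integer(ly$cout_l),
      cout_total = as.integer(ly$cout_h + ly$cout_l))
  }
  for (key in names(model$nodes)) {
    blocks <- model$nodes[[key]]$blocks
    for (b in seq_along(blocks)) add(sprintf("%s.conv%d", key, b), blocks[[b]])
  }
  add("head", model$head)
  do.call(rbind, rows)
}

# ---- forward ---------------------------------------------------------------

oct_layer_forward <- function(tp, ly, xh, xl, training, up_mode, act = TRUE) {
  k <- ly$k
  leaf <- function(p) if (is.null(p)) NULL else tp_leaf(tp, p)
  yh <- NULL
  yl <- NULL
  if (ly$cout_h > 0L) {
    yh <- op_conv(tp, xh, leaf(ly$Whh), k)
    if (!is.null(ly$Wlh) && !is.null(xl)) {
      yh <- op_add(tp, yh, op_upsample2(tp, op_conv(tp, xl, leaf(ly$Wlh), k), up_mode))
    }
    if (!is.null(ly$bias_h)) yh <- op_add_chanbias(tp, yh, leaf(ly$bias_h))
    if (isTRUE(ly$norm)) {
      yh <- op_instance_norm(tp, yh, ly$norm_h$gamma, ly$norm_h$beta,
                             ly$norm_h$state, training)
    }
    if (act) yh <- op_relu(tp, yh)
  }
  if (ly$cout_l > 0L) {
    yl <- op_conv(tp, op_avgpool2(tp, xh), leaf(ly$Whl), k)
    if (!is.null(ly$Wll) && !is.null(xl)) {
      yl <- op_add(tp, yl, op_conv(tp, xl, leaf(ly$Wll), k))
    }
    if (!is.null(ly$bias_l)) yl <- op_add_chanbias(tp, yl, leaf(ly$bias_l))
    if (isTRUE(ly$norm)) {
      yl <- op_instance_norm(tp, yl, ly$norm_l$gamma, ly$norm_l$beta,
                             ly$norm_l$state, training)
    }
    if (act) yl <- op_relu(tp, yl)
  }
  list(h = yh, l = yl)
}

op_add_chanbias <- function(tp, x, b) {
  d <- dim(x$value)
  bb <- array(rep(b$value, each = d[1] * d[2]), d)
  tp_push(tp, x$value + bb, list(x, b), function(g) {
    list(g, colSums(matrix(g, d[1] * d[2], d[3])))
  })
}

cbam_layer_forward <- function(tp, ly, x) {
  leaf <- function(p) tp_leaf(tp, p)
  W1 <- leaf(ly$W1); b1 <- leaf(ly$b1)
  W2 <- leaf(ly$W2); b2 <- leaf(ly$b2)
  mlp <- function(v) op_dense(tp, op_relu(tp, op_dense(tp, v, W1, b1)), W2, b2)
  mc <- op_sigmoid(tp, op_add(tp, mlp(op_global_avgpool(tp, x)),
                              mlp(op_global_maxpool(tp, x))))
  f1 <- op_scale_channels(tp, x, mc)
  desc <- op_concat(tp, list(op_channel_mean(tp, f1), op_channel_max(tp, f1)))
  ms <- op_sigmoid(tp, op_conv(tp, desc, leaf(ly$Ws), ly$k, leaf(ly$bs)))
  op_scale_spatial(tp, f1, ms)
}

forward_tape <- function(model, image, training = FALSE, tp = NULL) {
  cfg <- model$cfg
  if (is.null(tp)) tp <- new_tape()
  x <- tp_const(tp, as_cube(image))
  d <- cfg$depth
  feats <- list()
  for (j in 0:(d - 1)) {
    for (i in 0:(d - 1 - j)) {
      nd <- model$nodes[[node_key(i, j)]]
      if (j == 0 && i == 0) {
        inh <- x
        inl <- NULL
      } else if (j == 0) {
        below <- feats[[node_key(i - 1, 0)]]
        inh <- op_avgpool2(tp, below$h)
        inl <- if (is.null(below$l)) NULL else op_avgpool2(tp, below$l)
      } else {
        lower <- feats[[node_key(i + 1, j - 1)]]
        uph <- op_upsample2(tp, lower$h, cfg$upsample)
        upl <- if (is.null(lower$l)) NULL else op_upsample2(tp, lower$l, cfg$upsample)
        sibs <- lapply(0:(j - 1), function(jj) feats[[node_key(i, jj)]])
        inh <- op_concat(tp, c(lapply(sibs, `[[`, "h"), list(uph)))
        inl_parts <- c(lapply(sibs, `[[`, "l"), list(upl))
        inl_parts <- inl_parts[!vapply(inl_parts, is.null, logical(1))]
        inl <- if (length(inl_parts)) op_concat(tp, inl_parts) else NULL
        inh <- cbam_layer_forward(tp, nd$cbam, inh)
        if (!is.null(nd$cbam_low) && !is.null(inl)) {
          inl <- cbam_layer_forward(tp, nd$cbam_low, inl)
        }
      }
      cur <- list(h = inh, l = inl)
      for (b in seq_along(nd$blocks)) {
        cur <- oct_layer_forward(tp, nd$blocks[[b]], cur$h, cur$l, training,
                                 cfg$octconv_upsample)
      }
      feats[[node_key(i, j)]] <- cur
    }
  }
  top <- feats[[node_key(0, d - 1)]]
  logits <- oct_layer_forward(tp, model$head, top$h, top$l, training,
                              cfg$octconv_upsample, act = FALSE)$h
  prob <- op_sigmoid(tp, logits)
  list(tape = tp, prob = prob)
}

pad_to_multiple <- function(image, m) {
  d <- dim(image)
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  if (ph == 0 && pw == 0) {
    return(list(image = image, h = d[1], w = d[2]))
  }
  out <- matrix(0, d[1] + ph, d[2] + pw)
  out[seq_len(d[1]), seq_len(d[2])] <- image
  list(image = out, h = d[1], w = d[2])
}

#' Predict the foreground probability map for one image
#'
#' Runs the network in evaluation mode. Images whose dimensions are not
#' divisible by `2^depth` are letterbox zero-padded (bottom/right) and the
#' output cropped back to the input size.
#'
#' @param model An `echo_model`.
#' @param image Numeric matrix in `[0, 1]`.
#' @return Probability matrix in `[0, 1]` of the input's size.
#' @export
predict_prob <- function(model, image) {
  if (!is.matrix(image)) stop("image must be a numeric matrix")
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 1) {
    stop("image must be normalized to [0, 1]")
  }
  m <- 2^model$cfg$depth
  pp <- pad_to_multiple(image, m)
  out <- forward_tape(model, pp$image, training = FALSE)
  out$prob$value[seq_len(pp$h), seq_len(pp$w), 1]
}

#' @export
predict.echo_model <- function(object, image, type = c("prob", "mask"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- predict_prob(object, image)
  if (type == "prob") p else predict_mask(p, threshold)
}

#' Threshold a probability map into a binary mask
#'
#' @param p Probability matrix in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]`; foreground where
#'   `p >= threshold`.
#' @return Logical matrix.
#' @export
predict_mask <- function(p, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  p >= threshold
}

# ---- training --------------------------------------------------------------

loss_node <- function(tp, prob, mask, loss, pars) {
  switch(loss,
    tversky_focal = op_focal_from_ti(
      tp, op_tversky_index(tp, prob, mask, pars$alpha, pars$beta), pars$gamma),
    dice = op_focal_from_ti(
      tp, op_tversky_index(tp, prob, mask, 0.5, 0.5), 1),
    cross_entropy = op_bce(tp, prob, mask))
}

#' Train the segmentation model
#'
#' Adam optimization with per-image updates, a seeded shuffle per epoch, and
#' a per-epoch validation pass. The model's parameters are updated in place
#' and the model is also returned with the accumulated `history`.
#'
#' @param model An `echo_model` from [build_model()].
#' @param data List of training pairs, each `list(image = matrix,
#'   mask = logical matrix)`.
#' @param loss `"tversky_focal"` (default), `"dice"` or `"cross_entropy"`.
#' @param epochs Number of passes over the data.
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Seed for shuffling (parameter initialization is seeded at
#'   [build_model()]).
#' @param val Validation pairs (defaults to `data`); per-epoch mean AOM at
#'   threshold 0.5 is recorded.
#' @param tversky List with `alpha`, `beta`, `gamma` for the Tversky-family
#'   losses (defaults 0.7 / 0.3 / 2).
#' @param val_every Compute validation AOM every this many epochs (rows in
#'   between carry the last computed value); default 1.
#' @param verbose Print one line per epoch.
#' @return The model, with a `data.frame` `history` (`epoch`, `loss`,
#'   `val_aom`) attached.
#' @export
train_model <- function(model, data,
                        loss = c("tversky_focal", "dice", "cross_entropy"),
                        epochs = 10, lr = 1e-3, seed = 1L, val = NULL,
                        tversky = list(alpha = 0.7, beta = 0.3, gamma = 2),
                        val_every = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  if (length(data) == 0L) stop("empty training dataset")
  if (is.null(val)) val <- data
  m <- 2^model$cfg$depth
  prep <- function(pair) {
    pp <- pad_to_multiple(pair$image, m)
    mk <- pad_to_multiple(pair$mask * 1, m)
    list(image = pp$image, mask = array(mk$image, c(dim(mk$image), 1L)),
         h = pp$h, w = pp$w)
  }
  dat <- lapply(data, prep)
  epoch0 <- if (is.null(model$history)) 0L else max(model$history$epoch)
  hist_rows <- vector("list", epochs)
  last_val <- NA_real_
  step_losses <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(dat))
      total <- 0
      for (idx in ord) {
        pair <- dat[[idx]]
        fw <- forward_tape(model, pair$image, training = TRUE)
        ln <- loss_node(fw$tape, fw$prob, pair$mask, loss, tversky)
        lval <- ln$value
        if (!is.finite(lval)) {
          stop(sprintf("non-finite loss (%g) at epoch %d, sample %d: aborting",
                       lval, ep + epoch0, idx))
        }
        zero_grads(model$params)
        tp_backward(fw$tape, ln)
        model$opt$t <- model$opt$t + 1L
        adam_step(model$params, lr, model$opt$t)
        total <- total + lval
        step_losses <- c(step_losses, lval)
      }
      if (ep %% val_every == 0L || ep == epochs) {
        aoms <- vapply(val, function(pair) {
          pm <- predict_mask(predict_prob(model, pair$image), 0.5)
          if (!any(pm)) return(0)
          overlap_metrics(pair$mask, pm)$AOM
        }, numeric(1))
        last_val <- mean(aoms)
      }
      hist_rows[[ep]] <- data.frame(epoch = ep + epoch0,
                                    loss = total / length(dat),
                                    val_aom = last_val)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  val AOM %.4f",
                        ep + epoch0, total / length(dat), last_val))
      }
    }
  })
  hist <- do.call(rbind, hist_rows)
  model$history <- rbind(model$history, hist)
  model$step_losses <- c(model$step_losses, step_losses)
  model
}
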