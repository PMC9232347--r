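# Independent brute-force oracles used to validate the package's fast paths.
# These are deliberately naive (loops, explicit set arithmetic) and never
# call into the implementation they check.

# Dense same-padded stride-1 convolution by direct patch summation.
oracle_conv2d_same <- function(x, W4, b = NULL) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  k <- dim(W4)[1]
  pad <- (k - 1) / 2
  h <- dim(x)[1]
  w <- dim(x)[2]
  cin <- dim(x)[3]
  cout <- dim(W4)[4]
  if (is.null(b)) b <- numeric(cout)
  xp <- array(0, c(h + 2 * pad, w + 2 * pad, cin))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  out <- array(0, c(h, w, cout))
  for (co in seq_len(cout)) {
    for (yy in seq_len(h)) {
      for (xx in seq_len(w)) {
        patch <- xp[yy:(yy + k - 1), xx:(xx + k - 1), , drop = FALSE]
        out[yy, xx, co] <- sum(as.numeric(patch) * as.numeric(W4[, , , co])) + b[co]
      }
    }
  }
  out
}

# Elementwise maximum projection by explicit per-pixel looping.
oracle_mip <- function(frames) {
  d <- dim(frames[[1]])
  out <- matrix(-Inf, d[1], d[2])
  for (f in frames) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        if (f[i, j] > out[i, j]) out[i, j] <- f[i, j]
      }
    }
  }
  out
}

# Exhaustive 256-bin Otsu: maximize between-class variance over every bin
# split of the [0, 1] histogram; threshold is the midpoint of the argmax bin
# (first and last argmax averaged on ties).
oracle_otsu <- function(x, levels = 256) {
  breaks <- seq(0, 1, length.out = levels + 1)
  hh <- hist(as.numeric(x), breaks = breaks, plot = FALSE)
  counts <- hh$counts
  mids <- hh$mids
  best <- -Inf
  arg <- integer(0)
  for (i in seq_len(levels)) {
    w1 <- 0; m1 <- 0
    for (j in 1:i) {
      w1 <- w1 + counts[j]
      m1 <- m1 + counts[j] * mids[j]
    }
    w2 <- 0; m2 <- 0
    if (i < levels) {
      for (j in (i + 1):levels) {
        w2 <- w2 + counts[j]
        m2 <- m2 + counts[j] * mids[j]
      }
    }
    if (w1 == 0 || w2 == 0) next
    v <- w1 * w2 * (m1 / w1 - m2 / w2)^2
    if (v > best + 1e-12) {
      best <- v
      arg <- i
    } else if (abs(v - best) <= 1e-12) {
      arg <- c(arg, i)
    }
  }
  (mids[arg[1]] + mids[arg[length(arg)]]) / 2
}

# Connected-component counting by BFS flood fill in plain R.
oracle_count_components <- function(mask, conn = 8) {
  h <- nrow(mask)
  w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (conn == 8) {
    expand.grid(di = -1:1, dj = -1:1)
  } else {
    data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  count <- 0L
  for (j0 in seq_len(w)) {
    for (i0 in seq_len(h)) {
      if (!mask[i0, j0] || seen[i0, j0]) next
      count <- count + 1L
      queue <- list(c(i0, j0))
      seen[i0, j0] <- TRUE
      while (length(queue)) {
        cur <- queue[[1]]
        queue <- queue[-1]
        for (o in seq_len(nrow(offs))) {
          ni <- cur[1] + offs$di[o]
          nj <- cur[2] + offs$dj[o]
          if (ni >= 1 && nj >= 1 && ni <= h && nj <= w &&
              mask[ni, nj] && !seen[ni, nj]) {
            seen[ni, nj] <- TRUE
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  count
}

# Overlap metrics via index-set arithmetic (setdiff/intersect/union), a
# different route than the implementation's logical-vector sums.
oracle_overlap <- function(A, B) {
  a <- which(A)
  b <- which(B)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  aom <- inter / uni
  avm <- length(setdiff(a, b)) / length(a)
  aum <- length(setdiff(b, a)) / length(b)
  tp <- inter
  fp <- length(setdiff(b, a))
  fn <- length(setdiff(a, b))
  tn <- length(A) - tp - fp - fn
  list(AOM = aom, AVM = avm, AUM = aum,
       CM = (aom + (1 - avm) + (1 - aum)) / 3,
       sen = tp / (tp + fn), spe = tp / (tp + fp),
       TP = tp, FP = fp, TN = tn, FN = fn)
}

# AUC as the Mann-Whitney pairwise comparison statistic (ties count 1/2).
oracle_auc <- function(p, A) {
  pos <- as.numeric(p)[as.logical(A)]
  neg <- as.numeric(p)[!as.logical(A)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Vertical box blur with edge replication, direct 1-D convolution.
oracle_vblur <- function(m, L) {
  pad <- (L - 1) / 2
  h <- nrow(m)
  out <- m * 0
  for (j in seq_len(ncol(m))) {
    for (i in seq_len(h)) {
      acc <- 0
      for (d in -pad:pad) {
        ii <- min(max(i + d, 1), h)
        acc <- acc + m[ii, j]
      }
      out[i, j] <- acc / L
    }
  }
  out
}

# Shared tiny fixtures ------------------------------------------------------

random_mask <- function(h = 16, w = 16, p = 0.4) {
  matrix(stats::runif(h * w) < p, h, w)
}

phantom_pairs <- function(phs) {
  do.call(c, lapply(phs, function(ph) {
    lapply(seq_along(ph$frames), function(t) {
      list(image = ph$frames[[t]], mask = ph$masks[[t]])
    })
  }))
}
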