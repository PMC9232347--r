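# Minimal reverse-mode automatic differentiation on a linear tape.
#
# A tape node is an environment with fields:
#   value   — numeric scalar/vector/matrix/array
#   parents — list of parent nodes
#   backfn  — function(grad) -> list of gradients aligned with parents
#             (NULL entries for non-differentiable parents)
#   param   — an ad_param environment if the node wraps a trainable parameter
#   grad    — accumulator, filled during the backward sweep
# Nodes are appended in evaluation order, so reverse tape order is a valid
# topological order for backpropagation.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = list(), backfn = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  nd$grad <- NULL
  n <- tp$n + 1L
  if (n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

#' @noRd
ad_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL # Adam first moment
  p$v <- NULL # Adam second moment
  class(p) <- "ad_param"
  p
}

tp_leaf <- function(tp, p) tp_push(tp, p$value, param = p)

tp_const <- function(tp, v) tp_push(tp, v)

# Backward sweep from a scalar root. Gradients of parameter leaves are
# accumulated into their ad_param's $grad (summed across multiple uses,
# e.g. the shared CBAM MLP).
tp_backward <- function(tp, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- 1
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) {
      p <- nd$param
      p$grad <- if (is.null(p$grad)) nd$grad else p$grad + nd$grad
    }
    if (is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL # release memory as we go
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# One Adam update over a flat list of ad_params; t is the (1-based) step.
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$m)) {
      p$m <- g * 0
      p$v <- g * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# Run an expression with a temporarily fixed RNG state, restoring the
# caller's state afterwards so seeded builds do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
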