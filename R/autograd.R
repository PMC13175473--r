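# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is an `ad` node: an environment holding a
# plain numeric matrix in $value, the list of parent nodes, and a pullback
# closure that maps the upstream gradient to gradients for those parents.
# Plain matrices/numerics passed to an op are treated as constants.
# Node creation order gives a valid topological order, so backward() just
# walks reachable nodes by decreasing id.

.ad_state <- new.env(parent = emptyenv())
.ad_state$id <- 0L

ad_node <- function(value, parents = NULL, pb = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  .ad_state$id <- .ad_state$id + 1L
  e$id <- .ad_state$id
  e$value <- value
  e$parents <- parents
  e$pb <- pb
  e$param <- param
  e$grad <- NULL
  class(e) <- "ad"
  e
}

#' @keywords internal
ad_param <- function(value) {
  v <- as.matrix(value)
  storage.mode(v) <- "double"
  ad_node(v, param = TRUE)
}

is_ad <- function(x) inherits(x, "ad")

ad_value <- function(x) if (is_ad(x)) x$value else x

# Build a node from `value` whose differentiable inputs are the ad elements
# of `ins`; `grads` computes the full list of input gradients given g.
.ad_make <- function(value, ins, grads) {
  mask <- vapply(ins, is_ad, logical(1))
  if (!any(mask)) return(value)
  ad_node(value, parents = ins[mask], pb = function(g) grads(g)[mask])
}

.as_scalar <- function(x) {
  x <- ad_value(x)
  length(x) == 1L
}

ad_add <- function(a, b) {
  if (.as_scalar(a) && !.as_scalar(b)) return(ad_add(b, a))
  av <- ad_value(a); bv <- ad_value(b)
  if (.as_scalar(b)) {
    .ad_make(av + as.numeric(bv), list(a, b), function(g) {
      list(g, matrix(sum(g), 1L, 1L))
    })
  } else if (is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L) {
    # broadcast a row vector over all rows (bias addition)
    .ad_make(sweep(av, 2L, as.numeric(bv), "+"), list(a, b), function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else {
    stopifnot(all(dim(av) == dim(bv)))
    .ad_make(av + bv, list(a, b), function(g) list(g, g))
  }
}

ad_neg <- function(a) {
  .ad_make(-ad_value(a), list(a), function(g) list(-g))
}

ad_sub <- function(a, b) ad_add(a, ad_neg_or_const(b))

ad_neg_or_const <- function(b) if (is_ad(b)) ad_neg(b) else -b

ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  if (.as_scalar(b)) {
    s <- as.numeric(bv)
    .ad_make(av * s, list(a, b), function(g) {
      list(g * s, matrix(sum(g * av), 1L, 1L))
    })
  } else if (.as_scalar(a)) {
    s <- as.numeric(av)
    .ad_make(s * bv, list(a, b), function(g) {
      list(matrix(sum(g * bv), 1L, 1L), g * s)
    })
  } else {
    stopifnot(all(dim(av) == dim(bv)))
    .ad_make(av * bv, list(a, b), function(g) list(g * bv, g * av))
  }
}

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  .ad_make(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

# a %*% t(b)
ad_tcross <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  .ad_make(tcrossprod(av, bv), list(a, b), function(g) {
    list(g %*% bv, t(g) %*% av)
  })
}

# S %*% h where S is a constant (possibly sparse) operator
ad_spmm <- function(S, h) {
  hv <- ad_value(h)
  .ad_make(as.matrix(S %*% hv), list(h), function(g) {
    list(as.matrix(Matrix::crossprod(S, g)))
  })
}

# scale row i of h by s[i]; s is n x 1
ad_rowscale <- function(h, s) {
  hv <- ad_value(h); sv <- as.numeric(ad_value(s))
  .ad_make(hv * sv, list(h, s), function(g) {
    list(g * sv, matrix(rowSums(g * hv), ncol = 1L))
  })
}

ad_sigmoid <- function(a) {
  v <- stats::plogis(ad_value(a))
  .ad_make(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_logsigmoid <- function(a) {
  x <- ad_value(a)
  v <- ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))
  .ad_make(v, list(a), function(g) list(g * stats::plogis(-x)))
}

ad_exp <- function(a) {
  v <- exp(ad_value(a))
  .ad_make(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  av <- ad_value(a)
  .ad_make(log(av), list(a), function(g) list(g / av))
}

ad_relu <- function(a) {
  av <- ad_value(a)
  .ad_make(pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

ad_sum <- function(a) {
  av <- ad_value(a)
  .ad_make(matrix(sum(av), 1L, 1L), list(a), function(g) {
    list(array(as.numeric(g), dim(av)))
  })
}

ad_mean <- function(a) {
  av <- ad_value(a)
  n <- length(av)
  .ad_make(matrix(mean(av), 1L, 1L), list(a), function(g) {
    list(array(as.numeric(g) / n, dim(av)))
  })
}

ad_colmeans <- function(a) {
  av <- ad_value(a)
  n <- nrow(av)
  .ad_make(matrix(colMeans(av), 1L), list(a), function(g) {
    list(matrix(1, n, 1L) %*% g / n)
  })
}

ad_transpose <- function(a) {
  .ad_make(t(ad_value(a)), list(a), function(g) list(t(g)))
}

# log-softmax over rows, max-subtracted for stability
ad_logsoftmax <- function(a) {
  x <- ad_value(a)
  m <- apply(x, 1L, max)
  xs <- x - m
  lse <- log(rowSums(exp(xs)))
  v <- xs - lse
  .ad_make(v, list(a), function(g) {
    list(g - exp(v) * rowSums(g))
  })
}

# table row lookup (embedding); idx is 1-based, may repeat
ad_embed <- function(tab, idx) {
  tv <- ad_value(tab)
  .ad_make(tv[idx, , drop = FALSE], list(tab), function(g) {
    out <- matrix(0, nrow(tv), ncol(tv))
    rs <- rowsum(g, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

ad_rows <- function(a, idx) {
  av <- ad_value(a)
  .ad_make(av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    rs <- rowsum(g, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# rows rescaled to unit Euclidean norm
ad_l2normalize <- function(a, eps = 1e-12) {
  av <- ad_value(a)
  r <- sqrt(rowSums(av^2) + eps)
  v <- av / r
  .ad_make(v, list(a), function(g) {
    list((g - v * rowSums(g * v)) / r)
  })
}

# inverted dropout; mask drawn from the current RNG stream
ad_dropout <- function(a, p, training) {
  if (!training || p <= 0) return(a)
  av <- ad_value(a)
  mask <- array((stats::runif(length(av)) >= p) / (1 - p), dim(av))
  .ad_make(av * mask, list(a), function(g) list(g * mask))
}

# Backpropagate from a scalar (or any) node; fills $grad on reachable nodes.
ad_backward <- function(root, grad = NULL) {
  stopifnot(is_ad(root))
  nodes <- vector("list", 64L)
  n_nodes <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- vector("list", 64L)
  stack[[1L]] <- root
  top <- 1L
  while (top > 0L) {
    nd <- stack[[top]]
    top <- top - 1L
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) length(nodes) <- 2L * length(nodes)
    nodes[[n_nodes]] <- nd
    for (p in nd$parents) {
      top <- top + 1L
      if (top > length(stack)) length(stack) <- 2L * length(stack)
      stack[[top]] <- p
    }
  }
  nodes <- nodes[seq_len(n_nodes)]
  for (nd in nodes) nd$grad <- NULL
  root$grad <- if (is.null(grad)) {
    array(1, dim(root$value))
  } else {
    grad
  }
  ord <- order(vapply(nodes, function(x) x$id, numeric(1)), decreasing = TRUE)
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$pb) || is.null(nd$grad)) next
    gs <- nd$pb(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
    if (!nd$param) nd$grad <- NULL
  }
  invisible(root)
}

# Collect every ad_param node inside an arbitrarily nested list.
ad_collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (is_ad(e)) {
      if (e$param) out[[length(out) + 1L]] <<- e
    } else if (is.list(e)) {
      for (el in e) walk(el)
    }
  }
  walk(x)
  out
}
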