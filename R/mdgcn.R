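# Directed multiplex graph convolution.
#
# Each layer scores, per node and per graph, how much to trust incoming vs
# outgoing messages. The score combines neighbor diversity (a directional
# Dirichlet energy: how much a node's representation disagrees with its in-
# or out-neighborhood) with degree diversity (a learnable embedding indexed
# by the node's in-/out-degree). A temperature softmax turns the two scores
# into complementary gates, and gated messages from all M graphs are
# averaged with a residual connection.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .Random.seed_get()
  set.seed(seed)
  on.exit(.Random.seed_set(old))
  expr
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

#' Per-node directional Dirichlet energy
#'
#' For node representations `H` (n x w) and a normalized neighbor operator
#' `S` (n x n, nonnegative), returns the n x w energy matrix
#' \deqn{e = (I+S)(H \odot H) - 2\big(((I+S)H) \odot H - H \odot H\big),}
#' whose i-th row measures, per feature, the squared discrepancy between
#' node i and its S-neighborhood (plus a self term weighted by
#' \eqn{1 - \sum_j s_{ij}}). A node with an all-zero S row gets
#' \eqn{e_i = h_i \odot h_i}. Accepts plain matrices or autodiff nodes.
#'
#' @param H n x w matrix of node representations (or `ad` node).
#' @param S n x n normalized operator (sparse or dense), treated as constant.
#' @return n x w energy matrix (or `ad` node if `H` is one).
#' @export
dirichlet_energy <- function(H, S) {
  if (!is_ad(H)) H <- as.matrix(H)
  if (nrow(S) != nrow(ad_value(H))) stop("shape mismatch between H and S")
  P <- ad_mul(H, H)
  a1 <- ad_add(P, ad_spmm(S, P))
  sh <- ad_add(ad_spmm(S, H), H)
  a2 <- ad_sub(ad_mul(sh, H), P)
  ad_sub(a1, ad_mul(a2, 2))
}

#' Complementary directional gates
#'
#' Fuses directional energies with degree embeddings into per-node scalar
#' scores \eqn{q_{dir} = (-e_{dir} + Deg_{dir}) w_{dir} + b_{dir}} and
#' normalizes them with a temperature softmax. Computed as
#' \eqn{\Gamma_\rightarrow = \sigma((q_\rightarrow - q_\leftarrow)/\tau)},
#' which is the two-way softmax in a numerically stable form, so
#' \eqn{\Gamma_\rightarrow + \Gamma_\leftarrow = 1} holds exactly.
#'
#' @param e_out,e_in n x w directional energy matrices.
#' @param deg_out,deg_in n x w degree-embedding rows.
#' @param w_out,w_in w x 1 projection vectors.
#' @param b_out,b_in Scalar biases.
#' @param tau Temperature (> 0), scalar or 1 x 1 node of its log.
#' @return List with n x 1 `gamma_out` and `gamma_in` (values in (0,1)).
#' @export
directional_gates <- function(e_out, e_in, deg_out, deg_in,
                              w_out, w_in, b_out = 0, b_in = 0, tau = 1) {
  if (!is_ad(tau) && tau <= 0) stop("temperature must be positive")
  q_out <- ad_add(ad_matmul(ad_add(ad_neg(e_out), deg_out), w_out), b_out)
  q_in <- ad_add(ad_matmul(ad_add(ad_neg(e_in), deg_in), w_in), b_in)
  inv_tau <- if (is_ad(tau)) ad_exp(ad_neg(tau)) else 1 / tau
  gamma_out <- ad_sigmoid(ad_mul(ad_sub(q_out, q_in), inv_tau))
  gamma_in <- ad_sub(1, gamma_out)
  list(gamma_out = gamma_out, gamma_in = gamma_in,
       q_out = q_out, q_in = q_in)
}

#' One gated multi-graph convolution step
#'
#' Updates node representations as
#' \deqn{H' = \alpha H + \frac{1}{M} \sum_m \big(\Gamma_\rightarrow^{(m)}
#'   S_\rightarrow^{(m)} H W_\rightarrow + \Gamma_\leftarrow^{(m)}
#'   S_\leftarrow^{(m)} H W_\leftarrow\big).}
#' No elementwise nonlinearity is applied; the node-level gating is the
#' nonlinearity.
#'
#' @param H n x w input representations.
#' @param operators List over graphs of `S_out`/`S_in` operators
#'   (as from [prepare_operators()]).
#' @param gates List over graphs of `gamma_out`/`gamma_in` n x 1 vectors.
#' @param W_out,W_in w x w' transformation matrices.
#' @param alpha Residual weight on `H` (requires w' = w when nonzero).
#' @return n x w' updated representations.
#' @export
layer_forward <- function(H, operators, gates, W_out, W_in, alpha = 0.5) {
  M <- length(operators)
  stopifnot(M >= 1L, length(gates) == M)
  if (alpha != 0 && ncol(ad_value(H)) != ncol(ad_value(W_out))) {
    stop("residual term needs matching input/output widths")
  }
  acc <- NULL
  for (m in seq_len(M)) {
    term <- ad_add(
      ad_rowscale(ad_matmul(ad_spmm(operators[[m]]$S_out, H), W_out),
                  gates[[m]]$gamma_out),
      ad_rowscale(ad_matmul(ad_spmm(operators[[m]]$S_in, H), W_in),
                  gates[[m]]$gamma_in))
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  out <- ad_mul(acc, 1 / M)
  if (alpha != 0) out <- ad_add(out, ad_mul(H, alpha))
  out
}

#' Initialize encoder parameters
#'
#' Widths follow a learnable input projection (f -> hidden) so the residual
#' term is well defined at every layer; all subsequent layers are
#' hidden -> hidden. The gate projections `w`, `b` and the log-temperature
#' are shared across graphs within a layer; degree-embedding tables are per
#' layer, per graph and per direction, indexed by the raw degree clamped to
#' `max_degree`. Temperatures are stored as log values (init 0, i.e. tau=1).
#'
#' @param n_feat Input feature dimension f.
#' @param hidden Hidden width (default 256).
#' @param n_layers Number of convolution layers L (default 3).
#' @param n_graphs Number of multiplex layers M.
#' @param max_degree Degree index clamp (default 512).
#' @param alpha Residual weight (default 0.5).
#' @param activation `"none"` (default: the gating is the only nonlinearity)
#'   or `"relu"`, applied after every layer except the last.
#' @param seed Optional integer seed for deterministic initialization.
#' @return An object of class `mdgcn_params`.
#' @export
mdgcn_params <- function(n_feat, hidden = 256, n_layers = 3, n_graphs,
                         max_degree = 512, alpha = 0.5,
                         activation = c("none", "relu"), seed = NULL) {
  activation <- match.arg(activation)
  stopifnot(n_layers >= 1L, n_graphs >= 1L, hidden >= 1L)
  with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) {
      list(
        W_out = ad_param(glorot(hidden, hidden)),
        W_in = ad_param(glorot(hidden, hidden)),
        w_out = ad_param(glorot(hidden, 1L)),
        w_in = ad_param(glorot(hidden, 1L)),
        b_out = ad_param(matrix(0, 1L, 1L)),
        b_in = ad_param(matrix(0, 1L, 1L)),
        log_tau = ad_param(matrix(0, 1L, 1L)),
        deg_out = lapply(seq_len(n_graphs), function(m) {
          ad_param(0.01 * matrix(stats::rnorm((max_degree + 1L) * hidden),
                                 max_degree + 1L, hidden))
        }),
        deg_in = lapply(seq_len(n_graphs), function(m) {
          ad_param(0.01 * matrix(stats::rnorm((max_degree + 1L) * hidden),
                                 max_degree + 1L, hidden))
        }))
    })
    structure(list(W_proj = ad_param(glorot(n_feat, hidden)),
                   layers = layers, n_feat = n_feat, hidden = hidden,
                   n_layers = n_layers, n_graphs = n_graphs,
                   max_degree = max_degree, alpha = alpha,
                   activation = activation),
              class = "mdgcn_params")
  })
}

deg_index <- function(d, max_degree) pmin(as.integer(round(d)), max_degree) + 1L

#' Encode node representations over a multiplex graph
#'
#' Runs `n_layers` gated directional convolutions, recomputing energies and
#' gates at every layer, and returns the final representations together with
#' all per-layer, per-graph gate vectors (needed by the consistency
#' regularizer). Dropout is applied between hidden layers only when
#' `training = TRUE`.
#'
#' @param params An `mdgcn_params` object.
#' @param operators Result of [prepare_operators()] (length M, or a subset
#'   selected with `graphs`).
#' @param X Input features (n x f), plain matrix or `ad` node.
#' @param graphs Integer indices of the multiplex layers to use (default all
#'   `length(operators)`); degree tables are indexed by these.
#' @param training Logical; enables dropout.
#' @param dropout Dropout rate between layers (default 0.5).
#' @return List with `H` (final representations; `ad` node — use `$value`)
#'   and `gates`, a list over layers of lists over graphs with `gamma_out`
#'   and `gamma_in`.
#' @export
mdgcn_encode <- function(params, operators, X, graphs = NULL,
                         training = FALSE, dropout = 0.5) {
  if (is.null(graphs)) graphs <- seq_along(operators)
  stopifnot(length(graphs) >= 1L, max(graphs) <= params$n_graphs,
            max(graphs) <= length(operators))
  ops <- operators[graphs]
  H <- ad_matmul(X, params$W_proj)
  all_gates <- vector("list", params$n_layers)
  for (l in seq_len(params$n_layers)) {
    lp <- params$layers[[l]]
    gates <- vector("list", length(graphs))
    for (k in seq_along(graphs)) {
      m <- graphs[k]
      op <- ops[[k]]
      e_out <- dirichlet_energy(H, op$S_out)
      e_in <- dirichlet_energy(H, op$S_in)
      d_out <- ad_embed(lp$deg_out[[m]], deg_index(op$d_out, params$max_degree))
      d_in <- ad_embed(lp$deg_in[[m]], deg_index(op$d_in, params$max_degree))
      g <- directional_gates(e_out, e_in, d_out, d_in,
                             lp$w_out, lp$w_in, lp$b_out, lp$b_in,
                             tau = lp$log_tau)
      gates[[k]] <- g[c("gamma_out", "gamma_in")]
    }
    H <- layer_forward(H, ops, gates, lp$W_out, lp$W_in, params$alpha)
    if (l < params$n_layers) {
      if (identical(params$activation, "relu")) H <- ad_relu(H)
      H <- ad_dropout(H, dropout, training)
    }
    all_gates[[l]] <- gates
  }
  list(H = H, gates = all_gates)
}

#' Final node embeddings as a plain matrix
#'
#' Convenience wrapper around [mdgcn_encode()] in evaluation mode.
#'
#' @inheritParams mdgcn_encode
#' @return n x hidden numeric matrix.
#' @export
mdgcn_embed <- function(params, operators, X, graphs = NULL) {
  ad_value(mdgcn_encode(params, operators, X, graphs = graphs,
                        training = FALSE)$H)
}

# recursively strip ad nodes to plain values / rebuild them
params_values <- function(x) {
  if (is_ad(x)) return(ad_value(x))
  if (is.list(x)) return(lapply(x, params_values))
  x
}

params_restore <- function(x) {
  if (is.list(x)) return(lapply(x, params_restore))
  if (is.matrix(x)) return(ad_param(x))
  x
}

#' Save / load encoder checkpoints
#'
#' @param params An `mdgcn_params` (or any nested parameter list).
#' @param path File path.
#' @return `path` invisibly; `mdgcn_load()` returns the restored object.
#' @export
mdgcn_save <- function(params, path) {
  saveRDS(list(version = 1L, class = class(params),
               values = params_values(unclass(params))), path)
  invisible(path)
}

#' @rdname mdgcn_save
#' @export
mdgcn_load <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$version, 1L))
  out <- params_restore(obj$values)
  class(out) <- obj$class
  out
}
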