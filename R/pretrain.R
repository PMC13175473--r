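# Infomax-style multiplex contrastive pretraining.
#
# Each network layer is encoded independently (shared encoder weights,
# per-graph degree tables) under two views: the original features (positive)
# and a row-permuted corruption (negative). A bilinear discriminator scores
# node embeddings against a graph-level readout; the per-graph contrastive
# losses are summed, and a learnable consensus matrix Z is pulled toward the
# mean positive embedding and pushed from the mean negative one.

#' Graph-level mean readout
#'
#' Mean-pools node embeddings of the positive (original) view into one
#' graph-level vector. By default all nodes contribute; optionally only the
#' labeled positive genes are pooled.
#'
#' @param H n x w embedding matrix (or `ad` node).
#' @param nodes Optional integer indices of rows to pool (default all).
#' @return 1 x w vector (or `ad` node).
#' @export
graph_readout <- function(H, nodes = NULL) {
  if (nrow(ad_value(H)) == 0L) stop("empty embedding matrix")
  if (!is.null(nodes)) {
    stopifnot(length(nodes) >= 1L)
    H <- ad_rows(H, nodes)
  }
  ad_colmeans(H)
}

#' Bilinear contrastive loss for one graph
#'
#' With node scores \eqn{s_v = \tilde h_v M g} under the positive and
#' negative views, the loss is
#' \deqn{-\frac{1}{n}\sum_v \log\sigma(s_{v,+})
#'       -\frac{1}{n}\sum_v \log\sigma(1 - s_{v,-}),}
#' evaluated with numerically stable log-sigmoids. The second term uses
#' `1 - score` inside the sigmoid (the printed form); set
#' `negative_form = "one_minus_sigmoid"` for the conventional
#' \eqn{\log(1-\sigma(s))} variant.
#'
#' @param H_pos,H_neg n x w embeddings of the positive and corrupted views.
#' @param M w x w bilinear discriminator matrix.
#' @param g 1 x w graph-level readout vector.
#' @param negative_form `"as_printed"` (default) or `"one_minus_sigmoid"`.
#' @return Nonnegative scalar (1 x 1; `ad` node if any input is one).
#' @export
contrastive_loss <- function(H_pos, H_neg, M, g,
                             negative_form = c("as_printed",
                                               "one_minus_sigmoid")) {
  negative_form <- match.arg(negative_form)
  stopifnot(all(dim(ad_value(H_pos)) == dim(ad_value(H_neg))))
  gc <- ad_transpose(g)
  s_pos <- ad_matmul(ad_matmul(H_pos, M), gc)
  s_neg <- ad_matmul(ad_matmul(H_neg, M), gc)
  term_pos <- ad_neg(ad_mean(ad_logsigmoid(s_pos)))
  term_neg <- if (negative_form == "as_printed") {
    ad_neg(ad_mean(ad_logsigmoid(ad_sub(1, s_neg))))
  } else {
    # log(1 - sigma(s)) = logsigmoid(-s)
    ad_neg(ad_mean(ad_logsigmoid(ad_neg(s_neg))))
  }
  ad_add(term_pos, term_neg)
}

#' Cross-graph consensus loss
#'
#' \deqn{\|Z - \bar H_+\|_F^2 - \|Z - \bar H_-\|_F^2,} where the bars are
#' means over graphs. Negative values indicate Z sits closer to the positive
#' consensus than to the corrupted one; swapping the two view sets flips the
#' sign.
#'
#' @param Z n x w consensus matrix.
#' @param H_pos_list,H_neg_list Lists over graphs of n x w embeddings.
#' @return Scalar (1 x 1; `ad` node if any input is one).
#' @export
consensus_loss <- function(Z, H_pos_list, H_neg_list) {
  mean_of <- function(hs) {
    acc <- hs[[1]]
    for (h in hs[-1]) acc <- ad_add(acc, h)
    ad_mul(acc, 1 / length(hs))
  }
  sumsq <- function(d) ad_sum(ad_mul(d, d))
  d_pos <- ad_sub(Z, mean_of(H_pos_list))
  d_neg <- ad_sub(Z, mean_of(H_neg_list))
  ad_sub(sumsq(d_pos), sumsq(d_neg))
}

#' Multiplex contrastive pretraining
#'
#' Optimizes the sum of per-graph contrastive losses plus `beta` times the
#' consensus loss with AdamW, resampling one corrupted view per epoch, and
#' returns the learned consensus embedding Z together with the trained
#' encoder.
#'
#' @param mg A `multiplex_graph`.
#' @param operators Result of [prepare_operators()] for `mg`.
#' @param hidden Encoder hidden width.
#' @param n_layers Encoder depth.
#' @param epochs Training epochs (default 200).
#' @param beta Consensus-loss weight (default 0.001).
#' @param lr AdamW learning rate (default 0.01).
#' @param dropout Dropout rate during training (default 0.5).
#' @param readout_nodes Optional node indices for the readout pool
#'   (default all nodes of the positive view).
#' @param patience Early abort when the loss has not improved by `tol` for
#'   this many epochs (default 30).
#' @param tol Minimal improvement counted by `patience`.
#' @param max_degree Degree clamp for the encoder tables.
#' @param seed Integer seed controlling initialization and corruption.
#' @param verbose Print the loss every 20 epochs.
#' @return List with `Z` (n x hidden matrix), `params` (trained
#'   `mdgcn_params`), `discriminators`, and the per-epoch `loss` trajectory.
#' @export
pretrain_consensus <- function(mg, operators = prepare_operators(mg),
                               hidden = 64, n_layers = 2, epochs = 200,
                               beta = 0.001, lr = 0.01, dropout = 0.5,
                               readout_nodes = NULL, patience = 30,
                               tol = 1e-4, max_degree = 512, seed = 1,
                               verbose = FALSE) {
  X <- mg$X
  n <- nrow(X)
  M <- length(operators)
  with_seed(seed, {
    params <- mdgcn_params(ncol(X), hidden = hidden, n_layers = n_layers,
                           n_graphs = M, max_degree = max_degree)
    disc <- lapply(seq_len(M), function(m) ad_param(glorot(hidden, hidden)))
    Z <- ad_param(0.01 * matrix(stats::rnorm(n * hidden), n, hidden))
    opt <- optimizer_adamw(c(ad_collect_params(unclass(params)), disc,
                             list(Z)), lr = lr)
    losses <- numeric(0)
    best <- Inf
    stall <- 0L
    for (ep in seq_len(epochs)) {
      X_neg <- X[sample.int(n), , drop = FALSE]
      H_pos <- vector("list", M)
      H_neg <- vector("list", M)
      J <- NULL
      for (m in seq_len(M)) {
        H_pos[[m]] <- mdgcn_encode(params, operators, X, graphs = m,
                                   training = TRUE, dropout = dropout)$H
        H_neg[[m]] <- mdgcn_encode(params, operators, X_neg, graphs = m,
                                   training = TRUE, dropout = dropout)$H
        g <- graph_readout(H_pos[[m]], nodes = readout_nodes)
        lc <- contrastive_loss(H_pos[[m]], H_neg[[m]], disc[[m]], g)
        J <- if (is.null(J)) lc else ad_add(J, lc)
      }
      if (beta > 0) {
        J <- ad_add(J, ad_mul(consensus_loss(Z, H_pos, H_neg), beta))
      }
      jv <- as.numeric(ad_value(J))
      if (!is.finite(jv)) stop("pretraining diverged (non-finite loss)")
      losses <- c(losses, jv)
      opt_zero(opt)
      ad_backward(J)
      opt_step(opt)
      if (verbose && ep %% 20L == 0L) {
        message(sprintf("pretrain epoch %d: J = %.4f", ep, jv))
      }
      if (jv < best - tol) {
        best <- jv
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    list(Z = ad_value(Z), params = params,
         discriminators = lapply(disc, ad_value), loss = losses)
  })
}
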