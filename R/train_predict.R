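# Supervised classifier: a second directional encoder plus a linear softmax
# head, trained with summed cross-entropy on the labeled genes and a
# consistency regularizer that shrinks the spread of the learned
# directional gates across nodes.

#' Softmax classification head
#'
#' \eqn{\hat Y = \mathrm{softmax}(H W_{cls} + b_{cls})}; column 2 is the
#' positive-class (driver) probability used as the gene score.
#'
#' @param H n x hidden representation matrix (or `ad` node).
#' @param head List with `W_cls` (hidden x 2) and `b_cls` (1 x 2).
#' @return n x 2 row-stochastic matrix (or `ad` node of log-probabilities if
#'   `log = TRUE`).
#' @param log Return log-probabilities instead of probabilities.
#' @export
classify <- function(H, head, log = FALSE) {
  logits <- ad_add(ad_matmul(H, head$W_cls), head$b_cls)
  lp <- ad_logsoftmax(logits)
  if (log) lp else if (is_ad(lp)) ad_exp(lp) else exp(lp)
}

#' Supervised cross-entropy loss
#'
#' \eqn{L_{sup} = -\sum_{i \in V_L} \log \hat Y_{i, y_i}}: a sum (not a
#' mean) over the labeled nodes.
#'
#' @param log_probs n x 2 log-probability matrix (or `ad` node).
#' @param labeled Integer indices of labeled nodes.
#' @param y Labels in \{0,1\} for `labeled` (1 = driver).
#' @return Nonnegative scalar (1 x 1; `ad` node if `log_probs` is one).
#' @export
supervised_loss <- function(log_probs, labeled, y) {
  stopifnot(length(labeled) == length(y), all(y %in% c(0, 1)))
  lp <- ad_rows(log_probs, labeled)
  mask <- matrix(0, length(labeled), 2L)
  mask[cbind(seq_along(labeled), y + 1L)] <- 1
  ad_neg(ad_sum(ad_mul(lp, mask)))
}

#' Gate consistency regularizer
#'
#' Per node, the directional gates are first averaged over all layers and
#' graphs; the regularizer is then the mean squared deviation of these
#' node-level averages from their overall mean, for each direction:
#' \deqn{L_{reg} = \frac{1}{n}\sum_i (\bar\gamma_\rightarrow -
#'   \Gamma_{i,\rightarrow})^2 + \frac{1}{n}\sum_i (\bar\gamma_\leftarrow -
#'   \Gamma_{i,\leftarrow})^2,}
#' which equals the population variance of the out-gates plus that of the
#' in-gates (and, by gate complementarity, twice the out-gate variance).
#'
#' @param gates Gate structure from [mdgcn_encode()]: list over layers of
#'   lists over graphs with `gamma_out`, `gamma_in` (n x 1).
#' @return Nonnegative scalar (`ad` node if the gates are nodes).
#' @export
consistency_reg <- function(gates) {
  if (length(gates) == 0L) stop("empty gate list")
  acc_out <- NULL
  acc_in <- NULL
  cnt <- 0L
  for (layer in gates) {
    for (g in layer) {
      acc_out <- if (is.null(acc_out)) g$gamma_out else ad_add(acc_out, g$gamma_out)
      acc_in <- if (is.null(acc_in)) g$gamma_in else ad_add(acc_in, g$gamma_in)
      cnt <- cnt + 1L
    }
  }
  g_out <- ad_mul(acc_out, 1 / cnt)
  g_in <- ad_mul(acc_in, 1 / cnt)
  var_term <- function(g) {
    d <- ad_sub(g, ad_mean(g))
    ad_mean(ad_mul(d, d))
  }
  ad_add(var_term(g_out), var_term(g_in))
}

#' Total training objective
#'
#' \eqn{L = L_{sup} + \lambda L_{reg}}.
#'
#' @param l_sup Supervised loss (scalar or `ad` node).
#' @param l_reg Regularizer (scalar or `ad` node).
#' @param lambda Balance weight >= 0 (default 3e-4).
#' @return Scalar (`ad` node if inputs are).
#' @export
total_loss <- function(l_sup, l_reg, lambda = 3e-4) {
  stopifnot(lambda >= 0)
  if (lambda == 0) return(l_sup)
  ad_add(l_sup, ad_mul(l_reg, lambda))
}

#' Training configuration
#'
#' Collects the tunables of the supervised stage with the published
#' defaults: AdamW, learning rate 0.01, weight decay 0, three convolution
#' layers of width 256, dropout 0.5, residual weight 0.5, lambda 3e-4.
#' Desk-scale runs should lower `hidden`, `n_layers` and `epochs`.
#'
#' @param lr,weight_decay,dropout,hidden,n_layers,alpha,lambda Numeric
#'   hyperparameters (see Description).
#' @param epochs Maximum epochs (default 1000).
#' @param patience Early-stopping patience on validation loss (default 30).
#' @param val_fraction Fraction of labeled nodes held out for early stopping.
#' @param max_degree Degree-embedding clamp.
#' @param activation Hidden-layer nonlinearity for the encoder, `"none"`
#'   (default) or `"relu"`.
#' @param directionality `FALSE` symmetrizes every layer (ablation).
#' @param seed Integer seed.
#' @return List of class `training_config`.
#' @export
training_config <- function(lr = 0.01, weight_decay = 0, dropout = 0.5,
                            hidden = 256, n_layers = 3, alpha = 0.5,
                            lambda = 3e-4, epochs = 1000, patience = 30,
                            val_fraction = 0.1, max_degree = 512,
                            activation = c("none", "relu"),
                            directionality = TRUE, seed = 1) {
  activation <- match.arg(activation)
  stopifnot(lr > 0, dropout >= 0, dropout < 1, hidden >= 1, n_layers >= 1,
            lambda >= 0, epochs >= 1, patience >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(as.list(environment()), class = "training_config")
}

#' Train the driver-gene classifier
#'
#' Optimizes the total objective on the training labels with AdamW and early
#' stopping on held-out validation loss, then scores every gene.
#'
#' @param mg A `multiplex_graph`.
#' @param positives,negatives Integer indices of the training labels
#'   (positives = known plus pseudo-positives; negatives = inferred set).
#' @param config A [training_config()].
#' @param operators Optional precomputed [prepare_operators()] result
#'   (must match `config$directionality`).
#' @return Object of class `driver_model`: trained `params` and `head`, the
#'   per-gene positive-class `scores`, per-epoch `train_loss`/`val_loss`,
#'   the epoch of the best validation loss, and the gate values.
#' @export
train_classifier <- function(mg, positives, negatives,
                             config = training_config(),
                             operators = NULL) {
  stopifnot(length(positives) >= 1L, length(negatives) >= 1L,
            length(intersect(positives, negatives)) == 0L)
  if (is.null(operators)) {
    operators <- prepare_operators(mg, symmetrize = !config$directionality)
  }
  X <- mg$X
  labeled <- c(positives, negatives)
  y <- c(rep(1, length(positives)), rep(0, length(negatives)))
  with_seed(config$seed, {
    # stratified validation split for early stopping
    n_vp <- max(1L, floor(config$val_fraction * length(positives)))
    n_vn <- max(1L, floor(config$val_fraction * length(negatives)))
    vp <- sample(seq_along(positives), n_vp)
    vn <- sample(seq_along(negatives), n_vn)
    val_sel <- c(vp, length(positives) + vn)
    if (config$val_fraction == 0) val_sel <- integer(0)
    tr_sel <- setdiff(seq_along(labeled), val_sel)
    if (length(tr_sel) == 0L) stop("no labeled nodes left for training")

    params <- mdgcn_params(ncol(X), hidden = config$hidden,
                           n_layers = config$n_layers,
                           n_graphs = length(operators),
                           max_degree = config$max_degree,
                           alpha = config$alpha,
                           activation = config$activation)
    head <- list(W_cls = ad_param(glorot(config$hidden, 2L)),
                 b_cls = ad_param(matrix(0, 1L, 2L)))
    opt <- optimizer_adamw(c(ad_collect_params(unclass(params)),
                             ad_collect_params(head)),
                           lr = config$lr,
                           weight_decay = config$weight_decay)
    best_val <- Inf
    best_values <- NULL
    best_epoch <- 0L
    stall <- 0L
    tl <- numeric(0)
    vl <- numeric(0)
    for (ep in seq_len(config$epochs)) {
      enc <- mdgcn_encode(params, operators, X, training = TRUE,
                          dropout = config$dropout)
      lp <- classify(enc$H, head, log = TRUE)
      l_sup <- supervised_loss(lp, labeled[tr_sel], y[tr_sel])
      l_reg <- consistency_reg(enc$gates)
      loss <- total_loss(l_sup, l_reg, config$lambda)
      lv <- as.numeric(ad_value(loss))
      if (!is.finite(lv)) stop("training diverged (non-finite loss)")
      tl <- c(tl, lv)
      opt_zero(opt)
      ad_backward(loss)
      opt_step(opt)
      # validation loss in eval mode (no dropout)
      if (length(val_sel) > 0L) {
        enc_ev <- mdgcn_encode(params, operators, X, training = FALSE)
        lp_ev <- classify(enc_ev$H, head, log = TRUE)
        cur_val <- as.numeric(ad_value(
          supervised_loss(lp_ev, labeled[val_sel], y[val_sel])))
      } else {
        cur_val <- lv
      }
      vl <- c(vl, cur_val)
      if (cur_val < best_val - 1e-6) {
        best_val <- cur_val
        best_epoch <- ep
        best_values <- list(params = params_values(unclass(params)),
                            head = params_values(head))
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    if (!is.null(best_values)) {
      params <- params_restore(best_values$params)
      class(params) <- "mdgcn_params"
      head <- params_restore(best_values$head)
    }
    enc <- mdgcn_encode(params, operators, X, training = FALSE)
    probs <- ad_value(classify(enc$H, head))
    structure(list(params = params, head = head,
                   scores = probs[, 2L],
                   gates = params_values(enc$gates),
                   train_loss = tl, val_loss = vl,
                   best_epoch = best_epoch,
                   positives = positives, negatives = negatives,
                   config = config),
              class = "driver_model")
  })
}

#' Ranked gene table from a trained model
#'
#' @param model A `driver_model`.
#' @param genes Gene symbols (same order as the training graph).
#' @param exclude_train Drop the training positives/negatives from the table.
#' @return Data frame with `gene`, `score`, `label_status`
#'   (`positive` / `negative` / `unlabeled`), sorted by descending score.
#' @export
rank_genes <- function(model, genes, exclude_train = FALSE) {
  status <- rep("unlabeled", length(genes))
  status[model$positives] <- "positive"
  status[model$negatives] <- "negative"
  out <- data.frame(gene = genes, score = model$scores,
                    label_status = status, stringsAsFactors = FALSE)
  if (exclude_train) out <- out[out$label_status == "unlabeled", ]
  out[order(-out$score, out$gene), ]
}
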