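# Negative-sample inference by internal contrastive learning (ICL).
#
# A one-class model is trained on the positive genes only: each feature
# vector is cut into all contiguous sliding windows of length k; encoder G
# embeds the window, encoder F embeds its complement, and the model learns
# to match each complement with its own window among all m = f - k + 1
# candidates. Genes whose windows are hard to match (high summed loss) look
# internally inconsistent with the positive class and are taken as
# high-confidence negatives.

#' Sliding window pairs of a feature vector
#'
#' Splits `x` (length f) into m = f - k + 1 pairs: window j is the
#' contiguous slice `x[j:(j+k-1)]`, the complement is the remaining entries
#' in original order.
#'
#' @param x Numeric vector of length f.
#' @param k Window length, 1 <= k < f.
#' @return List with matrices `a` (m x k windows), `b` (m x (f-k)
#'   complements) and `k`.
#' @export
build_windows <- function(x, k) {
  f <- length(x)
  if (k < 1 || k >= f) stop("window length k must satisfy 1 <= k < f")
  m <- f - k + 1L
  a <- matrix(0, m, k)
  b <- matrix(0, m, f - k)
  for (j in seq_len(m)) {
    w <- j:(j + k - 1L)
    a[j, ] <- x[w]
    b[j, ] <- x[-w]
  }
  list(a = a, b = b, k = k)
}

icl_mlp_params <- function(d_in, hidden, d_out) {
  list(W1 = ad_param(glorot(d_in, hidden)),
       b1 = ad_param(matrix(0, 1L, hidden)),
       W2 = ad_param(glorot(hidden, d_out)),
       b2 = ad_param(matrix(0, 1L, d_out)))
}

icl_mlp_forward <- function(p, x) {
  h <- ad_relu(ad_add(ad_matmul(x, p$W1), p$b1))
  ad_l2normalize(ad_add(ad_matmul(h, p$W2), p$b2))
}

# m x m similarity matrix between complements (rows) and windows (cols)
icl_similarity <- function(model, windows) {
  fe <- icl_mlp_forward(model$F, windows$b)
  ge <- icl_mlp_forward(model$G, windows$a)
  ad_mul(ad_tcross(fe, ge), 1 / model$tau)
}

#' ICL loss of one window pair
#'
#' \deqn{\ell_j = -\ln \frac{\exp(F^N(b_j)\cdot G^N(a_j)/\tau)}
#'   {\sum_{j'} \exp(F^N(b_j)\cdot G^N(a_{j'})/\tau)},}
#' the cross-entropy of matching complement j to its own window among the m
#' candidate windows, computed with a stable log-softmax. Always >= 0, and
#' exactly 0 when m = 1.
#'
#' @param model An `icl_model` (see [train_icl()]).
#' @param windows Result of [build_windows()].
#' @param j Window index in 1..m.
#' @return Nonnegative scalar.
#' @export
icl_loss <- function(model, windows, j) {
  m <- nrow(windows$a)
  stopifnot(j >= 1, j <= m)
  logp <- ad_value(ad_logsoftmax(icl_similarity(model, windows)))
  -logp[j, j]
}

#' Train the ICL model on positive genes
#'
#' Minimizes the mean window-matching loss over all positive samples and all
#' windows with AdamW. Encoders F and G are two-layer feedforward networks
#' with unit-norm outputs.
#'
#' @param X_pos Feature rows of the positive genes (>= 2 rows).
#' @param k Window length (default 8).
#' @param tau Softmax temperature (default 0.1).
#' @param epochs Training epochs (default 100).
#' @param hidden,d_out Encoder widths (defaults 64, 32).
#' @param lr Learning rate (default 0.01).
#' @param seed Integer seed.
#' @param verbose Print loss every 20 epochs.
#' @return Object of class `icl_model` with encoders, `tau`, `k` and the
#'   training `loss` trajectory.
#' @export
train_icl <- function(X_pos, k = 8, tau = 0.1, epochs = 100, hidden = 64,
                      d_out = 32, lr = 0.01, seed = 1, verbose = FALSE) {
  X_pos <- as.matrix(X_pos)
  f <- ncol(X_pos)
  if (nrow(X_pos) < 2L) stop("need at least 2 positive samples")
  if (tau <= 0) stop("temperature must be positive")
  if (k < 1 || k >= f) stop("window length k must satisfy 1 <= k < f")
  wins <- lapply(seq_len(nrow(X_pos)), function(i) build_windows(X_pos[i, ], k))
  m <- f - k + 1L
  diag_mask <- diag(m)
  with_seed(seed, {
    model <- structure(list(F = icl_mlp_params(f - k, hidden, d_out),
                            G = icl_mlp_params(k, hidden, d_out),
                            tau = tau, k = k),
                       class = "icl_model")
    opt <- optimizer_adamw(ad_collect_params(list(model$F, model$G)), lr = lr)
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      total <- NULL
      for (w in wins) {
        logp <- ad_logsoftmax(icl_similarity(model, w))
        li <- ad_neg(ad_mean(ad_mul(logp, diag_mask)))  # mean over m windows /m
        total <- if (is.null(total)) li else ad_add(total, li)
      }
      # ad_mean over the masked matrix divides by m^2; rescale to mean over
      # windows: multiply by m, then average over samples
      loss <- ad_mul(total, m / length(wins))
      lv <- as.numeric(ad_value(loss))
      if (!is.finite(lv)) stop("ICL training diverged (non-finite loss)")
      losses[ep] <- lv
      opt_zero(opt)
      ad_backward(loss)
      opt_step(opt)
      if (verbose && ep %% 20L == 0L) {
        message(sprintf("ICL epoch %d: loss = %.4f", ep, lv))
      }
    }
    model$loss <- losses
    model
  })
}

#' Anomaly score of a feature vector
#'
#' \eqn{y(x) = \sum_j \ell_j}: the summed window-matching losses over all m
#' windows. Higher scores mean the sample is internally less consistent with
#' the patterns the model learned on positives, hence more likely negative.
#'
#' @param model A trained `icl_model`.
#' @param x Numeric feature vector.
#' @return Nonnegative scalar.
#' @export
icl_score <- function(model, x) {
  w <- build_windows(x, model$k)
  logp <- ad_value(ad_logsoftmax(icl_similarity(model, w)))
  -sum(diag(logp))
}

#' Score candidates and select the negative set
#'
#' Scores every candidate gene, ranks descending by anomaly score (ties
#' broken by ascending gene index), and returns the top `n_select` as the
#' inferred high-confidence negative set.
#'
#' @param model A trained `icl_model`.
#' @param X Feature matrix of all genes.
#' @param candidates Integer indices eligible as negatives (unlabeled genes
#'   minus pseudo-positives).
#' @param n_select Number of negatives to select (typically the number of
#'   positives after augmentation). If the pool is smaller, all candidates
#'   are taken with a warning.
#' @return Object of class `anomaly_scores`: data frame with `index`,
#'   `score`, `selected`, ordered by rank.
#' @export
score_and_select <- function(model, X, candidates, n_select) {
  X <- as.matrix(X)
  stopifnot(length(candidates) >= 1L, n_select >= 0)
  sc <- vapply(candidates, function(i) icl_score(model, X[i, ]), numeric(1))
  ord <- order(-sc, candidates)
  if (n_select > length(candidates)) {
    warning("candidate pool smaller than requested negative count; taking all")
    n_select <- length(candidates)
  }
  out <- data.frame(index = candidates[ord], score = sc[ord],
                    selected = seq_along(ord) <= n_select)
  class(out) <- c("anomaly_scores", "data.frame")
  out
}

#' Negative-inference pipeline
#'
#' Trains the ICL model on the (augmented) positive set and selects the
#' inferred negatives from the remaining unlabeled genes.
#'
#' @param features Gene representation matrix the ICL operates on: the
#'   consensus embedding from [pretrain_consensus()] (default pipeline) or
#'   the raw feature matrix.
#' @param positives Integer indices of positives (labeled plus pseudo).
#' @param n_select Number of negatives (default `length(positives)`).
#' @param exclude Additional indices excluded from the candidate pool.
#' @inheritParams train_icl
#' @return List with `negatives` (indices), `scores` (`anomaly_scores`) and
#'   the trained `model`.
#' @export
infer_negatives <- function(features, positives, n_select = length(positives),
                            exclude = integer(), k = 8, tau = 0.1,
                            epochs = 100, seed = 1, ...) {
  features <- as.matrix(features)
  model <- train_icl(features[positives, , drop = FALSE], k = k, tau = tau,
                     epochs = epochs, seed = seed, ...)
  pool <- setdiff(seq_len(nrow(features)), union(positives, exclude))
  scores <- score_and_select(model, features, pool, n_select)
  list(negatives = scores$index[scores$selected], scores = scores,
       model = model)
}
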