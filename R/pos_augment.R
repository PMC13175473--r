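# Pseudo-positive augmentation.
#
# A light two-stage graph model (Chebyshev polynomial convolution followed
# by one normalized GCN aggregation) is trained on the labeled genes; its
# class probabilities drive an entropy filter on the unlabeled genes, and an
# RBF spectral-clustering constraint computed on the labeled positives
# filters out candidates far from the positive feature clusters.

# symmetric normalization D^{-1/2} A D^{-1/2} (zero degrees -> zero factor)
sym_normalize <- function(A) {
  d <- as.numeric(Matrix::rowSums(A))
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Di <- Matrix::Diagonal(x = inv)
  methods::as(Di %*% A %*% Di, "CsparseMatrix")
}

# scaled Laplacian 2 L / lambda_max - I with lambda_max by power iteration
scaled_laplacian <- function(A, iters = 50) {
  n <- nrow(A)
  L <- Matrix::Diagonal(n) - sym_normalize(A)
  v <- matrix(1 / sqrt(n), n, 1)
  lam <- 2
  for (i in seq_len(iters)) {
    w <- as.matrix(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    v <- w / nw
    lam <- as.numeric(t(v) %*% as.matrix(L %*% v))
  }
  lam <- max(lam, 1e-6) * (1 + 1e-6)  # safety margin: keep spectrum in [-1, 1]
  methods::as((2 / lam) * L - Matrix::Diagonal(n), "CsparseMatrix")
}

# Chebyshev basis features T_k(Lhat) X for k = 0..K
cheb_features <- function(Lhat, X, K) {
  stopifnot(K >= 0)
  out <- vector("list", K + 1L)
  out[[1]] <- X
  if (K >= 1) out[[2]] <- as.matrix(Lhat %*% X)
  if (K >= 2) {
    for (k in 3:(K + 1L)) {
      out[[k]] <- as.matrix(2 * (Lhat %*% out[[k - 1L]])) - out[[k - 2L]]
    }
  }
  out
}

#' Union graph across multiplex layers
#'
#' Symmetrized union of all layer adjacencies, used as the default
#' probability graph for the augmentation model.
#'
#' @param mg A `multiplex_graph`.
#' @return Sparse symmetric binary adjacency.
#' @export
union_adjacency <- function(mg) {
  A <- mg$layers[[1]]
  for (m in seq_along(mg$layers)[-1]) A <- A + mg$layers[[m]]
  A <- A + Matrix::t(A)
  A <- methods::as(methods::as((A > 0) * 1, "generalMatrix"),
                   "CsparseMatrix")
  Matrix::diag(A) <- 0
  Matrix::drop0(A)
}

#' Fit the class-probability model
#'
#' Trains softmax(S [sum_k T_k(Lhat) X Theta_k] W) by cross-entropy on the
#' labeled genes, where S is the symmetric normalized adjacency and T_k the
#' Chebyshev polynomials of the scaled Laplacian (T0 = I, T1 = Lhat,
#' Tk = 2 Lhat Tk-1 - Tk-2).
#'
#' @param X Feature matrix (n x f).
#' @param A Probability-graph adjacency (symmetric).
#' @param labeled Integer indices of labeled genes.
#' @param y Labels in \{0,1\} for `labeled` (1 = positive class).
#' @param K Chebyshev order (default 2).
#' @param hidden Width of the Chebyshev stage output (default 16).
#' @param epochs,lr Training schedule (defaults 200, 0.01).
#' @param seed Integer seed.
#' @return Object of class `prob_model` with a `predict_probs()` method via
#'   [class_probabilities()].
#' @export
fit_prob_model <- function(X, A, labeled, y, K = 2, hidden = 16,
                           epochs = 200, lr = 0.01, seed = 1) {
  stopifnot(K >= 0, length(labeled) == length(y), all(y %in% c(0, 1)))
  X <- as.matrix(X)
  S <- sym_normalize(A)
  Lhat <- scaled_laplacian(A)
  Tk <- cheb_features(Lhat, X, K)
  with_seed(seed, {
    theta <- lapply(seq_len(K + 1L), function(k) {
      ad_param(glorot(ncol(X), hidden))
    })
    W <- ad_param(glorot(hidden, 2L))
    opt <- optimizer_adamw(c(theta, list(W)), lr = lr)
    target_col <- y + 1L
    for (ep in seq_len(epochs)) {
      acc <- NULL
      for (k in seq_len(K + 1L)) {
        t <- ad_matmul(Tk[[k]], theta[[k]])
        acc <- if (is.null(acc)) t else ad_add(acc, t)
      }
      logits <- ad_matmul(ad_spmm(S, acc), W)
      logp <- ad_logsoftmax(ad_rows(logits, labeled))
      mask <- matrix(0, length(labeled), 2L)
      mask[cbind(seq_along(labeled), target_col)] <- 1
      loss <- ad_neg(ad_mean(ad_mul(logp, mask)))
      opt_zero(opt)
      ad_backward(loss)
      opt_step(opt)
    }
    structure(list(theta = lapply(theta, ad_value), W = ad_value(W),
                   K = K, S = S, Lhat = Lhat),
              class = "prob_model")
  })
}

#' Class probabilities from a fitted probability model
#'
#' @param model A `prob_model` from [fit_prob_model()].
#' @param X Feature matrix the model was fitted on (n x f).
#' @return n x 2 row-stochastic matrix; column 2 is the positive class.
#' @export
class_probabilities <- function(model, X) {
  Tk <- cheb_features(model$Lhat, as.matrix(X), model$K)
  acc <- 0
  for (k in seq_len(model$K + 1L)) acc <- acc + Tk[[k]] %*% model$theta[[k]]
  logits <- as.matrix(model$S %*% acc) %*% model$W
  p <- exp(logits - apply(logits, 1L, max))
  p / rowSums(p)
}

#' Prediction entropy of a probability matrix
#'
#' \eqn{H_i = -\sum_c p_{ic} \log p_{ic}} with natural logarithms and the
#' convention \eqn{0 \log 0 = 0}; bounded by \eqn{\log C}.
#'
#' @param P Row-stochastic matrix.
#' @return Numeric vector of entropies.
#' @export
prediction_entropy <- function(P) {
  P <- as.matrix(P)
  rowSums(ifelse(P > 0, -P * log(P), 0))
}

#' Rank unlabeled genes by prediction entropy
#'
#' Keeps unlabeled genes whose temporary label (probability argmax) is the
#' positive class, sorts them by ascending entropy, and truncates to
#' `retain_count` lowest-entropy candidates.
#'
#' @param P n x 2 row-stochastic class probabilities (column 2 = positive).
#' @param unlabeled Integer indices of unlabeled genes.
#' @param retain_count Maximum number of candidates kept (>= 0).
#' @return Data frame with columns `index`, `p_pos`, `entropy`, sorted by
#'   ascending entropy; possibly empty.
#' @export
entropy_rank <- function(P, unlabeled, retain_count) {
  stopifnot(retain_count >= 0)
  P <- as.matrix(P)
  H <- prediction_entropy(P)
  cand <- unlabeled[P[unlabeled, 2L] > P[unlabeled, 1L]]
  out <- data.frame(index = cand, p_pos = P[cand, 2L], entropy = H[cand])
  out <- out[order(out$entropy, out$index), , drop = FALSE]
  utils::head(out, retain_count)
}

#' RBF spectral clustering of the labeled positives
#'
#' Standardizes the positive features (per-column z-scoring fit on the
#' positives), builds the RBF affinity
#' \eqn{\kappa(q,u) = \exp(-\|\phi(q)-\phi(u)\|^2 / 2\sigma^2)}, performs
#' normalized-cut spectral clustering into exactly two clusters (k-means on
#' the top-2 eigenvectors of the normalized affinity), and returns the two
#' cluster centroids in the standardized feature space along with each
#' positive's distance to its nearest centroid.
#'
#' @param X_pos Feature rows of the labeled positives (|S+| x f, >= 2 rows).
#' @param sigma RBF bandwidth; default is the median pairwise distance.
#' @param seed Seed for the k-means step.
#' @return Object of class `rbf_clusters`: `centroids` (2 x f), `cluster`
#'   assignments, `d_pos` distances of the positives, `center`/`scale` of
#'   the standardization, `sigma`.
#' @export
rbf_cluster_positives <- function(X_pos, sigma = NULL, seed = 1) {
  X_pos <- as.matrix(X_pos)
  if (nrow(X_pos) < 2L) stop("need at least 2 labeled positives")
  center <- colMeans(X_pos)
  scl <- sqrt(colMeans(sweep(X_pos, 2L, center)^2))
  scl[scl == 0] <- 1
  phi <- sweep(sweep(X_pos, 2L, center), 2L, scl, "/")
  D <- as.matrix(stats::dist(phi))
  if (is.null(sigma)) {
    sigma <- stats::median(D[upper.tri(D)])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  if (sigma <= 0) stop("sigma must be positive")
  K <- exp(-D^2 / (2 * sigma^2))
  if (all(abs(K - 1) < 1e-12)) stop("degenerate affinity: identical features")
  deg <- rowSums(K)
  Dn <- diag(1 / sqrt(deg))
  Ksym <- Dn %*% K %*% Dn
  eig <- eigen(Ksym, symmetric = TRUE)
  U <- eig$vectors[, 1:2, drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  cl <- with_seed(seed, stats::kmeans(U, centers = 2L, nstart = 10L))$cluster
  centroids <- rbind(colMeans(phi[cl == 1L, , drop = FALSE]),
                     colMeans(phi[cl == 2L, , drop = FALSE]))
  d_pos <- centroid_distance_std(phi, centroids)
  structure(list(centroids = centroids, cluster = cl, d_pos = d_pos,
                 center = center, scale = scl, sigma = sigma),
            class = "rbf_clusters")
}

centroid_distance_std <- function(phi, centroids) {
  d1 <- sqrt(rowSums(sweep(phi, 2L, centroids[1L, ])^2))
  d2 <- sqrt(rowSums(sweep(phi, 2L, centroids[2L, ])^2))
  pmin(d1, d2)
}

#' Distance of candidate genes to the positive cluster centroids
#'
#' @param fit An `rbf_clusters` object.
#' @param X_cand Candidate feature rows on the original feature scale.
#' @return Numeric vector: min distance to either centroid after applying
#'   the standardization fit on the positives.
#' @export
centroid_distance <- function(fit, X_cand) {
  X_cand <- as.matrix(X_cand)
  phi <- sweep(sweep(X_cand, 2L, fit$center), 2L, fit$scale, "/")
  centroid_distance_std(phi, fit$centroids)
}

#' Final pseudo-positive selection rule
#'
#' A candidate joins the pseudo-positive set when (i) its temporary label is
#' the positive class (guaranteed by [entropy_rank()]), (ii) its positive
#' probability is at least `theta_p` (inclusive), and (iii) its centroid
#' distance does not exceed mean + population SD of the labeled positives'
#' own centroid distances (inclusive).
#'
#' @param candidates Data frame from [entropy_rank()].
#' @param distances Centroid distances for `candidates$index`, same order.
#' @param d_pos Centroid distances of the labeled positives.
#' @param theta_p Confidence threshold in (0,1), default 0.8.
#' @return Data frame of class `pseudo_label_set` with the selected genes
#'   and their probability/entropy/distance evidence; attribute
#'   `d_threshold` records the distance cutoff.
#' @export
select_pseudo_positives <- function(candidates, distances, d_pos,
                                    theta_p = 0.8) {
  stopifnot(nrow(candidates) == length(distances))
  d_thr <- mean(d_pos) + sqrt(mean((d_pos - mean(d_pos))^2))
  keep <- candidates$p_pos >= theta_p & distances <= d_thr
  out <- cbind(candidates[keep, , drop = FALSE],
               distance = distances[keep])
  rownames(out) <- NULL
  attr(out, "d_threshold") <- d_thr
  class(out) <- c("pseudo_label_set", "data.frame")
  out
}

#' Pseudo-positive augmentation pipeline
#'
#' Runs the full positive-augmentation stage: fits the probability model on
#' the labeled genes (positives vs. provisional negatives sampled from the
#' unlabeled pool when none are given), entropy-ranks the unlabeled genes,
#' clusters the labeled positives, and applies the selection rule.
#'
#' @param mg A `multiplex_graph`.
#' @param positives Integer indices of labeled positive genes.
#' @param negatives Optional indices used as the negative class when fitting
#'   the probability model; defaults to a random unlabeled sample of equal
#'   size (provisional, standard in positive-unlabeled practice).
#' @param theta_p Probability threshold (default 0.8).
#' @param retain_count Entropy-retention count (default `2 * length(positives)`).
#' @param K Chebyshev order (default 2).
#' @param sigma RBF bandwidth (default: median heuristic).
#' @param graph Probability graph: `"union"` (default) or a layer index.
#' @param epochs Probability-model epochs (default 200).
#' @param use_distance_filter Set `FALSE` to drop the centroid-distance
#'   clause (ablation; the clause only ever filters).
#' @param seed Integer seed.
#' @return A `pseudo_label_set` (see [select_pseudo_positives()]); attribute
#'   `prob_model` holds the fitted model.
#' @export
augment_positives <- function(mg, positives, negatives = NULL,
                              theta_p = 0.8, retain_count = 2 * length(positives),
                              K = 2, sigma = NULL, graph = "union",
                              epochs = 200, use_distance_filter = TRUE,
                              seed = 1) {
  n <- nrow(mg$X)
  A <- if (identical(graph, "union")) {
    union_adjacency(mg)
  } else {
    Ax <- mg$layers[[graph]]
    methods::as(methods::as(((Ax + Matrix::t(Ax)) > 0) * 1,
                            "generalMatrix"), "CsparseMatrix")
  }
  unlabeled <- setdiff(seq_len(n), positives)
  if (is.null(negatives)) {
    negatives <- with_seed(seed + 1L,
                           sample(unlabeled, min(length(positives),
                                                 length(unlabeled))))
  }
  unlabeled <- setdiff(unlabeled, negatives)
  labeled <- c(positives, negatives)
  y <- c(rep(1, length(positives)), rep(0, length(negatives)))
  model <- fit_prob_model(mg$X, A, labeled, y, K = K, epochs = epochs,
                          seed = seed)
  P <- class_probabilities(model, mg$X)
  cand <- entropy_rank(P, unlabeled, retain_count)
  fit <- rbf_cluster_positives(mg$X[positives, , drop = FALSE],
                               sigma = sigma, seed = seed)
  d_cand <- if (nrow(cand) > 0L) {
    centroid_distance(fit, mg$X[cand$index, , drop = FALSE])
  } else {
    numeric(0)
  }
  if (!use_distance_filter) d_cand <- rep(-Inf, nrow(cand))
  out <- select_pseudo_positives(cand, d_cand, fit$d_pos, theta_p = theta_p)
  attr(out, "prob_model") <- model
  attr(out, "rbf_fit") <- fit
  out
}
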