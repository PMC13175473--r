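# Metrics, cross-validation harness, imbalance experiments and the
# known-driver interaction analysis.

#' Ranking and classification metrics
#'
#' AUROC by the rank formula with midrank tie handling, AUPRC by
#' step-function integration of the precision-recall curve (average
#' precision), and F1 at a score threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), at least one of each class.
#' @param threshold F1 threshold on the score (default 0.5).
#' @return Named numeric vector `auroc`, `auprc`, `f1`.
#' @export
metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("need at least one positive and one negative")
  r <- rank(scores)  # midranks
  auroc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-scores, labels)  # ties: negatives first (conservative)
  tp <- cumsum(labels[ord] == 1L)
  prec <- tp / seq_along(tp)
  rec <- tp / np
  drec <- diff(c(0, rec))
  auprc <- sum(prec * drec)
  pred <- as.integer(scores >= threshold)
  tp2 <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  f1 <- if (2 * tp2 + fp + fn == 0) 0 else 2 * tp2 / (2 * tp2 + fp + fn)
  c(auroc = auroc, auprc = auprc, f1 = f1)
}

stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Repeated stratified cross-validation
#'
#' Runs `n_seeds` repeats of stratified `n_folds`-fold cross-validation over
#' the labeled genes. Inside each training fold the model is fitted on the
#' fold's training labels and evaluated on the held-out labeled genes. When
#' `augment = TRUE`, pseudo-positive augmentation and negative inference are
#' re-run inside each fold using only that fold's training labels, so test
#' genes never influence their own labels; `global_mode = TRUE` instead
#' performs augmentation once on all labels before splitting.
#'
#' @param mg A `multiplex_graph`.
#' @param positives,negatives Integer indices of the labeled genes.
#' @param config A [training_config()]; its seed is combined with the run
#'   seed.
#' @param n_seeds,n_folds Repeats and folds (defaults 10 and 5).
#' @param augment Re-run the augmentation stages inside folds.
#' @param global_mode One-shot global augmentation before splitting.
#' @param augment_args List of arguments forwarded to [augment_positives()]
#'   and [infer_negatives()] (`theta_p`, `k`, `tau`, `epochs`, ...).
#' @param seed Base seed for fold assignment.
#' @return Object of class `cv_result`: per-run data frame `runs`
#'   (seed, fold, auroc, auprc, f1) and `summary` (mean and SD per metric).
#' @export
cross_validate <- function(mg, positives, negatives,
                           config = training_config(), n_seeds = 10,
                           n_folds = 5, augment = FALSE, global_mode = FALSE,
                           augment_args = list(), seed = 1) {
  operators <- prepare_operators(mg, symmetrize = !config$directionality)
  if (global_mode && augment) {
    # one-shot global augmentation before splitting (leaks pseudo-labels
    # into test folds; kept for comparison with the in-fold default)
    fa <- fold_augment(mg, positives, integer(0), augment_args, seed = seed)
    positives <- fa$positives
    negatives <- fa$negatives
  }
  labeled <- c(positives, negatives)
  y <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
  runs <- list()
  for (s in seq_len(n_seeds)) {
    fold <- stratified_folds(y, n_folds, seed = seed * 1000L + s)
    for (k in seq_len(n_folds)) {
      test <- labeled[fold == k]
      tr_pos <- labeled[fold != k & y == 1L]
      tr_neg <- labeled[fold != k & y == 0L]
      if (sum(y[fold == k] == 1L) == 0L) stop("fold without positives")
      if (augment && !global_mode) {
        fa <- fold_augment(mg, tr_pos, test, augment_args,
                           seed = seed * 1000L + s + k)
        tr_pos <- fa$positives
        tr_neg <- fa$negatives
      }
      cfg <- config
      cfg$seed <- config$seed + 7919L * s + k
      model <- train_classifier(mg, tr_pos, tr_neg, cfg,
                                operators = operators)
      m <- metrics(model$scores[test], y[fold == k])
      runs[[length(runs) + 1L]] <- data.frame(seed = s, fold = k,
                                              auroc = m["auroc"],
                                              auprc = m["auprc"],
                                              f1 = m["f1"])
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  summ <- data.frame(metric = c("auroc", "auprc", "f1"),
                     mean = c(mean(runs$auroc), mean(runs$auprc),
                              mean(runs$f1)),
                     sd = c(stats::sd(runs$auroc), stats::sd(runs$auprc),
                            stats::sd(runs$f1)))
  structure(list(runs = runs, summary = summ), class = "cv_result")
}

# in-fold augmentation: pseudo-positives, then ICL negatives, avoiding the
# test genes entirely
fold_augment <- function(mg, tr_pos, test, augment_args, seed) {
  aa <- function(name, default) {
    if (!is.null(augment_args[[name]])) augment_args[[name]] else default
  }
  aug <- augment_positives(mg, tr_pos,
                           theta_p = aa("theta_p", 0.8),
                           retain_count = aa("retain_count", 2 * length(tr_pos)),
                           K = aa("K", 2),
                           epochs = aa("prob_epochs", 100),
                           seed = seed)
  pseudo <- setdiff(aug$index, test)
  pos_aug <- union(tr_pos, pseudo)
  feats <- aa("icl_features", mg$X)
  neg <- infer_negatives(feats, pos_aug,
                         n_select = length(pos_aug),
                         exclude = test,
                         k = aa("k", min(8L, ncol(feats) - 1L)),
                         tau = aa("tau", 0.1),
                         epochs = aa("icl_epochs", 50),
                         seed = seed)
  list(positives = pos_aug, negatives = neg$negatives)
}

#' Class-imbalance experiment
#'
#' Re-runs cross-validation with the negative set subsampled or extended to
#' positive:negative ratios such as 1:1, 1:1.5, 1:2, reporting AUPRC (and
#' the other metrics) per ratio.
#'
#' @param mg A `multiplex_graph`.
#' @param positives Integer indices of positives.
#' @param negative_pool Ranked candidate negatives (most confident first);
#'   the first `ratio * length(positives)` entries are used per ratio.
#' @param ratios Numeric negative:positive ratios (default `c(1, 1.5, 2)`).
#' @param ... Passed to [cross_validate()].
#' @return Data frame: one row per ratio with mean metrics, plus attribute
#'   `cv` holding the full `cv_result` objects.
#' @export
imbalance_experiment <- function(mg, positives, negative_pool,
                                 ratios = c(1, 1.5, 2), ...) {
  res <- list()
  cvs <- list()
  for (r in ratios) {
    n_neg <- round(r * length(positives))
    if (n_neg > length(negative_pool)) {
      stop("negative pool too small for ratio 1:", r)
    }
    cv <- cross_validate(mg, positives, negative_pool[seq_len(n_neg)], ...)
    cvs[[as.character(r)]] <- cv
    res[[length(res) + 1L]] <- data.frame(
      ratio = r, n_negatives = n_neg,
      auroc = mean(cv$runs$auroc),
      auprc = mean(cv$runs$auprc),
      f1 = mean(cv$runs$f1))
  }
  out <- do.call(rbind, res)
  attr(out, "cv") <- cvs
  out
}

#' Interaction counts with known driver genes
#'
#' For every gene and every network layer, counts its known-driver
#' in-neighbors, out-neighbors, and the size of their union (`total`; a
#' driver interacting in both directions is counted once). For undirected
#' layers the three counts coincide. Spearman rank correlations (midrank
#' ties) between the gene scores and each count are reported per layer with
#' large-sample t-approximation p-values.
#'
#' @param mg A `multiplex_graph`.
#' @param cdg Integer indices of the known driver genes.
#' @param scores Per-gene scores; correlations are computed over `genes`
#'   (default: all genes outside `cdg`).
#' @param genes Integer indices over which to correlate.
#' @return List with `counts` (list per layer of data frames with
#'   `in_count`, `out_count`, `total_count`) and `correlations` (data frame:
#'   layer, type, rho, p_value, n).
#' @export
cdg_interaction_analysis <- function(mg, cdg, scores,
                                     genes = setdiff(seq_along(scores), cdg)) {
  if (length(cdg) == 0L) stop("empty known-driver set")
  ind <- numeric(length(mg$genes))
  ind[cdg] <- 1
  counts <- vector("list", length(mg$layers))
  cors <- list()
  for (m in seq_along(mg$layers)) {
    A <- mg$layers[[m]]
    out_c <- as.numeric(A %*% ind)           # arcs gene -> driver
    in_c <- as.numeric(Matrix::crossprod(A, ind))  # arcs driver -> gene
    U <- (A + Matrix::t(A)) > 0
    tot_c <- as.numeric(U %*% ind)
    counts[[m]] <- data.frame(in_count = in_c, out_count = out_c,
                              total_count = tot_c)
    for (type in c("in", "out", "total")) {
      v <- switch(type, "in" = in_c, out = out_c, total = tot_c)[genes]
      rho <- spearman_rho(scores[genes], v)
      cors[[length(cors) + 1L]] <- data.frame(
        layer = m, directed = mg$directed[m], type = type, rho = rho,
        p_value = spearman_pvalue(rho, length(genes)), n = length(genes))
    }
  }
  list(counts = counts, correlations = do.call(rbind, cors))
}

spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

spearman_pvalue <- function(rho, n) {
  if (!is.finite(rho) || n < 3) return(NA_real_)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
  2 * stats::pt(-abs(tt), df = n - 2)
}
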