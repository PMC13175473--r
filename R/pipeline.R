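#' End-to-end driver-gene prioritization
#'
#' Runs the full pipeline on a prepared multiplex graph: (1) contrastive
#' pretraining of a consensus embedding, (2) pseudo-positive augmentation,
#' (3) ICL negative inference on the consensus embedding, (4) supervised
#' training of the directional classifier on the augmented labels, and (5)
#' a ranked gene table. Every stage draws its randomness from `seed`, so two
#' runs with identical inputs and seed produce identical tables.
#'
#' @param mg A `multiplex_graph`.
#' @param positives Integer indices (or gene symbols) of known drivers.
#' @param config A [training_config()] for the classifier stage.
#' @param pretrain_args,augment_args,negatives_args Optional argument lists
#'   forwarded to [pretrain_consensus()], [augment_positives()] and
#'   [infer_negatives()].
#' @param use_pos_augment,use_neg_infer Ablation switches; with
#'   `use_neg_infer = FALSE`, `fallback_negatives` must supply a negative
#'   set (e.g. a curated non-driver list).
#' @param fallback_negatives Indices used as negatives when negative
#'   inference is disabled.
#' @param seed Master seed.
#' @return Object of class `driver_pipeline`: the ranked `table`, the
#'   trained `model`, `pseudo_positives`, `negatives`, consensus `Z`.
#' @export
run_pipeline <- function(mg, positives, config = training_config(),
                         pretrain_args = list(), augment_args = list(),
                         negatives_args = list(),
                         use_pos_augment = TRUE, use_neg_infer = TRUE,
                         fallback_negatives = NULL, seed = 1) {
  if (is.character(positives)) positives <- match(positives, mg$genes)
  stopifnot(!anyNA(positives), length(positives) >= 2L)
  operators <- prepare_operators(mg, symmetrize = !config$directionality)

  pre <- do.call(pretrain_consensus,
                 utils::modifyList(list(mg = mg, operators = operators,
                                        seed = seed),
                                   pretrain_args))
  pseudo <- integer(0)
  evidence <- NULL
  if (use_pos_augment) {
    aug <- do.call(augment_positives,
                   utils::modifyList(list(mg = mg, positives = positives,
                                          seed = seed),
                                     augment_args))
    pseudo <- aug$index
    evidence <- aug
  }
  pos_aug <- union(positives, pseudo)

  if (use_neg_infer) {
    kk <- negatives_args$k
    if (is.null(kk)) kk <- min(8L, ncol(pre$Z) - 1L)
    negatives_args$k <- kk
    neg <- do.call(infer_negatives,
                   utils::modifyList(list(features = pre$Z,
                                          positives = pos_aug,
                                          seed = seed),
                                     negatives_args))
    negatives <- neg$negatives
    neg_scores <- neg$scores
  } else {
    if (is.null(fallback_negatives)) {
      stop("use_neg_infer = FALSE requires fallback_negatives")
    }
    negatives <- setdiff(fallback_negatives, pos_aug)
    neg_scores <- NULL
  }

  cfg <- config
  cfg$seed <- seed
  model <- train_classifier(mg, pos_aug, negatives, cfg,
                            operators = operators)
  structure(list(table = rank_genes(model, mg$genes),
                 model = model,
                 pseudo_positives = pseudo,
                 pseudo_evidence = evidence,
                 negatives = negatives,
                 negative_scores = neg_scores,
                 Z = pre$Z,
                 pretrain_loss = pre$loss,
                 seed = seed),
            class = "driver_pipeline")
}

#' @export
print.driver_pipeline <- function(x, ...) {
  cat("driver_pipeline:", nrow(x$table), "genes ranked;",
      length(x$pseudo_positives), "pseudo-positives;",
      length(x$negatives), "inferred negatives\n")
  cat("top genes:\n")
  print(utils::head(x$table, 5))
  invisible(x)
}
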