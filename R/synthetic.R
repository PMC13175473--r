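# Synthetic multiplex graphs with planted driver structure.
#
# The generator states a small world the whole pipeline can be tested in:
# planted-partition layers whose within-class edge probability is controlled
# by a homophily parameter, an optional directional signal in the directed
# layers (driver -> non-driver arcs more likely than the reverse),
# class-conditional Gaussian features standing in for z-scored mutation /
# methylation / expression values, and a hidden subset of true positives
# relabeled as unlabeled so augmentation recovery can be measured.

#' Synthetic multiplex graph configuration
#'
#' Defaults mirror the shapes of the real data the pipeline targets: six
#' layers (three directed), 48 features, roughly 10% positives, and
#' moderately informative structure.
#'
#' @param n Number of genes (default 200).
#' @param M Number of layers (default 6).
#' @param n_directed How many layers are directed (default `M / 2`).
#' @param n_positives Number of true driver genes (default `round(0.1 * n)`).
#' @param f Feature dimension (default 48).
#' @param homophily h in \[0,1\]: fraction of edge mass on within-class pairs
#'   (0.5 = no structure; default 0.8).
#' @param delta Direction asymmetry in \[0,1\]: how strongly cross-class arcs
#'   in directed layers prefer the driver -> non-driver orientation
#'   (0 = none; default 0.5).
#' @param density Expected edge density per layer (default 0.05).
#' @param effect Class-mean separation of the informative features, in SD
#'   units (default 1).
#' @param informative_frac Fraction of features carrying the class signal
#'   (default 0.25).
#' @param hidden_frac Fraction of true positives relabeled as unlabeled
#'   (default 0.2).
#' @param label_noise Fraction of visible positive labels flipped onto
#'   non-drivers (default 0).
#' @param seed Integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n = 200, M = 6, n_directed = floor(M / 2),
                         n_positives = round(0.1 * n), f = 48,
                         homophily = 0.8, delta = 0.5, density = 0.05,
                         effect = 1, informative_frac = 0.25,
                         hidden_frac = 0.2, label_noise = 0, seed = 1) {
  stopifnot(n >= 10, M >= 1, n_directed >= 0, n_directed <= M,
            n_positives >= 2, n_positives < n,
            homophily >= 0, homophily <= 1, delta >= 0, delta <= 1,
            density > 0, density < 1, effect >= 0,
            informative_frac > 0, informative_frac <= 1,
            hidden_frac >= 0, hidden_frac < 1,
            label_noise >= 0, label_noise < 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic multiplex dataset
#'
#' Within-class ordered pairs receive edge probability proportional to
#' `homophily`, cross-class pairs to `1 - homophily`, rescaled so the
#' expected density matches `density` exactly. In directed layers,
#' cross-class arc probabilities are additionally scaled by `1 + delta` in
#' the driver -> non-driver orientation and `1 - delta` in the reverse,
#' planting a directional class signal while preserving the expected
#' density. Features are class-conditional Gaussians (informative columns
#' shifted by `effect` SDs for drivers) and are z-scored. A `hidden_frac`
#' subset of the true positives is removed from the visible label set.
#'
#' @param config A [synth_config()].
#' @return List with `graph` (a `multiplex_graph`), `truth` (0/1 vector of
#'   true driver status), `positives` (visible labeled positive indices),
#'   `hidden_positives` (true positives relabeled unlabeled), and `config`.
#' @export
generate_synthetic <- function(config = synth_config()) {
  with_seed(config$seed, {
    n <- config$n
    truth <- integer(n)
    truth[sample.int(n, config$n_positives)] <- 1L
    same <- outer(truth, truth, "==")
    h <- config$homophily
    w_frac <- (sum(same) - n) / (n * (n - 1))  # fraction of within-class pairs
    scale_c <- config$density / (w_frac * h + (1 - w_frac) * (1 - h))
    base <- ifelse(same, scale_c * h, scale_c * (1 - h))
    diag(base) <- 0
    if (max(base) * (1 + config$delta) > 1) {
      stop("requested density/homophily implies edge probabilities > 1")
    }
    directed_flags <- rep(c(TRUE, FALSE),
                          c(config$n_directed, config$M - config$n_directed))
    layers <- vector("list", config$M)
    for (m in seq_len(config$M)) {
      P <- base
      if (directed_flags[m] && config$delta > 0) {
        drv_to_non <- outer(truth == 1L, truth == 0L, "&")
        non_to_drv <- outer(truth == 0L, truth == 1L, "&")
        P[drv_to_non] <- P[drv_to_non] * (1 + config$delta)
        P[non_to_drv] <- P[non_to_drv] * (1 - config$delta)
      }
      if (directed_flags[m]) {
        A <- Matrix::Matrix((matrix(stats::runif(n * n), n, n) < P) * 1,
                            sparse = TRUE)
        diag(A) <- 0
      } else {
        up <- upper.tri(P)
        draw <- matrix(0, n, n)
        draw[up] <- (stats::runif(sum(up)) < P[up]) * 1
        A <- Matrix::Matrix(draw + t(draw), sparse = TRUE)
      }
      layers[[m]] <- methods::as(methods::as(A, "generalMatrix"),
                                 "CsparseMatrix")
    }
    n_inf <- max(1L, round(config$informative_frac * config$f))
    X <- matrix(stats::rnorm(n * config$f), n, config$f)
    X[truth == 1L, seq_len(n_inf)] <- X[truth == 1L, seq_len(n_inf)] +
      config$effect
    X <- zscore_columns(X)
    genes <- sprintf("g%04d", seq_len(n))
    rownames(X) <- genes
    mg <- multiplex_graph(layers, X, directed = directed_flags, genes = genes)
    pos <- which(truth == 1L)
    n_hidden <- round(config$hidden_frac * length(pos))
    hidden <- if (n_hidden > 0) sort(sample(pos, n_hidden)) else integer(0)
    visible <- setdiff(pos, hidden)
    if (config$label_noise > 0) {
      n_noise <- round(config$label_noise * length(visible))
      if (n_noise > 0) {
        visible <- sort(c(visible, sample(which(truth == 0L), n_noise)))
      }
    }
    list(graph = mg, truth = truth, positives = visible,
         hidden_positives = hidden, config = config)
  })
}

#' Difficulty presets and sweeps
#'
#' `synth_preset()` returns the configuration of a named preset:
#' `"easy"` (homophily 0.9, effect 2), `"medium"` (0.7, 1) or
#' `"hard"` (0.5, 0 — a pure null). `difficulty_sweep()` generates one
#' dataset per grid point over homophily, delta and effect.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [synth_config()].
#' @return `synth_preset()`: a `synth_config`; `difficulty_sweep()`: a list
#'   of [generate_synthetic()] results, one per grid row.
#' @export
synth_preset <- function(preset = c("easy", "medium", "hard"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
                 easy = list(homophily = 0.9, effect = 2),
                 medium = list(homophily = 0.7, effect = 1),
                 hard = list(homophily = 0.5, effect = 0, delta = 0))
  do.call(synth_config, utils::modifyList(args, list(...)))
}

#' @rdname synth_preset
#' @param base A `synth_config` used as the template.
#' @param grid Data frame with any of the columns `homophily`, `delta`,
#'   `effect`, `seed`.
#' @export
difficulty_sweep <- function(base = synth_config(), grid) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    for (nm in intersect(names(grid), names(cfg))) cfg[[nm]] <- grid[[nm]][i]
    class(cfg) <- "synth_config"
    generate_synthetic(cfg)
  })
}

#' Write a synthetic dataset to the standard file formats
#'
#' Emits one edge-list TSV per layer, a manifest TSV, a feature table and a
#' positive gene list, so the files can be read back through the I/O module.
#'
#' @param data Result of [generate_synthetic()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mg <- data$graph
  paths <- character(length(mg$layers))
  for (m in seq_along(mg$layers)) {
    A <- mg$layers[[m]]
    idx <- Matrix::which(A != 0, arr.ind = TRUE)
    if (!mg$directed[m]) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    el <- edge_list(mg$genes[idx[, 1]], mg$genes[idx[, 2]],
                    directed = mg$directed[m])
    paths[m] <- sprintf("layer%02d.tsv", m)
    write_edge_list(el, file.path(dir, paths[m]))
  }
  utils::write.table(data.frame(path = paths, directed = mg$directed),
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ft <- data.frame(gene = mg$genes, mg$X, check.names = FALSE)
  utils::write.table(ft, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(mg$genes[data$positives], file.path(dir, "positives.txt"))
  writeLines(mg$genes[data$truth == 1L], file.path(dir, "truth.txt"))
  invisible(file.path(dir, "manifest.tsv"))
}
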