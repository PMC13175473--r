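#' Read a two-column edge list
#'
#' Reads a whitespace- or tab-delimited two-column file of gene-gene edges.
#' Lines starting with `#` are skipped. A first line whose two tokens look
#' like column names (`from/to`, `source/target`, `gene1/gene2`) is treated
#' as a header. Duplicate pairs and self-loops are removed; their counts are
#' kept in attributes `n_duplicates` and `n_self_loops`.
#'
#' @param path Path to the edge-list file.
#' @param directed Logical; whether edges are directed source -> target.
#'   Undirected edges are stored once and symmetrized when the adjacency
#'   matrix is built.
#' @return An object of class `edge_list`: a data frame with columns `from`
#'   and `to`, attribute `directed`, and cleaning counts.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(edge_list(character(), character(), directed = directed))
  }
  toks <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    stop("malformed edge list line ", lineno[bad[1]], " in ", path,
         ": expected 2 columns, got ", length(toks[[bad[1]]]))
  }
  from <- vapply(toks, `[[`, character(1), 1L)
  to <- vapply(toks, `[[`, character(1), 2L)
  header_names <- c("from", "to", "source", "target", "gene1", "gene2",
                    "geneA", "geneB")
  if (tolower(from[1]) %in% tolower(header_names) &&
      tolower(to[1]) %in% tolower(header_names)) {
    from <- from[-1]
    to <- to[-1]
  }
  edge_list(from, to, directed = directed)
}

#' Construct a cleaned edge list
#'
#' @param from,to Character vectors of endpoint gene symbols.
#' @param directed Logical directed flag.
#' @return An `edge_list` (see [read_edge_list()]).
#' @export
edge_list <- function(from, to, directed = FALSE) {
  stopifnot(length(from) == length(to))
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]
  to <- to[!self]
  if (!directed) {
    # canonical orientation so A-B and B-A are the same undirected edge
    lo <- pmin(from, to)
    hi <- pmax(from, to)
    from <- lo
    to <- hi
  }
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  out <- data.frame(from = from[!dup], to = to[!dup],
                    stringsAsFactors = FALSE)
  attr(out, "directed") <- directed
  attr(out, "n_self_loops") <- n_self
  attr(out, "n_duplicates") <- n_dup
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Write an edge list to a two-column TSV
#'
#' @param el An `edge_list`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(el, path) {
  utils::write.table(as.data.frame(el)[, c("from", "to")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' @param path Path to the file; `#` comments and blank lines are skipped.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Read a gene feature table
#'
#' TSV with a header; first column holds gene symbols, remaining columns are
#' numeric features.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with genes as row names.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) stop("feature table needs a gene column plus >=1 feature")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicated gene symbols in feature table")
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric feature columns in ", path)
  rownames(X) <- genes
  X
}

#' Read a network manifest
#'
#' A manifest is a TSV with header columns `path` and `directed`
#' (`TRUE`/`FALSE`); paths are resolved relative to the manifest location.
#'
#' @param path Manifest file path.
#' @return List of `edge_list` objects.
#' @export
read_network_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("path", "directed") %in% names(df)))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    read_edge_list(p, directed = as.logical(df$directed[i]))
  })
}

#' Align networks, features and labels to one gene universe
#'
#' The gene universe is the gene set of the feature table (features are
#' mandatory for every node, so the feature matrix stays dense). Edges that
#' touch genes outside the universe are dropped and counted; genes absent
#' from a layer become isolated nodes in that layer. The operation is
#' idempotent: aligning an already-aligned input changes nothing.
#'
#' @param edges List of `edge_list` objects (one per network layer).
#' @param features Numeric matrix of node features with gene row names.
#' @param positives Character vector of known driver gene symbols.
#' @param negatives Optional character vector of known non-driver symbols.
#' @return A list with `universe` (character), `layers` (filtered
#'   `edge_list`s), `X`, `positives`/`negatives` (integer indices),
#'   `dropped_edges` (integer per layer), `dropped_positives`.
#' @export
align_to_universe <- function(edges, features, positives = character(),
                              negatives = character()) {
  universe <- rownames(features)
  if (is.null(universe) || length(universe) == 0L) {
    stop("feature matrix must have gene row names")
  }
  layers <- vector("list", length(edges))
  dropped <- integer(length(edges))
  any_overlap <- FALSE
  for (m in seq_along(edges)) {
    el <- edges[[m]]
    keep <- el$from %in% universe & el$to %in% universe
    dropped[m] <- sum(!keep)
    if (any(keep)) any_overlap <- TRUE
    layers[[m]] <- edge_list(el$from[keep], el$to[keep],
                             directed = attr(el, "directed"))
  }
  if (length(edges) > 0L && !any_overlap) {
    stop("no gene of the feature table appears in any network")
  }
  miss_pos <- setdiff(positives, universe)
  if (length(miss_pos) > 0L) {
    warning(length(miss_pos), " positive gene(s) absent from the universe; dropped")
  }
  list(universe = universe,
       layers = layers,
       X = features,
       positives = match(intersect(positives, universe), universe),
       negatives = match(intersect(negatives, universe), universe),
       dropped_edges = dropped,
       dropped_positives = miss_pos)
}

#' Column-wise z-scoring with the population standard deviation
#'
#' Constant columns are mapped to all-zero rather than NaN.
#'
#' @param X Numeric matrix.
#' @return Matrix of the same shape, each column with mean 0 and population
#'   variance 1 (or all zeros when constant).
#' @export
zscore_columns <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  Z <- sweep(X, 2L, mu)
  nz <- sd_pop > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2L, sd_pop[nz], "/")
  Z[, !nz] <- 0
  Z
}

#' Assemble a multi-omics feature matrix
#'
#' For each cancer type three features per gene are computed: the mutation
#' frequency (non-silent SNV count divided by exonic length in bases), the
#' mean tumor-minus-normal methylation difference over matched samples, and
#' the mean log2 tumor/normal expression fold change over matched samples.
#' The per-type blocks are concatenated and every column is z-scored over
#' genes (population SD; constant columns become zeros).
#'
#' @param tables List with data frames `mutation` (gene, cancer_type,
#'   snv_count, exonic_length), `methylation` (gene, cancer_type, sample,
#'   tumor, normal) and `expression` (same columns as methylation).
#' @param cancer_types Ordered character vector of cancer types; the output
#'   has `3 * length(cancer_types)` columns.
#' @return z-scored numeric matrix, genes x features, with informative column
#'   names (`<type>.mutfreq`, `<type>.methdiff`, `<type>.log2fc`).
#' @export
build_omics_features <- function(tables, cancer_types) {
  stopifnot(length(cancer_types) >= 1L)
  mut <- tables$mutation
  met <- tables$methylation
  expr <- tables$expression
  genes <- sort(unique(c(mut$gene, met$gene, expr$gene)))
  if (any(mut$exonic_length <= 0)) {
    bad <- mut$gene[mut$exonic_length <= 0][1]
    stop("non-positive exonic length for gene ", bad)
  }
  if (any(expr$tumor <= 0 | expr$normal <= 0)) {
    bad <- expr$gene[expr$tumor <= 0 | expr$normal <= 0][1]
    stop("non-positive expression value for gene ", bad,
         "; log2 fold change undefined")
  }
  n <- length(genes)
  X <- matrix(0, n, 3L * length(cancer_types))
  rownames(X) <- genes
  cn <- character(ncol(X))
  for (t in seq_along(cancer_types)) {
    ct <- cancer_types[t]
    j <- 3L * (t - 1L)
    m <- mut[mut$cancer_type == ct, , drop = FALSE]
    X[match(m$gene, genes), j + 1L] <- m$snv_count / m$exonic_length
    me <- met[met$cancer_type == ct, , drop = FALSE]
    if (nrow(me) > 0L) {
      d <- tapply(me$tumor - me$normal, me$gene, mean)
      X[match(names(d), genes), j + 2L] <- as.numeric(d)
    }
    ex <- expr[expr$cancer_type == ct, , drop = FALSE]
    if (nrow(ex) > 0L) {
      d <- tapply(log2(ex$tumor / ex$normal), ex$gene, mean)
      X[match(names(d), genes), j + 3L] <- as.numeric(d)
    }
    cn[j + 1:3] <- paste0(ct, c(".mutfreq", ".methdiff", ".log2fc"))
  }
  colnames(X) <- cn
  zscore_columns(X)
}
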