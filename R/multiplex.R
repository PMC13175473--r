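#' Construct a multiplex graph
#'
#' A multiplex graph holds M binary adjacency layers over one shared gene set
#' together with an n x f node feature matrix. Undirected layers store a
#' symmetric adjacency (each undirected edge is a bidirectional pair of
#' arcs). Diagonals are zero; entries are 0/1.
#'
#' @param layers List of n x n adjacency matrices (base or `Matrix` sparse),
#'   or `edge_list` objects which are converted using `genes`.
#' @param X Numeric feature matrix (n x f).
#' @param directed Logical vector, one flag per layer (ignored for
#'   `edge_list` input, which carries its own flag).
#' @param genes Character vector of gene symbols; defaults to `rownames(X)`.
#' @return An object of class `multiplex_graph` with elements `genes`,
#'   `layers` (sparse `dgCMatrix`), `directed`, `X`.
#' @export
multiplex_graph <- function(layers, X, directed = NULL, genes = rownames(X)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  stopifnot(length(genes) == n, !anyDuplicated(genes))
  if (length(layers) == 0L) stop("at least one network layer is required")
  if (is.null(directed)) {
    directed <- vapply(layers, function(l) {
      isTRUE(attr(l, "directed"))
    }, logical(1))
  }
  stopifnot(length(directed) == length(layers))
  adj <- vector("list", length(layers))
  for (m in seq_along(layers)) {
    l <- layers[[m]]
    if (inherits(l, "edge_list")) {
      A <- adjacency_from_edges(l, genes)
    } else {
      A <- methods::as(methods::as(Matrix::Matrix(l, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix")
      A <- methods::as(A, "dMatrix")
    }
    validate_adjacency(A, directed[m], n)
    adj[[m]] <- A
  }
  structure(list(genes = genes, layers = adj,
                 directed = as.logical(directed), X = X),
            class = "multiplex_graph")
}

adjacency_from_edges <- function(el, genes) {
  i <- match(el$from, genes)
  j <- match(el$to, genes)
  keep <- !is.na(i) & !is.na(j)
  i <- i[keep]; j <- j[keep]
  n <- length(genes)
  if (!isTRUE(attr(el, "directed"))) {
    i2 <- c(i, j); j2 <- c(j, i)
    i <- i2; j <- j2
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A@x[] <- 1  # collapse any duplicate entries to binary
  A
}

validate_adjacency <- function(A, directed, n) {
  if (!all(dim(A) == c(n, n))) stop("layer dimension mismatch")
  if (any(Matrix::diag(A) != 0)) stop("adjacency has nonzero diagonal")
  if (length(A@x) && any(A@x != 0 & A@x != 1)) {
    stop("adjacency entries must be binary")
  }
  if (!directed && !Matrix::isSymmetric(A)) {
    stop("undirected layer has an asymmetric adjacency")
  }
  invisible(TRUE)
}

#' @export
print.multiplex_graph <- function(x, ...) {
  cat("multiplex_graph:", length(x$genes), "genes,",
      length(x$layers), "layers (",
      sum(x$directed), "directed ),", ncol(x$X), "features\n")
  invisible(x)
}

#' Directed symmetric normalization of an adjacency matrix
#'
#' Computes the out-neighbor operator
#' \eqn{S_\rightarrow = D_\rightarrow^{-1/2} A D_\leftarrow^{-1/2}} and its
#' in-direction mirror
#' \eqn{S_\leftarrow = D_\leftarrow^{-1/2} A^\top D_\rightarrow^{-1/2}},
#' where \eqn{D_\rightarrow} and \eqn{D_\leftarrow} are the diagonal
#' out-degree and in-degree matrices. Zero degrees contribute a factor 0
#' (no NaN/Inf), so isolated nodes neither send nor receive messages. For a
#' symmetric adjacency both operators equal the classical
#' \eqn{D^{-1/2} A D^{-1/2}}.
#'
#' @param A Binary adjacency with zero diagonal (sparse or dense).
#' @param directed Logical; if `FALSE`, `A` must be symmetric.
#' @return List with sparse `S_out`, `S_in` and integer degree vectors
#'   `d_out`, `d_in`.
#' @export
normalize_directed <- function(A, directed = TRUE) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  validate_adjacency(A, directed, nrow(A))
  d_out <- as.numeric(Matrix::rowSums(A))
  d_in <- as.numeric(Matrix::colSums(A))
  inv_sqrt <- function(d) ifelse(d > 0, 1 / sqrt(d), 0)
  Do <- Matrix::Diagonal(x = inv_sqrt(d_out))
  Di <- Matrix::Diagonal(x = inv_sqrt(d_in))
  S_out <- Do %*% A %*% Di
  S_in <- Di %*% Matrix::t(A) %*% Do
  list(S_out = methods::as(S_out, "CsparseMatrix"),
       S_in = methods::as(S_in, "CsparseMatrix"),
       d_out = d_out, d_in = d_in)
}

#' Build normalized message-passing operators for every layer
#'
#' @param mg A `multiplex_graph`.
#' @param symmetrize If `TRUE` (the no-directionality ablation), every layer
#'   is first replaced by its symmetrized adjacency `(A + t(A)) > 0`, so in-
#'   and out-operators coincide.
#' @return List (one element per layer) of [normalize_directed()] results.
#' @export
prepare_operators <- function(mg, symmetrize = FALSE) {
  lapply(seq_along(mg$layers), function(m) {
    A <- mg$layers[[m]]
    directed <- mg$directed[m]
    if (symmetrize && directed) {
      A <- methods::as((A + Matrix::t(A)) > 0, "dMatrix") * 1
      A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
      directed <- FALSE
    }
    normalize_directed(A, directed)
  })
}

#' Corrupted feature view by row permutation
#'
#' Generates the negative view used by infomax-style contrastive
#' pretraining: the feature matrix with rows permuted uniformly at random,
#' which detaches features from graph positions while preserving the feature
#' row multiset and the adjacency.
#'
#' @param X Feature matrix with at least two rows.
#' @param seed Integer seed; the permutation is reproducible given the seed.
#' @param perm Optional explicit permutation (test hook), overriding `seed`.
#' @return List with `X_tilde`, `perm` and `seed`.
#' @export
corrupt_features <- function(X, seed = NULL, perm = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to permute")
  if (is.null(perm)) {
    perm <- if (is.null(seed)) {
      sample.int(n)
    } else {
      old <- .Random.seed_get()
      set.seed(seed)
      p <- sample.int(n)
      .Random.seed_set(old)
      p
    }
  }
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  list(X_tilde = X[perm, , drop = FALSE], perm = perm, seed = seed)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Save / load a prepared multiplex graph
#'
#' Serializes a `multiplex_graph` (and optionally its normalized operators)
#' to a single file for reuse across pipeline stages.
#'
#' @param mg A `multiplex_graph`.
#' @param path File path.
#' @param operators Optional result of [prepare_operators()].
#' @return `path` invisibly; `load_multiplex()` returns the saved list.
#' @export
save_multiplex <- function(mg, path, operators = NULL) {
  saveRDS(list(version = 1L, graph = mg, operators = operators), path)
  invisible(path)
}

#' @rdname save_multiplex
#' @export
load_multiplex <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$version, 1L))
  obj
}
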