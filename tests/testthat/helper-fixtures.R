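# Small fixtures built in code.

dm <- asNamespace("drivermux")
ad_value_of <- dm$ad_value

# random binary digraph with zero diagonal
random_adjacency <- function(n, p = 0.3, directed = TRUE, seed = 1) {
  set.seed(seed)
  A <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  if (!directed) A <- (A + t(A) > 0) * 1
  diag(A) <- 0
  A
}

# tiny multiplex graph with informative features
toy_multiplex <- function(n = 20, M = 2, f = 4, seed = 1) {
  set.seed(seed)
  layers <- lapply(seq_len(M), function(m) {
    random_adjacency(n, p = 0.2, directed = (m %% 2 == 1), seed = seed + m)
  })
  X <- matrix(rnorm(n * f), n, f)
  rownames(X) <- sprintf("g%03d", seq_len(n))
  multiplex_graph(layers, X, directed = (seq_len(M) %% 2 == 1))
}

# brute-force per-node Dirichlet energy oracle:
# e_i = sum_j s_ij (h_i - h_j)^2 + (1 - sum_j s_ij) h_i^2  (componentwise)
energy_oracle <- function(H, S) {
  S <- as.matrix(S)
  n <- nrow(H)
  e <- matrix(0, n, ncol(H))
  for (i in seq_len(n)) {
    acc <- rep(0, ncol(H))
    for (j in seq_len(n)) {
      acc <- acc + S[i, j] * (H[i, ] - H[j, ])^2
    }
    e[i, ] <- acc + (1 - sum(S[i, ])) * H[i, ]^2
  }
  e
}

# naive single-graph message passing oracle for one layer
layer_oracle <- function(H, op, gamma_out, gamma_in, W_out, W_in, alpha) {
  So <- as.matrix(op$S_out)
  Si <- as.matrix(op$S_in)
  n <- nrow(H)
  out <- matrix(0, n, ncol(W_out))
  for (i in seq_len(n)) {
    mo <- rep(0, ncol(W_out))
    mi <- rep(0, ncol(W_in))
    for (j in seq_len(n)) {
      mo <- mo + So[i, j] * (H[j, ] %*% W_out)
      mi <- mi + Si[i, j] * (H[j, ] %*% W_in)
    }
    out[i, ] <- alpha * H[i, ] + gamma_out[i] * mo + gamma_in[i] * mi
  }
  out
}

expect_close <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(as.numeric(x) - as.numeric(y))), tol)
}
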