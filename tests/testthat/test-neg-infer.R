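test_that("sliding windows cover the vector with ordered complements", {
  w <- build_windows(seq_len(48), k = 8)
  expect_equal(nrow(w$a), 41L)  # m = f - k + 1
  expect_equal(ncol(w$a), 8L)
  expect_equal(ncol(w$b), 40L)

  w2 <- build_windows(c(1, 2, 3, 4), k = 2)
  expect_equal(w2$a[1, ], c(1, 2))
  expect_equal(w2$b[1, ], c(3, 4))
  expect_equal(w2$a[2, ], c(2, 3))
  expect_equal(w2$b[2, ], c(1, 4))  # complement keeps original order
  # window + complement reconstruct the sample
  for (j in 1:3) {
    expect_setequal(c(w2$a[j, ], w2$b[j, ]), 1:4)
  }
  expect_error(build_windows(1:4, k = 4), "1 <= k < f")
  expect_error(build_windows(1:4, k = 0), "1 <= k < f")
})

test_that("ICL loss matches the softmax oracle and its closed cases", {
  # zero-weight encoders embed everything to the zero vector, so all
  # similarities are equal and the loss is ln m
  zero_mlp <- function(d_in) list(W1 = matrix(0, d_in, 4),
                                  b1 = matrix(0, 1, 4),
                                  W2 = matrix(0, 4, 3),
                                  b2 = matrix(0, 1, 3))
  model <- structure(list(F = zero_mlp(2), G = zero_mlp(2), tau = 0.1, k = 2),
                     class = "icl_model")
  w <- build_windows(c(1, 2, 3, 4), k = 2)  # m = 3
  for (j in 1:3) expect_equal(icl_loss(model, w, j), log(3), tolerance = 1e-10)
  expect_equal(icl_score(model, c(1, 2, 3, 4)), 3 * log(3), tolerance = 1e-9)

  # single candidate: loss 0 regardless of the model
  w1 <- list(a = w$a[1, , drop = FALSE], b = w$b[1, , drop = FALSE], k = 2)
  expect_equal(icl_loss(model, w1, 1), 0, tolerance = 1e-12)

  # random encoders vs direct formula evaluation
  set.seed(11)
  rnd_mlp <- function(d_in) list(W1 = matrix(rnorm(d_in * 4), d_in, 4),
                                 b1 = matrix(rnorm(4), 1, 4),
                                 W2 = matrix(rnorm(12), 4, 3),
                                 b2 = matrix(rnorm(3), 1, 3))
  model2 <- structure(list(F = rnd_mlp(2), G = rnd_mlp(2), tau = 0.5, k = 2),
                      class = "icl_model")
  fwd <- function(p, x) {
    h <- pmax(x %*% p$W1 + matrix(p$b1, nrow(x), 4, byrow = TRUE), 0)
    o <- h %*% p$W2 + matrix(p$b2, nrow(x), 3, byrow = TRUE)
    o / sqrt(rowSums(o^2) + 1e-12)
  }
  fe <- fwd(model2$F, w$b)
  ge <- fwd(model2$G, w$a)
  sim <- fe %*% t(ge) / 0.5
  for (j in 1:3) {
    oracle <- -log(exp(sim[j, j]) / sum(exp(sim[j, ])))
    expect_equal(icl_loss(model2, w, j), oracle, tolerance = 1e-9)
    expect_gte(icl_loss(model2, w, j), 0)
  }
})

test_that("ICL training reduces the loss and is seed-deterministic", {
  set.seed(12)
  X_pos <- matrix(rnorm(20 * 10), 20, 10)
  m1 <- train_icl(X_pos, k = 4, epochs = 30, seed = 5)
  expect_lt(mean(tail(m1$loss, 5)), m1$loss[1])
  m2 <- train_icl(X_pos, k = 4, epochs = 30, seed = 5)
  expect_identical(m1$loss, m2$loss)
  x_new <- rnorm(10)
  expect_identical(icl_score(m1, x_new), icl_score(m2, x_new))
  expect_error(train_icl(X_pos, k = 4, tau = 0), "positive")
  expect_error(train_icl(X_pos[1, , drop = FALSE], k = 4), "at least 2")
})

test_that("anomaly scores rank planted outliers above held-out positives", {
  gaps <- vapply(1:5, function(s) {
    set.seed(100 + s)
    f <- 12
    # positives share a latent factor, so every window carries information
    # about its complement; outliers are factor-free noise of matched scale
    u <- rnorm(f)
    make_pos <- function(n) {
      z <- rnorm(n)
      z %*% t(u) + 0.5 * matrix(rnorm(n * f), n, f)
    }
    pos <- make_pos(24)
    held <- make_pos(10)
    out <- matrix(rnorm(10 * f), 10, f) * sqrt(mean(u^2) + 0.25)
    model <- train_icl(pos, k = 4, epochs = 25, seed = s)
    sc_held <- apply(held, 1, function(x) icl_score(model, x))
    sc_out <- apply(out, 1, function(x) icl_score(model, x))
    mean(sc_out) - mean(sc_held)
  }, numeric(1))
  expect_gt(mean(gaps), 0)
  expect_gt(mean(gaps > 0), 0.5)
})

test_that("selection takes the top-scored candidates with stable ties", {
  zero_mlp <- function(d_in) list(W1 = matrix(0, d_in, 4),
                                  b1 = matrix(0, 1, 4),
                                  W2 = matrix(0, 4, 3),
                                  b2 = matrix(0, 1, 3))
  model <- structure(list(F = zero_mlp(3), G = zero_mlp(2), tau = 0.1, k = 2),
                     class = "icl_model")
  X <- matrix(rnorm(6 * 5), 6, 5)
  # all scores tie at m * ln m, so selection falls back to index order
  res <- score_and_select(model, X, candidates = c(5, 2, 4), n_select = 2)
  expect_equal(res$index[res$selected], c(2L, 4L))
  expect_warning(score_and_select(model, X, candidates = c(1, 2),
                                  n_select = 5), "smaller")
  # scores are sums of nonnegative terms
  expect_true(all(res$score >= 0))
})

test_that("negative inference avoids positives and pseudo-positives", {
  set.seed(14)
  feats <- matrix(rnorm(40 * 10), 40, 10)
  res <- infer_negatives(feats, positives = 1:8, n_select = 8,
                         exclude = 9:12, k = 4, epochs = 15, seed = 2)
  expect_length(res$negatives, 8L)
  expect_length(intersect(res$negatives, 1:12), 0L)
})
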