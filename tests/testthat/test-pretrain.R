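test_that("graph readout is a column mean", {
  u <- c(1, -2, 3)
  H <- rbind(u, u, u)
  expect_close(graph_readout(H), matrix(u, 1), 1e-15)
  H2 <- rbind(u, -u)
  expect_close(graph_readout(H2), matrix(0, 1, 3), 1e-15)
  set.seed(4)
  H3 <- matrix(rnorm(20), 5, 4)
  naive <- vapply(1:4, function(j) mean(H3[, j]), numeric(1))
  expect_close(graph_readout(H3), matrix(naive, 1), 1e-12)
  # pooling restricted to labeled positives
  expect_close(graph_readout(H3, nodes = c(1, 3)),
               matrix(colMeans(H3[c(1, 3), ]), 1), 1e-12)
  expect_error(graph_readout(H3[0, , drop = FALSE]), "empty")
})

test_that("contrastive loss matches direct evaluation of the formula", {
  set.seed(5)
  n <- 6; w <- 3
  H_pos <- matrix(rnorm(n * w), n, w)
  H_neg <- matrix(rnorm(n * w), n, w)
  # zero discriminator makes every score 0
  loss0 <- contrastive_loss(H_pos, H_neg, matrix(0, w, w),
                            matrix(1, 1, w))
  expect_equal(as.numeric(loss0), log(2) + log(1 + exp(-1)), tolerance = 1e-10)
  # the conventional variant gives 2 ln 2 at score 0
  loss0b <- contrastive_loss(H_pos, H_neg, matrix(0, w, w), matrix(1, 1, w),
                             negative_form = "one_minus_sigmoid")
  expect_equal(as.numeric(loss0b), 2 * log(2), tolerance = 1e-10)

  # random inputs vs a naive elementwise oracle
  M <- matrix(rnorm(w * w), w, w)
  g <- matrix(rnorm(w), 1, w)
  s_pos <- as.numeric(H_pos %*% M %*% t(g))
  s_neg <- as.numeric(H_neg %*% M %*% t(g))
  oracle <- -mean(log(plogis(s_pos))) - mean(log(plogis(1 - s_neg)))
  expect_equal(as.numeric(contrastive_loss(H_pos, H_neg, M, g)), oracle,
               tolerance = 1e-10)
  expect_gte(as.numeric(contrastive_loss(H_pos, H_neg, M, g)), 0)

  # perfect discrimination drives the loss to 0
  big <- 50
  loss_perfect <- contrastive_loss(matrix(big, n, 1), matrix(-big, n, 1),
                                   matrix(1, 1, 1), matrix(1, 1, 1))
  expect_lt(as.numeric(loss_perfect), 1e-8)
})

test_that("consensus loss follows the signed squared-distance identity", {
  set.seed(6)
  n <- 5; w <- 3
  Hp <- lapply(1:3, function(i) matrix(rnorm(n * w), n, w))
  Hn <- lapply(1:3, function(i) matrix(rnorm(n * w), n, w))
  Zp <- Reduce(`+`, Hp) / 3
  # Z at the positive mean with distinct negative mean is strictly negative
  v <- as.numeric(consensus_loss(Zp, Hp, Hn))
  expect_lt(v, 0)
  # equal means on both sides give 0
  expect_equal(as.numeric(consensus_loss(Zp, Hp, Hp)), 0)
  # swapping the view sets flips the sign
  expect_equal(as.numeric(consensus_loss(Zp, Hn, Hp)), -v, tolerance = 1e-10)
  # matches direct Frobenius evaluation
  Z <- matrix(rnorm(n * w), n, w)
  Zn <- Reduce(`+`, Hn) / 3
  direct <- sum((Z - Zp)^2) - sum((Z - Zn)^2)
  expect_equal(as.numeric(consensus_loss(Z, Hp, Hn)), direct,
               tolerance = 1e-10)
})

test_that("pretraining reduces the objective and separates the views", {
  d <- generate_synthetic(synth_config(n = 50, M = 2, n_directed = 1, f = 8,
                                       n_positives = 10, effect = 1.5,
                                       density = 0.1, seed = 21))
  mg <- d$graph
  pre <- pretrain_consensus(mg, hidden = 8, n_layers = 1, epochs = 15,
                            dropout = 0, seed = 3)
  expect_lt(pre$loss[2], pre$loss[1])
  expect_lt(min(pre$loss), pre$loss[1])
  expect_equal(dim(pre$Z), c(50L, 8L))
  expect_true(all(is.finite(pre$Z)))

  # separation property: positive-view scores exceed corrupted-view scores
  # (mean over graphs), averaged over 5 seeds
  seps <- vapply(1:5, function(s) {
    dd <- generate_synthetic(synth_config(n = 40, M = 2, n_directed = 1,
                                          f = 8, n_positives = 8,
                                          effect = 1.5, density = 0.12,
                                          seed = 30 + s))
    pp <- pretrain_consensus(dd$graph, hidden = 8, n_layers = 1, epochs = 18,
                             dropout = 0, seed = s)
    ops <- prepare_operators(dd$graph)
    gap <- 0
    set.seed(s)
    Xn <- dd$graph$X[sample.int(40), ]
    for (m in 1:2) {
      Hp <- mdgcn_embed(pp$params, ops, dd$graph$X, graphs = m)
      Hn <- mdgcn_embed(pp$params, ops, Xn, graphs = m)
      g <- graph_readout(Hp)
      sp <- Hp %*% pp$discriminators[[m]] %*% t(g)
      sn <- Hn %*% pp$discriminators[[m]] %*% t(g)
      gap <- gap + mean(sp) - mean(sn)
    }
    gap / 2
  }, numeric(1))
  expect_gt(mean(seps), 0)
})

test_that("the objective is additive over graphs in its contrastive part", {
  d <- generate_synthetic(synth_config(n = 30, M = 3, f = 6, n_positives = 6,
                                       density = 0.15, seed = 22))
  mg <- d$graph
  ops <- prepare_operators(mg)
  p <- mdgcn_params(6, hidden = 5, n_layers = 1, n_graphs = 3,
                    max_degree = 16, seed = 8)
  set.seed(9)
  disc <- lapply(1:3, function(m) matrix(rnorm(25), 5, 5))
  Xn <- mg$X[sample.int(30), ]
  per_graph <- vapply(1:3, function(m) {
    Hp <- mdgcn_embed(p, ops, mg$X, graphs = m)
    Hn <- mdgcn_embed(p, ops, Xn, graphs = m)
    as.numeric(contrastive_loss(Hp, Hn, disc[[m]], graph_readout(Hp)))
  }, numeric(1))
  expect_equal(sum(per_graph), per_graph[1] + per_graph[2] + per_graph[3])
  expect_true(all(per_graph >= 0))
})
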