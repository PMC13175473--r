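test_that("Chebyshev recurrence matches the direct polynomial", {
  A <- random_adjacency(8, p = 0.4, directed = FALSE, seed = 31)
  X <- matrix(rnorm(8 * 3), 8, 3)
  Lhat <- dm$scaled_laplacian(A)
  Tk <- dm$cheb_features(Lhat, X, K = 2)
  expect_identical(Tk[[1]], X)                     # T0 = I
  expect_close(Tk[[2]], as.matrix(Lhat %*% X), 1e-12)
  Ld <- as.matrix(Lhat)
  expect_close(Tk[[3]], (2 * Ld %*% Ld - diag(8)) %*% X, 1e-9)
  # scaled spectrum lies in [-1, 1]
  ev <- eigen(Ld, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(max(ev), 1 + 1e-8)
  expect_gte(min(ev), -1 - 1e-8)
})

test_that("class probabilities are row-stochastic and train on labels", {
  d <- generate_synthetic(synth_config(n = 60, M = 2, f = 8, n_positives = 12,
                                       effect = 2, density = 0.1, seed = 41))
  mg <- d$graph
  A <- union_adjacency(mg)
  pos <- d$positives
  set.seed(1)
  neg <- sample(setdiff(seq_len(60), which(d$truth == 1)), length(pos))
  model <- fit_prob_model(mg$X, A, c(pos, neg),
                          c(rep(1, length(pos)), rep(0, length(neg))),
                          K = 2, epochs = 100, seed = 2)
  P <- class_probabilities(model, mg$X)
  expect_close(rowSums(P), rep(1, 60), 1e-6)
  expect_true(all(P >= 0))
  # labeled positives get a higher mean positive probability than negatives
  expect_gt(mean(P[pos, 2]), mean(P[neg, 2]))
})

test_that("prediction entropy matches its closed cases", {
  expect_equal(prediction_entropy(matrix(c(0.5, 0.5), 1)), log(2),
               tolerance = 1e-12)
  expect_equal(prediction_entropy(matrix(c(1, 0), 1)), 0)
  expect_equal(prediction_entropy(matrix(c(0.9, 0.1), 1)),
               -0.9 * log(0.9) - 0.1 * log(0.1), tolerance = 1e-12)
  # bounded by ln C
  set.seed(3)
  p1 <- runif(20)
  P <- cbind(p1, 1 - p1)
  H <- prediction_entropy(P)
  expect_true(all(H >= 0 & H <= log(2) + 1e-12))
})

test_that("entropy ranking keeps positive-leaning low-entropy candidates", {
  P <- rbind(c(0.05, 0.95),   # node 1: confident positive
             c(0.45, 0.55),   # node 2: uncertain positive
             c(0.30, 0.70),   # node 3: mid positive
             c(0.90, 0.10),   # node 4: confident negative
             c(0.20, 0.80))   # node 5: labeled, must be ignored
  cand <- entropy_rank(P, unlabeled = 1:4, retain_count = 2)
  expect_equal(cand$index, c(1L, 3L))  # ascending entropy, negatives excluded
  expect_equal(cand$p_pos, c(0.95, 0.70))
  expect_equal(nrow(entropy_rank(P, 1:4, 0)), 0L)
})

test_that("RBF spectral clustering recovers separated blobs", {
  set.seed(7)
  blob1 <- matrix(rnorm(30, mean = 0), 15, 2)
  blob2 <- matrix(rnorm(30, mean = 6), 15, 2)
  fit <- rbf_cluster_positives(rbind(blob1, blob2), seed = 5)
  cl <- fit$cluster
  expect_true(all(cl[1:15] == cl[1]) && all(cl[16:30] == cl[16]))
  expect_false(cl[1] == cl[16])
  # centroids close to the standardized blob means
  phi <- scale(rbind(blob1, blob2),
               center = fit$center, scale = fit$scale)
  mu_blob <- rbind(colMeans(phi[1:15, ]), colMeans(phi[16:30, ]))
  d_cent <- min(sum((fit$centroids[1, ] - mu_blob[1, ])^2),
                sum((fit$centroids[1, ] - mu_blob[2, ])^2))
  expect_lt(d_cent, 0.05)
  expect_error(rbf_cluster_positives(matrix(1, 4, 2)), "degenerate|identical")
  expect_error(rbf_cluster_positives(blob1[1, , drop = FALSE]), "at least 2")
})

test_that("a singleton cluster's centroid equals its member", {
  X <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(10, 10))
  fit <- rbf_cluster_positives(X, seed = 2)
  k_single <- which(tabulate(fit$cluster, 2) == 1L)
  member <- which(fit$cluster == k_single)
  phi <- (X[member, ] - fit$center) / fit$scale
  expect_close(fit$centroids[k_single, ], phi, 1e-12)
  # distance of that member to its own centroid is zero
  expect_lt(fit$d_pos[member], 1e-12)
})

test_that("selection rule boundaries are inclusive and the set can be empty", {
  cand <- data.frame(index = 1:3, p_pos = c(0.8, 0.799, 0.9),
                     entropy = c(0.3, 0.2, 0.1))
  d_pos <- c(1, 2, 3)  # mean 2, population sd sqrt(2/3)
  thr <- 2 + sqrt(2 / 3)
  sel <- select_pseudo_positives(cand, distances = c(thr, 0.1, thr + 1e-9),
                                 d_pos = d_pos, theta_p = 0.8)
  # p = theta exactly and d = mean+sd exactly are included (>=, <=);
  # p below theta and d above threshold are excluded
  expect_equal(sel$index, 1L)
  expect_equal(attr(sel, "d_threshold"), thr)
  empty <- select_pseudo_positives(cand[0, ], numeric(0), d_pos)
  expect_equal(nrow(empty), 0L)
})

test_that("the distance clause only ever filters the candidate set", {
  d <- generate_synthetic(synth_config(n = 80, M = 2, f = 8, n_positives = 16,
                                       effect = 1.5, density = 0.1,
                                       hidden_frac = 0.25, seed = 43))
  with_f <- augment_positives(d$graph, d$positives, epochs = 60, seed = 4)
  without_f <- augment_positives(d$graph, d$positives, epochs = 60, seed = 4,
                                 use_distance_filter = FALSE)
  expect_true(all(with_f$index %in% without_f$index))
  # pseudo-labels never overlap the labeled positives
  expect_length(intersect(with_f$index, d$positives), 0L)
})
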