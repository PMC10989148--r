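# dgi_gnn: normalized operator, GCN forward, corruption, discriminator,
# objective, gradients, training.

test_that("adjacency augmentation and normalization match hand computations", {
  # single node, no edges
  S1 <- augment_and_normalize_adjacency(matrix(0, 1, 1), alpha = 0.8)
  expect_equal(as.matrix(S1), matrix(1))

  # two nodes, one edge: A~ = [[.8,.2],[.2,.8]], row sums 1 -> S = A~
  A2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(as.matrix(augment_adjacency(A2, 0.8)),
               matrix(c(0.8, 0.2, 0.2, 0.8), 2))
  S2 <- augment_and_normalize_adjacency(A2, 0.8)
  expect_equal(as.matrix(S2), matrix(c(0.8, 0.2, 0.2, 0.8), 2))

  # spectral radius <= 1 on random graphs (eigendecomposition oracle)
  for (s in 1:6) {
    n <- sample(3:20, 1)
    A <- random_adjacency(n, 0.4, seed = s)
    S <- augment_and_normalize_adjacency(A, alpha = 0.8)
    ev <- eigen(as.matrix(S), symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-9)
    expect_true(Matrix::isSymmetric(S))
  }

  # isolated node with alpha = 0 has a zero row sum
  A_iso <- matrix(0, 3, 3); A_iso[1, 2] <- A_iso[2, 1] <- 1
  expect_error(augment_and_normalize_adjacency(A_iso, alpha = 0),
               "alpha > 0")
  expect_error(augment_adjacency(A2, 1.2), "\\[0, 1\\]")
  expect_error(augment_and_normalize_adjacency(diag(2)), "zero diagonal")
})

test_that("gcn_forward equals the dense matrix-product oracle", {
  # identity operator, identity weights, identity activation -> X unchanged
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_forward(diag(4), X, list(diag(3)), "identity"), X)

  # 1-node graph: H = act(X W)
  S1 <- augment_and_normalize_adjacency(matrix(0, 1, 1), 0.8)
  W <- matrix(rnorm(6), 3, 2)
  X1 <- matrix(c(1, -2, 3), 1)
  expect_equal(gcn_forward(S1, X1, list(W), "prelu", 0.25),
               ifelse(X1 %*% W > 0, X1 %*% W, 0.25 * (X1 %*% W)))

  # random graphs <= 20 nodes vs an explicit dense loop oracle
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(5:20, 1)
    A <- random_adjacency(n, 0.3, seed = 200 + s)
    X <- matrix(rnorm(n * 4), n, 4)
    Ws <- list(matrix(rnorm(4 * 6, sd = 0.5), 4, 6),
               matrix(rnorm(6 * 3, sd = 0.5), 6, 3))
    slopes <- c(0.25, 0.1)
    S <- augment_and_normalize_adjacency(A, 0.8)
    got <- gcn_forward(S, X, Ws, "prelu", slopes)

    # oracle: dense normalization and triple loops, no Matrix involved
    At <- 0.8 * diag(n) + 0.2 * A
    d <- rowSums(At)
    Sd <- diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
    H <- X
    for (l in 1:2) {
      Z <- matrix(0, n, ncol(Ws[[l]]))
      SH <- matrix(0, n, ncol(H))
      for (i in 1:n) for (k in seq_len(ncol(H))) {
        SH[i, k] <- sum(Sd[i, ] * H[, k])
      }
      for (i in 1:n) for (k in seq_len(ncol(Z))) {
        Z[i, k] <- sum(SH[i, ] * Ws[[l]][, k])
      }
      H <- ifelse(Z > 0, Z, slopes[l] * Z)
    }
    expect_equal(got, H, tolerance = 1e-6)
  }

  expect_error(gcn_forward(diag(3), matrix(0, 3, 2), list(diag(3))),
               "shape mismatch")
})

test_that("graph corruption permutes rows uniformly and reproducibly", {
  X <- matrix(rnorm(20), 5, 4)
  Xc <- corrupt_graph(X, seed = 3)
  expect_equal(apply(X, 2, sort), apply(Xc, 2, sort))  # row multiset kept
  expect_false(all(attr(Xc, "perm") == 1:5))           # identity excluded
  expect_identical(corrupt_graph(X, seed = 3), Xc)     # seeded determinism

  X2 <- matrix(1:4, 2, 2)
  Xc2 <- corrupt_graph(X2, seed = 1)
  expect_equal(attr(Xc2, "perm"), c(2L, 1L))           # only the swap
})

test_that("readout and discriminator follow the closed forms", {
  H0 <- matrix(0, 4, 3)
  B <- matrix(rnorm(9), 3, 3)
  rd <- readout_and_discriminate(H0, B)
  expect_equal(rd$summary, rep(0.5, 3))
  expect_equal(rd$scores, rep(0.5, 4))

  H <- matrix(rnorm(12), 4, 3)
  expect_equal(readout_and_discriminate(H, matrix(0, 3, 3))$scores,
               rep(0.5, 4))

  rd2 <- readout_and_discriminate(H, B)
  s_direct <- 1 / (1 + exp(-colMeans(H)))
  scores_direct <- sapply(1:4, function(i)
    1 / (1 + exp(-sum(H[i, ] * (B %*% s_direct)))))
  expect_equal(rd2$summary, s_direct, tolerance = 1e-9)
  expect_equal(rd2$scores, scores_direct, tolerance = 1e-9)
})

test_that("the DGI objective matches its closed forms and stays <= 0", {
  expect_equal(dgi_objective(0.5, 0.5), 2 * log(0.5))
  # perfect discrimination approaches the supremum 0 from below
  expect_gt(suppressMessages(dgi_objective(1, 0)), -1e-5)
  expect_lte(suppressMessages(dgi_objective(1, 0)), 0)

  set.seed(8)
  p <- runif(10); q <- runif(7)
  oracle <- sum(sapply(p, log)) + sum(sapply(q, function(x) log(1 - x)))
  expect_equal(dgi_objective(p, q), oracle, tolerance = 1e-9)
  expect_lte(dgi_objective(p, q), 0)
  # uninformative scores: exactly -(N + M) ln 2
  expect_equal(dgi_objective(rep(0.5, 10), rep(0.5, 7)), -17 * log(2))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(21)
  n <- 6
  A <- random_adjacency(n, 0.5, seed = 7)
  S <- augment_and_normalize_adjacency(A, 0.8)
  X <- matrix(rnorm(n * 3), n, 3)
  Xc <- corrupt_graph(X, seed = 2)
  params <- list(W = list(matrix(rnorm(3 * 4, sd = 0.5), 3, 4),
                          matrix(rnorm(4 * 4, sd = 0.5), 4, 4)),
                 slope = c(0.25, 0.3),
                 B = matrix(rnorm(16, sd = 0.5), 4, 4))
  g <- coexpanel:::dgi_loss_grads(S, X, Xc, params, "prelu")
  loss_of <- function(p) {
    -coexpanel:::dgi_loss_grads(S, X, Xc, p, "prelu")$objective / (2 * n)
  }
  h <- 1e-6
  # spot-check several coordinates of every parameter block
  for (l in 1:2) {
    for (idx in list(c(1, 1), c(2, 3))) {
      p2 <- params
      p2$W[[l]][idx[1], idx[2]] <- p2$W[[l]][idx[1], idx[2]] + h
      fd <- (loss_of(p2) - loss_of(params)) / h
      expect_equal(g$gW[[l]][idx[1], idx[2]], fd, tolerance = 1e-3)
    }
    p2 <- params
    p2$slope[l] <- p2$slope[l] + h
    fd <- (loss_of(p2) - loss_of(params)) / h
    expect_equal(g$gslope[l], fd, tolerance = 1e-3)
  }
  for (idx in list(c(1, 2), c(4, 4))) {
    p2 <- params
    p2$B[idx[1], idx[2]] <- p2$B[idx[1], idx[2]] + h
    fd <- (loss_of(p2) - loss_of(params)) / h
    expect_equal(g$gB[idx[1], idx[2]], fd, tolerance = 1e-3)
  }
})

make_block_graph <- function(n_per_block = 50, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_block * 4, 0), ncol = 4),
             matrix(rnorm(n_per_block * 4, 3), ncol = 4),
             matrix(rnorm(n_per_block * 4, -3), ncol = 4))
  rownames(X) <- sprintf("g%03d", seq_len(nrow(X)))
  lay <- cbind(rnorm(3 * n_per_block, rep(c(0, 20, 40), each = n_per_block)),
               rnorm(3 * n_per_block))
  cal <- calibrate_threshold(lay, 5)
  build_graph(rownames(X), X, lay, cal$threshold)
}

test_that("DGI training improves the objective, is seeded, and is equivariant", {
  g <- make_block_graph()
  cfg <- gcn_config(hidden_dim = 16, epochs = 80, seed = 4)
  fit1 <- train_and_embed(g, cfg)
  fit2 <- train_and_embed(g, cfg)
  expect_identical(fit1$state$log, fit2$state$log)  # bitwise reproducible
  expect_identical(fit1$embeddings, fit2$embeddings)

  # optimization makes progress from the epoch-0 objective (5 seeds,
  # tolerate one failure)
  gains <- sapply(1:5, function(s) {
    fit <- train_and_embed(g, gcn_config(hidden_dim = 16, epochs = 80,
                                         seed = s))
    max(fit$state$log$objective) > fit$state$log$objective[1]
  })
  expect_gte(sum(gains), 4)

  # permutation equivariance with the corruption permutations injected
  n <- length(g$node_ids)
  perms <- lapply(1:20, function(i) {
    set.seed(1000 + i); sample(n)
  })
  cfg_eq <- gcn_config(hidden_dim = 8, epochs = 20, seed = 9)
  fit_a <- train_and_embed(g, cfg_eq, corruption_perms = perms)
  pi_ <- sample(n)
  g_p <- build_graph(g$node_ids[pi_], g$X[pi_, ], g$layout2d[pi_, ],
                     g$threshold)
  inv <- order(pi_)
  perms_p <- lapply(perms, function(pp) inv[pp[pi_]])
  fit_b <- train_and_embed(g_p, cfg_eq, corruption_perms = perms_p)
  expect_equal(fit_b$embeddings, fit_a$embeddings[pi_, ],
               tolerance = 1e-8)
})

test_that("training aborts with diagnostics on a non-finite objective", {
  g <- make_block_graph(20, seed = 3)
  g$X[1, 1] <- NaN  # poisoned feature propagates to the objective
  expect_error(
    train_and_embed(g, gcn_config(hidden_dim = 8, epochs = 50, seed = 1)),
    "non-finite DGI objective at epoch 1")
})
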