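# dgi_gnn: GCN encoder trained with the Deep Graph Infomax objective.
#
# The encoder stacks GCN layers H(l+1) = PReLU(S H(l) W(l)) on the
# self-loop-augmented, symmetrically normalized operator
# S = D^{-1/2} ((1 - alpha) A + alpha I) D^{-1/2}. Training contrasts node
# embeddings of the real graph against embeddings of a feature-permuted
# (corrupted) copy through a bilinear discriminator against the sigmoid of
# the mean-pooled graph summary, maximizing
# L = sum_i log D(h_i, s) + sum_j log(1 - D(h'_j, s)).
# All gradients are derived in closed form and optimized with Adam.

#' Configuration of the GCN encoder and DGI training loop
#'
#' @param alpha self-loop strength in \[0, 1\] of the augmented adjacency
#'   `(1 - alpha) A + alpha I` (default 0.8).
#' @param n_layers number of GCN layers (default 2).
#' @param hidden_dim width of every hidden/embedding layer (default 64).
#' @param activation elementwise nonlinearity; `"prelu"` (parametric
#'   rectified linear unit, learnable slope per layer) or `"identity"`.
#' @param epochs maximum training epochs (default 300).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param patience early-stopping patience in epochs without objective
#'   improvement beyond `tol` (default 30).
#' @param tol objective improvement tolerance for early stopping
#'   (default 1e-4).
#' @param seed RNG seed controlling initialization and per-epoch corruption.
#' @return a `gcn_config` list.
#' @export
gcn_config <- function(alpha = 0.8, n_layers = 2, hidden_dim = 64,
                       activation = c("prelu", "identity"), epochs = 300,
                       learning_rate = 1e-3, patience = 30, tol = 1e-4,
                       seed = 0) {
  activation <- match.arg(activation)
  if (alpha < 0 || alpha > 1) {
    abort("alpha must be in [0, 1]", "coexpanel_config_error")
  }
  if (n_layers < 1 || hidden_dim < 1) {
    abort("layer count and width must be positive", "coexpanel_config_error")
  }
  structure(list(alpha = alpha, n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim), activation = activation,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 patience = as.integer(patience), tol = tol,
                 seed = as.integer(seed)),
            class = "gcn_config")
}

#' Add self-loops to an adjacency matrix
#'
#' Computes the augmented adjacency `(1 - alpha) A + alpha I`; with the
#' default `alpha = 0.8` a zero-diagonal adjacency gains diagonal entries of
#' exactly 0.8.
#'
#' @param A symmetric 0/1 adjacency matrix with zero diagonal (dense or
#'   `Matrix` sparse).
#' @param alpha self-loop strength in \[0, 1\].
#' @return the augmented matrix (sparse if `A` was).
#' @export
augment_adjacency <- function(A, alpha = 0.8) {
  if (alpha < 0 || alpha > 1) {
    abort("alpha must be in [0, 1]", "coexpanel_config_error")
  }
  (1 - alpha) * A + alpha * Matrix::Diagonal(nrow(A))
}

#' Self-loop augmented, symmetrically normalized graph operator
#'
#' Returns `S = D^{-1/2} ((1 - alpha) A + alpha I) D^{-1/2}` where `D` is the
#' diagonal row-sum matrix of the augmented adjacency. `S` is symmetric with
#' spectral radius <= 1.
#'
#' @inheritParams augment_adjacency
#' @return sparse symmetric operator.
#' @export
augment_and_normalize_adjacency <- function(A, alpha = 0.8) {
  if (!inherits(A, "Matrix")) A <- Matrix::Matrix(A, sparse = TRUE)
  if (!Matrix::isSymmetric(A)) {
    abort("adjacency must be symmetric", "coexpanel_input_error")
  }
  if (any(Matrix::diag(A) != 0)) {
    abort("adjacency must have a zero diagonal", "coexpanel_input_error")
  }
  At <- augment_adjacency(A, alpha)
  d <- Matrix::rowSums(At)
  if (any(d <= 0)) {
    abort("zero row sum in augmented adjacency (isolated node with alpha = 0); use alpha > 0",
          "coexpanel_input_error")
  }
  Dis <- Matrix::Diagonal(x = 1 / sqrt(d))
  Dis %*% At %*% Dis
}

prelu <- function(z, slope) ifelse(z > 0, z, slope * z)
prelu_grad <- function(z, slope) ifelse(z > 0, 1, slope)

apply_activation <- function(z, activation, slope) {
  switch(activation, prelu = prelu(z, slope), identity = z)
}

#' GCN forward pass
#'
#' Applies `H(l+1) = act(S H(l) W(l))` starting from `H(0) = X` and returns
#' the final layer.
#'
#' @param S normalized graph operator from
#'   [augment_and_normalize_adjacency()].
#' @param X node feature matrix.
#' @param weights list of weight matrices with a consistent shape chain.
#' @param activation `"prelu"` or `"identity"`.
#' @param slopes numeric vector of PReLU slopes, one per layer.
#' @return dense matrix of final-layer embeddings.
#' @export
gcn_forward <- function(S, X, weights, activation = "prelu",
                        slopes = rep(0.25, length(weights))) {
  H <- as.matrix(X)
  for (l in seq_along(weights)) {
    W <- weights[[l]]
    if (ncol(H) != nrow(W)) {
      abort(sprintf("layer %d shape mismatch: H has %d columns, W has %d rows",
                    l, ncol(H), nrow(W)), "coexpanel_config_error")
    }
    Z <- as.matrix(S %*% H) %*% W
    H <- apply_activation(Z, activation, slopes[l])
  }
  H
}

#' Corrupt a graph by permuting node features
#'
#' Returns a row permutation of `X` (the adjacency is left untouched). The
#' permutation is drawn uniformly, excluding the identity when N >= 2, and is
#' attached as attribute `"perm"`.
#'
#' @param X node feature matrix with N >= 2 rows.
#' @param seed optional RNG seed.
#' @param perm optional explicit permutation (integer vector), bypassing the
#'   random draw; used for equivariance checks.
#' @return permuted copy of `X` with attribute `perm`.
#' @export
corrupt_graph <- function(X, seed = NULL, perm = NULL) {
  n <- nrow(X)
  if (n < 2) abort("need >= 2 nodes to corrupt", "coexpanel_input_error")
  if (is.null(perm)) {
    if (!is.null(seed)) set.seed(seed)
    perm <- sample.int(n)
    while (all(perm == seq_len(n))) perm <- sample.int(n)
  }
  Xp <- X[perm, , drop = FALSE]
  rownames(Xp) <- rownames(X)
  attr(Xp, "perm") <- perm
  Xp
}

#' Readout and bilinear discrimination
#'
#' The graph summary is the sigmoid of the column means of the embeddings,
#' `s = sigmoid(mean_i h_i)`; each node is scored with the bilinear
#' discriminator `D(h, s) = sigmoid(h' B s)`.
#'
#' @param H embedding matrix (N x d).
#' @param B bilinear discriminator matrix (d x d).
#' @param summary optional externally supplied summary vector (used to score
#'   corrupted embeddings against the real graph's summary).
#' @return list with `summary` (length-d vector) and `scores` (length-N
#'   vector in (0, 1)).
#' @export
readout_and_discriminate <- function(H, B, summary = NULL) {
  if (nrow(H) == 0) abort("empty embedding matrix", "coexpanel_input_error")
  s <- summary %||% sigmoid(colMeans(H))
  scores <- as.vector(sigmoid(H %*% (B %*% s)))
  list(summary = s, scores = scores)
}

#' Deep Graph Infomax objective
#'
#' `L = sum_i log D(h_i, s) + sum_j log(1 - D(h'_j, s))` on the natural-log
#' scale; training maximizes `L` (equivalently minimizes the binary
#' cross-entropy `-L`). Scores exactly 0 or 1 are clamped to
#' `[1e-7, 1 - 1e-7]` with a message.
#'
#' @param positive_scores discriminator scores of real nodes.
#' @param negative_scores discriminator scores of corrupted nodes.
#' @return the objective value (always <= 0).
#' @export
dgi_objective <- function(positive_scores, negative_scores) {
  clamp <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
  if (any(positive_scores <= 0 | positive_scores >= 1) ||
      any(negative_scores <= 0 | negative_scores >= 1)) {
    message("dgi_objective: scores at 0/1 clamped to [1e-7, 1 - 1e-7]")
  }
  sum(log(clamp(positive_scores))) + sum(log(1 - clamp(negative_scores)))
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Forward + closed-form gradients of the (negated, mean-scaled) DGI loss for
# one corruption. Returns the objective and gradients for every parameter.
# Kept internal; the finite-difference test in the suite checks it.
dgi_loss_grads <- function(S, X, Xc, params, activation) {
  L <- length(params$W)
  N <- nrow(X)
  fwd <- function(X0) {
    H <- as.matrix(X0); Zs <- vector("list", L); Hs <- vector("list", L + 1)
    SH <- vector("list", L)
    Hs[[1]] <- H
    for (l in seq_len(L)) {
      SH[[l]] <- as.matrix(S %*% H)
      Zs[[l]] <- SH[[l]] %*% params$W[[l]]
      H <- apply_activation(Zs[[l]], activation, params$slope[l])
      Hs[[l + 1]] <- H
    }
    list(H = H, Zs = Zs, Hs = Hs, SH = SH)
  }
  fp <- fwd(X)
  fc <- fwd(Xc)
  H2 <- fp$H; H2c <- fc$H
  m <- colMeans(H2)
  s <- sigmoid(m)
  Bs <- as.vector(params$B %*% s)
  u <- as.vector(H2 %*% Bs)   # positive logits
  v <- as.vector(H2c %*% Bs)  # negative logits
  p <- sigmoid(u); q <- sigmoid(v)
  objective <- sum(log(pmax(p, 1e-300))) + sum(log(pmax(1 - q, 1e-300)))

  scale <- 1 / (2 * N)  # mean-scaled loss for stable step sizes
  gU <- (p - 1) * scale  # d(-L)/du
  gV <- q * scale
  gB <- (crossprod(H2, gU) + crossprod(H2c, gV)) %*% t(s)
  gs <- as.vector(crossprod(params$B, crossprod(H2, gU) +
                              crossprod(H2c, gV)))
  gm <- gs * s * (1 - s)
  dH2 <- outer(gU, Bs) + matrix(gm / N, N, length(m), byrow = TRUE)
  dH2c <- outer(gV, Bs)

  gW <- vector("list", L)
  gslope <- numeric(L)
  backprop <- function(fwd_state, dH, X0) {
    for (l in rev(seq_len(L))) {
      Z <- fwd_state$Zs[[l]]
      dZ <- dH * switch(activation, prelu = prelu_grad(Z, params$slope[l]),
                        identity = matrix(1, nrow(Z), ncol(Z)))
      if (activation == "prelu") {
        gslope[l] <<- gslope[l] + sum(dH * Z * (Z <= 0))
      }
      gW[[l]] <<- (gW[[l]] %||% 0) + crossprod(fwd_state$SH[[l]], dZ)
      if (l > 1) dH <- as.matrix(S %*% (dZ %*% t(params$W[[l]])))
    }
  }
  backprop(fp, dH2, X)
  backprop(fc, dH2c, Xc)
  list(objective = objective, gW = gW, gB = gB, gslope = gslope)
}

adam_step <- function(theta, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the GCN with the Deep Graph Infomax objective
#'
#' Full-batch Adam ascent on the DGI objective with one fresh feature
#' permutation per epoch (M = N corrupted samples) and early stopping when
#' the objective fails to improve by `config$tol` for `config$patience`
#' epochs. Fully seeded: a fixed seed reproduces the training log bitwise on
#' the same platform. The returned embeddings come from the best-objective
#' epoch.
#'
#' @param graph a `gene_graph` from [build_graph()].
#' @param config a [gcn_config()].
#' @param corruption_perms optional list of explicit per-epoch permutations
#'   (for equivariance checks); entries beyond its length fall back to random
#'   draws.
#' @return list with `embeddings` (N x hidden_dim matrix, rownames = node
#'   ids) and `state` (weights `W`, PReLU `slope`s, discriminator `B`,
#'   training `log` data frame with columns epoch/objective).
#' @export
train_and_embed <- function(graph, config = gcn_config(),
                            corruption_perms = NULL) {
  S <- augment_and_normalize_adjacency(adjacency_matrix(graph), config$alpha)
  X <- as.matrix(graph$X)
  N <- nrow(X)
  set.seed(config$seed)
  dims <- c(ncol(X), rep(config$hidden_dim, config$n_layers))
  params <- list(
    W = lapply(seq_len(config$n_layers),
               function(l) glorot(dims[l], dims[l + 1])),
    slope = rep(0.25, config$n_layers),
    B = glorot(config$hidden_dim, config$hidden_dim))
  states <- lapply(c(params$W, list(params$B), list(params$slope)),
                   function(th) list(m = th * 0, v = th * 0, t = 0))
  log_obj <- numeric(0)
  best <- list(objective = -Inf, params = params)
  wait <- 0
  for (epoch in seq_len(config$epochs)) {
    perm <- if (!is.null(corruption_perms) &&
                epoch <= length(corruption_perms)) {
      corruption_perms[[epoch]]
    } else NULL
    Xc <- corrupt_graph(X, perm = perm)
    g <- dgi_loss_grads(S, X, Xc, params, config$activation)
    if (!is.finite(g$objective)) {
      abort(sprintf(
        "non-finite DGI objective at epoch %d (learning rate %g); reduce the learning rate",
        epoch, config$learning_rate), "coexpanel_training_error")
    }
    log_obj[epoch] <- g$objective
    if (g$objective > best$objective + config$tol) {
      best <- list(objective = g$objective, params = params)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
    for (l in seq_along(params$W)) {
      st <- adam_step(params$W[[l]], g$gW[[l]], states[[l]],
                      config$learning_rate)
      params$W[[l]] <- st$theta; states[[l]] <- st$state
    }
    st <- adam_step(params$B, g$gB, states[[length(params$W) + 1]],
                    config$learning_rate)
    params$B <- st$theta; states[[length(params$W) + 1]] <- st$state
    if (config$activation == "prelu") {
      st <- adam_step(params$slope, g$gslope, states[[length(params$W) + 2]],
                      config$learning_rate)
      params$slope <- st$theta; states[[length(params$W) + 2]] <- st$state
    }
  }
  H <- gcn_forward(S, X, best$params$W, config$activation, best$params$slope)
  rownames(H) <- graph$node_ids
  list(embeddings = H,
       state = list(W = best$params$W, slope = best$params$slope,
                    B = best$params$B,
                    log = data.frame(epoch = seq_along(log_obj),
                                     objective = log_obj),
                    config = config))
}

#' Write embeddings and the training log
#'
#' @param fit result of [train_and_embed()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_embedding_files <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- fit$embeddings
  df <- data.frame(gene = rownames(emb), emb, check.names = FALSE)
  names(df)[-1] <- paste0("e", seq_len(ncol(emb)))
  write_tsv(df, file.path(dir, "embeddings.tsv"))
  utils::write.csv(fit$state$log, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}
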