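# Shared fixture builders and independent oracles for the test suite.
# Oracles here are deliberately written as plain loops / direct formulas so
# they stay independent of the vectorized implementation paths they check.

# Quick expr_set from a matrix (genes x samples) and a condition vector.
make_expr <- function(values, conditions) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste(conditions,
                              stats::ave(seq_along(conditions), conditions,
                                         FUN = seq_along), sep = "_")
  }
  expression_set(values, stats::setNames(conditions, colnames(values)))
}

# Triplicated two-condition expression fixture with planted per-gene means
# (FPKM scale) and log-normal replicate noise.
make_two_group_expr <- function(mean_test, mean_control, sd_log10 = 0.05,
                                test = "blue", control = "dark", reps = 3,
                                seed = 1) {
  set.seed(seed)
  n <- length(mean_test)
  draw <- function(mu) {
    matrix(10^(log10(mu + 1) + stats::rnorm(n * reps, 0, sd_log10)) - 1,
           nrow = n)
  }
  vals <- cbind(draw(mean_test), draw(mean_control))
  vals[vals < 0] <- 0
  conds <- rep(c(test, control), each = reps)
  make_expr(vals, conds)
}

make_annot <- function(gene_ids, sp = 0, tm = 0, pathway = "",
                       description = "hypothetical protein") {
  df <- data.frame(gene_id = gene_ids,
                   signal_peptide = rep_len(sp, length(gene_ids)),
                   transmembrane = rep_len(tm, length(gene_ids)),
                   pathway = rep_len(pathway, length(gene_ids)),
                   description = rep_len(description, length(gene_ids)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

# Erdos-Renyi-ish random adjacency matrix (dense base matrix).
random_adjacency <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- stats::rbinom(length(up), 1, p)
  A + t(A)
}

# ---- independent graph-metric oracles (plain BFS / direct counting) ----

bfs_distances <- function(adj_list, start, n) {
  d <- rep(Inf, n)
  d[start] <- 0
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj_list[[v]]) {
      if (!is.finite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

adj_list_of <- function(A) {
  lapply(seq_len(nrow(A)), function(i) which(A[i, ] != 0))
}

oracle_degree <- function(A) rowSums(A != 0)

oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb, drop = FALSE] != 0) / 2
    2 * links / (k * (k - 1))
  })
}

# Brandes' algorithm, textbook form, unweighted.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  adj <- adj_list_of(A)
  cb <- rep(0, n)
  for (s in seq_len(n)) {
    stack <- integer(0)
    pred <- vector("list", n)
    sigma <- rep(0, n); sigma[s] <- 1
    d <- rep(-1, n); d[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      stack <- c(stack, v)
      for (w in adj[[v]]) {
        if (d[w] < 0) {
          queue <- c(queue, w)
          d[w] <- d[v] + 1
        }
        if (d[w] == d[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- rep(0, n)
    for (w in rev(stack)) {
      for (v in pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2  # undirected
}

oracle_eccentricity <- function(A) {
  n <- nrow(A)
  adj <- adj_list_of(A)
  sapply(seq_len(n), function(i) {
    d <- bfs_distances(adj, i, n)
    d <- d[is.finite(d)]
    max(d)
  })
}

# Textbook silhouette: plain double loop over points and clusters.
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  D <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(sapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Direct FAS evaluator following the printed formulas step by step.
oracle_fas <- function(labels, pathway_idx, k, M_g) {
  m <- table(labels[pathway_idx])
  N_w <- length(pathway_idx)
  r <- sort(as.numeric(m) / N_w, decreasing = TRUE)
  r_w <- N_w / M_g
  n <- length(r)
  z <- if (n <= k) sum(r) / r_w else
    (sum(r[1:k]) - sum(r[(k + 1):n])) / r_w
  log(1 + exp(z))
}

suppress_all <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}
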