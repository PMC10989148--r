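# graph_builder: node features, 2D layout, degree-calibrated threshold graph.

#' Build the node feature matrix
#'
#' Concatenates the log-normalized expression columns with the two binary
#' subcellular columns. Column order is fixed: the expression samples in
#' their matrix order, then `signal_peptide`, then `transmembrane` (so a
#' secretory gene ends in `1, 0`). With a triplicated test + control dataset
#' this gives 6 + 2 = 8 features per gene.
#'
#' @param expr_norm numeric matrix of log-normalized expression
#'   (genes x samples, rownames = gene ids), e.g. `log_normalize(expr$values)`.
#' @param annot a `gene_annotation` data frame; genes absent from it default
#'   to zero flags (logged) unless `default_missing = FALSE`.
#' @param default_missing whether missing annotations default to 0/empty.
#' @return numeric matrix (genes x (samples + 2)).
#' @export
build_node_features <- function(expr_norm, annot, default_missing = TRUE) {
  if (is.null(rownames(expr_norm))) {
    abort("expression matrix must have gene ids as rownames",
          "coexpanel_input_error")
  }
  al <- align_annotations(rownames(expr_norm), annot, default_missing)
  X <- cbind(expr_norm,
             signal_peptide = as.numeric(al$signal_peptide),
             transmembrane = as.numeric(al$transmembrane))
  X
}

#' Neighborhood-preserving 2D layout (t-SNE)
#'
#' Embeds the node feature rows into 2D with exact t-SNE (O(N^2) gradient;
#' the Barnes-Hut accuracy parameter `theta` is accepted for interface
#' compatibility but the gradient is computed exactly, i.e. at theta = 0
#' accuracy). Deterministic for a fixed `seed`.
#'
#' @param X numeric matrix (genes x features).
#' @param perplexity t-SNE perplexity (default 20); requires
#'   `nrow(X) - 1 >= 3 * perplexity`.
#' @param max_iter gradient iterations (default 1000).
#' @param theta Barnes-Hut accuracy knob, unused by the exact backend.
#' @param seed RNG seed for the random initialization (default 0).
#' @return N x 2 coordinate matrix with the rownames of `X`.
#' @export
embed_layout_2d <- function(X, perplexity = 20, max_iter = 1000, theta = 0.4,
                            seed = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n - 1 < 3 * perplexity) {
    abort(sprintf(
      "perplexity %g is too large for %d points; need N - 1 >= 3 * perplexity (reduce perplexity to <= %g)",
      perplexity, n, (n - 1) / 3), "coexpanel_parameter_error")
  }
  set.seed(seed)
  Y0 <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  Y <- tsne_exact_cpp(X, Y0, perplexity, as.integer(max_iter))
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("x", "y")
  attr(Y, "seed") <- seed
  Y
}

# Mean degree of the strict-threshold graph on a distance matrix:
# 2 * |edges| / N, i.e. each undirected edge contributes 2/N.
mean_degree_at <- function(dmat, threshold) {
  n <- nrow(dmat)
  sum(dmat[upper.tri(dmat)] < threshold) * 2 / n
}

#' Calibrate the edge distance threshold to a target mean degree
#'
#' Bisects the distance cutoff over `[0, max pairwise distance]` until the
#' achieved mean degree is within `tolerance` of the target or `max_iter`
#' iterations elapse. Mean degree is a step function of the threshold, so an
#' exact hit is not always attainable; the closest evaluated threshold is
#' then returned with a warning.
#'
#' @param layout2d N x 2 coordinate matrix.
#' @param target_mean_degree desired average degree (default 5).
#' @param tolerance acceptable deviation (default 0.25).
#' @param max_iter bisection iterations (default 60).
#' @return list with `threshold` and achieved `mean_degree`.
#' @export
calibrate_threshold <- function(layout2d, target_mean_degree = 5,
                                tolerance = 0.25, max_iter = 60) {
  n <- nrow(layout2d)
  if (n < 2) abort(">= 2 nodes required", "coexpanel_input_error")
  if (target_mean_degree > n - 1) {
    abort(sprintf(
      "target mean degree %g unreachable: maximum achievable with %d nodes is %d",
      target_mean_degree, n, n - 1), "coexpanel_parameter_error")
  }
  dmat <- as.matrix(stats::dist(layout2d))
  lo <- 0
  hi <- max(dmat) * (1 + 1e-9)  # strict '<' still admits the farthest pair
  best <- list(threshold = hi, mean_degree = mean_degree_at(dmat, hi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    md <- mean_degree_at(dmat, mid)
    if (abs(md - target_mean_degree) < abs(best$mean_degree -
                                           target_mean_degree)) {
      best <- list(threshold = mid, mean_degree = md)
    }
    if (abs(md - target_mean_degree) <= tolerance) {
      return(list(threshold = mid, mean_degree = md))
    }
    if (md < target_mean_degree) lo <- mid else hi <- mid
  }
  warning(sprintf(
    "target mean degree %g not attainable within tolerance %g; returning closest achieved %g",
    target_mean_degree, tolerance, best$mean_degree))
  best
}

#' Build the undirected gene graph from a layout
#'
#' Connects node pairs whose Euclidean distance in the 2D layout is strictly
#' smaller than `threshold`. No self-edges; the edge set is symmetric by
#' construction.
#'
#' @param node_ids character vector of gene ids (graph node order).
#' @param X node feature matrix aligned with `node_ids`.
#' @param layout2d N x 2 coordinates aligned with `node_ids`.
#' @param threshold distance cutoff (> 0 for a non-empty graph).
#' @return a `gene_graph`: list with `node_ids`, `X`, `edges` (m x 2 integer
#'   matrix, first column < second), `layout2d`, `threshold`.
#' @export
build_graph <- function(node_ids, X, layout2d, threshold) {
  n <- length(node_ids)
  stopifnot(nrow(X) == n, nrow(layout2d) == n)
  dmat <- as.matrix(stats::dist(layout2d))
  hit <- which(upper.tri(dmat) & dmat < threshold, arr.ind = TRUE)
  edges <- matrix(as.integer(hit), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(node_ids = node_ids, X = X, edges = edges,
                 layout2d = layout2d, threshold = threshold),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  n <- length(x$node_ids)
  cat(sprintf("gene_graph: %d nodes, %d edges (mean degree %.2f), %d features\n",
              n, nrow(x$edges), 2 * nrow(x$edges) / n, ncol(x$X)))
  invisible(x)
}

#' Sparse 0/1 adjacency matrix of a gene graph
#'
#' @param graph a `gene_graph`.
#' @return symmetric sparse `dgCMatrix` with zero diagonal.
#' @export
adjacency_matrix <- function(graph) {
  n <- length(graph$node_ids)
  e <- graph$edges
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n),
                            dimnames = list(graph$node_ids, graph$node_ids))
  A
}

as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = length(graph$node_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$node_ids)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, t(graph$edges))
  }
  g
}

#' Export a gene graph to disk
#'
#' Writes `edges.tsv` (gene_i, gene_j), `layout.tsv` (gene, x, y) and
#' `graph.graphml` (GraphML with node features as attributes) under `dir`.
#'
#' @param graph a `gene_graph`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_graph_files <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- graph$edges
  write_tsv(data.frame(gene_i = graph$node_ids[e[, 1]],
                       gene_j = graph$node_ids[e[, 2]]),
            file.path(dir, "edges.tsv"))
  write_tsv(data.frame(gene = graph$node_ids,
                       x = graph$layout2d[, 1], y = graph$layout2d[, 2]),
            file.path(dir, "layout.tsv"))
  g <- as_igraph(graph)
  for (k in seq_len(ncol(graph$X))) {
    nm <- colnames(graph$X)[k] %||% paste0("f", k)
    g <- igraph::set_vertex_attr(g, nm, value = graph$X[, k])
  }
  igraph::write_graph(g, file.path(dir, "graph.graphml"), format = "graphml")
  invisible(dir)
}
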