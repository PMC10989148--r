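# panels: clustering of embeddings, baselines, silhouette, FAS.

new_panel_assignment <- function(node_ids, labels, n_clusters, method,
                                 provenance = list()) {
  structure(list(node_ids = node_ids,
                 labels = stats::setNames(as.integer(labels), node_ids),
                 n_clusters = as.integer(n_clusters), method = method,
                 provenance = provenance),
            class = "panel_assignment")
}

#' @export
print.panel_assignment <- function(x, ...) {
  cat(sprintf("panel_assignment (%s): %d genes in %d panels\n", x$method,
              length(x$labels), x$n_clusters))
  print(table(panel = x$labels))
  invisible(x)
}

#' Cluster node embeddings into gene panels
#'
#' PCA projection of the embeddings followed by K-means with a fixed seed
#' and 10 restarts.
#'
#' @param embeddings N x d embedding matrix with gene ids as rownames.
#' @param n_clusters number of panels (>= 2, <= N).
#' @param pca_dims PCA dimensionality before K-means (default 16, truncated
#'   to the available dimensions).
#' @param seed RNG seed.
#' @param method_tag provenance tag (default `"dgi"`).
#' @return a `panel_assignment`.
#' @export
cluster_panels <- function(embeddings, n_clusters, pca_dims = 16, seed = 0,
                           method_tag = "dgi") {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n_clusters < 2) abort("n_clusters must be >= 2", "coexpanel_input_error")
  if (n_clusters > n) {
    abort(sprintf("n_clusters (%d) exceeds the number of genes (%d)",
                  n_clusters, n), "coexpanel_input_error")
  }
  pca_dims <- min(pca_dims, ncol(embeddings), n - 1)
  set.seed(seed)
  n_distinct <- nrow(unique(embeddings))
  if (n_distinct < n_clusters) {
    warning(sprintf(
      "only %d distinct embedding rows for %d clusters; degenerate seeded assignment",
      n_distinct, n_clusters))
    labels <- rep(1L, n)
  } else {
    pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(pca_dims), drop = FALSE]
    labels <- stats::kmeans(scores, centers = n_clusters, nstart = 10,
                            iter.max = 100)$cluster
  }
  new_panel_assignment(rownames(embeddings), labels, n_clusters, method_tag,
                       provenance = list(seed = seed, pca_dims = pca_dims))
}

#' Baseline clusterings on raw features
#'
#' The benchmark methods: agglomerative hierarchical clustering (Ward
#' linkage, `ward.D2`, on Euclidean distance) and K-means, each run on the
#' raw (non-embedded) feature matrix, with or without the two binary
#' subcellular columns.
#'
#' @param features numeric feature matrix (genes x features) with gene ids
#'   as rownames, e.g. from [build_node_features()].
#' @param method `"kmeans"` or `"hc"`.
#' @param n_clusters number of panels.
#' @param seed RNG seed (K-means restarts).
#' @param use_subcellular keep the subcellular columns (default `TRUE`)?
#' @param subcellular_cols names of the columns dropped when
#'   `use_subcellular = FALSE`.
#' @return a `panel_assignment` whose method tag is suffixed `_sub` when the
#'   subcellular columns are used.
#' @export
baseline_clusterings <- function(features, method = c("kmeans", "hc"),
                                 n_clusters, seed = 0,
                                 use_subcellular = TRUE,
                                 subcellular_cols = c("signal_peptide",
                                                      "transmembrane")) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (!use_subcellular && !is.null(colnames(features))) {
    keep <- !(colnames(features) %in% subcellular_cols)
    features <- features[, keep, drop = FALSE]
  }
  if (n_clusters < 2 || n_clusters > nrow(features)) {
    abort("n_clusters out of range", "coexpanel_input_error")
  }
  set.seed(seed)
  labels <- switch(method,
    kmeans = stats::kmeans(features, centers = n_clusters, nstart = 10,
                           iter.max = 100)$cluster,
    hc = stats::cutree(stats::hclust(stats::dist(features),
                                     method = "ward.D2"), k = n_clusters))
  tag <- paste0(method, if (use_subcellular) "_sub" else "")
  new_panel_assignment(rownames(features), labels, n_clusters, tag,
                       provenance = list(seed = seed))
}

#' Silhouette coefficient index of a clustering
#'
#' Mean over genes of `(b - a) / max(a, b)` with Euclidean distance, where
#' `a` is the mean distance to the gene's own cluster and `b` the smallest
#' mean distance to another cluster. Evaluated on the expression matrix (the
#' genes' sample profiles), not on embeddings, regardless of how the labels
#' were produced; singleton clusters contribute 0.
#'
#' @param x numeric matrix (genes x samples) of the feature space to score
#'   in, or an [expression_set()].
#' @param labels integer cluster labels, one per row of `x`; at least two
#'   non-empty clusters are required.
#' @return a single numeric value in \[-1, 1\].
#' @export
silhouette_index <- function(x, labels) {
  if (inherits(x, "expr_set")) x <- x$values
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) {
    abort("one label per row required", "coexpanel_input_error")
  }
  sizes <- table(labels)
  if (length(sizes) < 2) {
    abort("silhouette undefined for a single cluster", "coexpanel_input_error")
  }
  D <- as.matrix(stats::dist(x))
  # Per-point sum of distances to each cluster: N x K.
  csum <- t(rowsum(t(D), labels))
  cl_names <- colnames(csum)
  own <- match(as.character(labels), cl_names)
  n_own <- as.numeric(sizes[cl_names])[own]
  a <- csum[cbind(seq_len(nrow(D)), own)] / pmax(n_own - 1, 1)
  mean_other <- sweep(csum, 2, as.numeric(sizes[cl_names]), "/")
  mean_other[cbind(seq_len(nrow(D)), own)] <- Inf
  b <- apply(mean_other, 1, min)
  s <- (b - a) / pmax(a, b)
  s[n_own == 1] <- 0
  mean(s)
}

#' Functional Assignment Score of a pathway under a clustering
#'
#' Quantifies how strongly the genes of pathway `w` concentrate in the
#' top-ranked clusters. Clusters containing pathway genes are sorted by
#' their gene ratio `r_i = m_i / N_w` in descending order (ties broken by
#' cluster id); with `r_w = N_w / M_g` the pathway's share of the dataset,
#' the score is `softplus(sum(r_i) / r_w)` when the pathway spans `n <= k`
#' clusters and `softplus((sum of top-k r_i - sum of the rest) / r_w)`
#' otherwise (natural log, numerically stable softplus).
#'
#' @param assignment a `panel_assignment`.
#' @param pathway_genes character vector of the pathway's gene ids (must be
#'   assigned genes).
#' @param k number of clusters counted as correctly assigned (default 2).
#' @param total_genes dataset gene count `M_g` (default: all assigned genes).
#' @return the FAS value (a single non-negative number).
#' @export
functional_assignment_score <- function(assignment, pathway_genes, k = 2,
                                        total_genes = NULL) {
  M_g <- total_genes %||% length(assignment$labels)
  pathway_genes <- intersect(pathway_genes, names(assignment$labels))
  N_w <- length(pathway_genes)
  if (N_w == 0 || M_g == 0) {
    abort("FAS undefined: empty pathway or empty dataset",
          "coexpanel_domain_error")
  }
  summ <- assignment_summary(assignment, pathway_genes)
  r <- summ$ratio
  r_w <- N_w / M_g
  n <- nrow(summ)
  z <- if (n <= k) sum(r) / r_w
       else (sum(r[seq_len(k)]) - sum(r[-seq_len(k)])) / r_w
  softplus(z)
}

#' Per-cluster membership summary of a pathway
#'
#' @param assignment a `panel_assignment`.
#' @param pathway_genes character vector of gene ids.
#' @return data frame with columns `cluster`, `count` and `ratio`
#'   (`count / N_w`), sorted by descending ratio then ascending cluster id.
#' @export
assignment_summary <- function(assignment, pathway_genes) {
  lab <- assignment$labels[intersect(pathway_genes,
                                     names(assignment$labels))]
  counts <- table(lab)
  df <- data.frame(cluster = as.integer(names(counts)),
                   count = as.integer(counts),
                   ratio = as.integer(counts) / length(lab))
  df <- df[order(-df$ratio, df$cluster), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Choose the cluster number by reference-pathway FAS
#'
#' Scores each candidate clustering by the FAS of a reference pathway and
#' returns the candidate with the highest score (ties broken toward the
#' smallest n).
#'
#' @param assignments named list of `panel_assignment`s, one per candidate
#'   cluster number (names or `n_clusters` fields supply the candidates,
#'   conventionally 24, 10 and 7).
#' @param pathway_genes gene ids of the reference pathway (e.g.
#'   phototransduction).
#' @param k FAS top-cluster count (default 2).
#' @param total_genes dataset gene count `M_g` passed to the FAS.
#' @return list with `n` (chosen cluster number) and `report` (data frame of
#'   n and FAS).
#' @export
select_cluster_number <- function(assignments, pathway_genes, k = 2,
                                  total_genes = NULL) {
  ns <- vapply(assignments, function(a) a$n_clusters, integer(1))
  fas <- vapply(assignments, function(a)
    functional_assignment_score(a, pathway_genes, k = k,
                                total_genes = total_genes), numeric(1))
  report <- data.frame(n = unname(ns), fas = unname(fas))
  report <- report[order(report$n), , drop = FALSE]
  rownames(report) <- NULL
  best <- report$n[report$fas >= max(report$fas) - 1e-12]
  list(n = min(best), report = report)
}
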