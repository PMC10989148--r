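# panel_analytics: keyword gene extraction, enrichment, HGP/SGP designation,
# correlation topology networks with landmark genes, ROS kinetics helper.

#' Extract functional genes by description keywords
#'
#' Case-insensitive substring match of any keyword against the Swiss-Prot
#' style description, followed by a low-expression filter; when several
#' per-condition datasets are supplied, the eligible gene sets are merged.
#' The default keywords target nitrate-/nitrite-related (partial
#' denitrification, PD) genes.
#'
#' @param annot a `gene_annotation` data frame.
#' @param keywords non-empty character vector of keywords.
#' @param expr an [expression_set()], a plain FPKM matrix, or a list of
#'   either (one per condition dataset).
#' @param min_mean_expression FPKM cutoff on the per-dataset mean
#'   (default 1); a gene qualifies if it passes in at least one dataset.
#' @return sorted character vector of matching gene ids.
#' @export
extract_function_genes <- function(annot, keywords = c("nitrate", "nitrite"),
                                   expr = NULL, min_mean_expression = 1) {
  if (length(keywords) == 0) {
    abort("keyword list must be non-empty", "coexpanel_input_error")
  }
  pat <- paste(vapply(keywords,
                      function(k) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", k),
                      character(1)), collapse = "|")
  hit <- grepl(pat, annot$description, ignore.case = TRUE)
  genes <- annot$gene_id[hit]
  if (is.null(expr)) return(sort(genes))
  if (!is.list(expr) || inherits(expr, "expr_set")) expr <- list(expr)
  eligible <- character(0)
  for (e in expr) {
    v <- if (inherits(e, "expr_set")) e$values else as.matrix(e)
    common <- intersect(genes, rownames(v))
    keep <- common[rowMeans(v[common, , drop = FALSE]) >=
                     min_mean_expression]
    eligible <- union(eligible, keep)
  }
  sort(eligible)
}

#' Pathway enrichment within a gene panel
#'
#' Summarizes, per KEGG level-3 style pathway represented in the panel, the
#' member count, the mean FPKM under the light condition, the fold change of
#' light vs dark member-gene means (dark as control) and a p-value from a
#' two-sided paired-by-gene Wilcoxon signed-rank test of member-gene light
#' means against dark means (`test = "ttest"` switches to a paired t-test).
#' A pathway passes the filter when `p < p_max`, the fold change is outside
#' `fc_bounds`, and the mean expression is at least `min_mean_expression`
#' (low-expression pathways are removed). Pathways with fewer than 3 member
#' genes get no p-value and never pass.
#'
#' @param panel_genes gene ids of the panel.
#' @param annot a `gene_annotation` data frame.
#' @param expr an [expression_set()] containing light and dark samples.
#' @param light_condition,dark_condition condition labels.
#' @param p_max p-value threshold (default 0.01).
#' @param fc_bounds fold-change window outside which a pathway is considered
#'   responsive (default `c(0.5, 2)`).
#' @param min_mean_expression FPKM floor (default 10).
#' @param test `"wilcoxon"` (default) or `"ttest"`.
#' @return data frame with one row per pathway: `pathway`, `brite` (if
#'   annotated), `n_genes`, `mean_expression`, `fold_change`, `p_value`,
#'   `passes_filter`, sorted by descending mean expression.
#' @export
enrich_pathways <- function(panel_genes, annot, expr, light_condition,
                            dark_condition = "dark", p_max = 0.01,
                            fc_bounds = c(0.5, 2), min_mean_expression = 10,
                            test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  al <- align_annotations(panel_genes, annot)
  pairs <- pathway_pairs(al)
  if (nrow(pairs) == 0) {
    abort("no pathway annotations among the panel genes",
          "coexpanel_input_error")
  }
  light_s <- samples_of(expr, light_condition)
  dark_s <- samples_of(expr, dark_condition)
  light_mean <- rowMeans(expr$values[, light_s, drop = FALSE])
  dark_mean <- rowMeans(expr$values[, dark_s, drop = FALSE])
  has_brite <- !is.null(al$brite)
  rows <- lapply(split(pairs$gene_id, pairs$pathway), function(members) {
    lm <- light_mean[members]
    dm <- dark_mean[members]
    p <- NA_real_
    if (length(members) >= 3) {
      p <- tryCatch(
        if (test == "wilcoxon") {
          suppressWarnings(stats::wilcox.test(lm, dm, paired = TRUE))$p.value
        } else {
          stats::t.test(lm, dm, paired = TRUE)$p.value
        },
        error = function(e) 1)
      if (is.na(p)) p <- 1
    }
    fc <- mean(lm) / mean(dm)
    data.frame(n_genes = length(members), mean_expression = mean(lm),
               fold_change = fc, p_value = p,
               passes_filter = !is.na(p) & p < p_max &
                 (fc < fc_bounds[1] | fc > fc_bounds[2]) &
                 mean(lm) >= min_mean_expression)
  })
  out <- do.call(rbind, rows)
  out <- cbind(pathway = names(rows), out)
  if (has_brite) {
    brite_of <- function(pw) {
      g <- pairs$gene_id[pairs$pathway == pw]
      b <- al$brite[match(g, al$gene_id)]
      b <- b[b != ""]
      if (length(b) == 0) "" else names(sort(table(b), decreasing = TRUE))[1]
    }
    out$brite <- vapply(out$pathway, brite_of, character(1))
  }
  out <- out[order(-out$mean_expression), , drop = FALSE]
  rownames(out) <- NULL
  out
}

plurality_cluster <- function(assignment, genes, expr = NULL, role = "panel") {
  lab <- assignment$labels[intersect(genes, names(assignment$labels))]
  if (length(lab) == 0) return(NA_integer_)
  counts <- table(lab)
  top <- as.integer(names(counts)[counts == max(counts)])
  if (length(top) > 1) {
    if (!is.null(expr)) {
      sums <- vapply(top, function(cl) {
        g <- names(assignment$labels)[assignment$labels == cl]
        sum(expr$values[intersect(g, rownames(expr$values)), , drop = FALSE])
      }, numeric(1))
      warning(sprintf(
        "%s designation tie between clusters %s; broken by higher summed expression",
        role, paste(top, collapse = ", ")))
      top <- top[order(-sums, top)]
    } else {
      warning(sprintf(
        "%s designation tie between clusters %s; no expression supplied, smallest id chosen",
        role, paste(top, collapse = ", ")))
      top <- sort(top)
    }
  }
  top[1]
}

#' Designate hub and signaling gene panels
#'
#' The hub gene panel (HGP) is the cluster holding the plurality of the
#' partial-denitrification (nitrate/nitrite) genes; the signaling gene panel
#' (SGP) is the cluster holding the plurality of the phototransduction
#' genes. Ties are broken toward the cluster with higher summed expression
#' (with a warning). Per designated panel the mean FPKM and, when a DEG
#' table is supplied, the mean |log2 fold change| are reported; hub panels
#' are expected to pair high expression with low fold change and signaling
#' panels the reverse.
#'
#' @param assignment a `panel_assignment`.
#' @param pd_genes partial-denitrification gene ids (from
#'   [extract_function_genes()]).
#' @param photo_genes phototransduction gene ids.
#' @param expr optional [expression_set()] for tie-breaking and panel means.
#' @param degs optional `deg_table` for mean |log2FC| per panel.
#' @return list with `hgp`, `sgp` (cluster ids, `NA` when the gene set is
#'   empty) and `report` (one row per designated role).
#' @export
designate_panels <- function(assignment, pd_genes, photo_genes, expr = NULL,
                             degs = NULL) {
  if (length(pd_genes) == 0) warning("empty PD gene set; HGP not designated")
  if (length(photo_genes) == 0) {
    warning("empty phototransduction gene set; SGP not designated")
  }
  hgp <- if (length(pd_genes)) {
    plurality_cluster(assignment, pd_genes, expr, "HGP")
  } else NA_integer_
  sgp <- if (length(photo_genes)) {
    plurality_cluster(assignment, photo_genes, expr, "SGP")
  } else NA_integer_
  if (!is.na(hgp) && !is.na(sgp) && hgp == sgp) {
    warning(sprintf("HGP and SGP designate the same cluster (%d)", hgp))
  }
  panel_stats <- function(cl) {
    if (is.na(cl)) {
      return(data.frame(cluster = NA_integer_, n_genes = NA_integer_,
                        mean_expression = NA_real_, mean_abs_log2fc = NA_real_))
    }
    g <- names(assignment$labels)[assignment$labels == cl]
    me <- if (!is.null(expr)) {
      mean(expr$values[intersect(g, rownames(expr$values)), , drop = FALSE])
    } else NA_real_
    ml <- if (!is.null(degs)) {
      mean(abs(degs$log2_fold_change[degs$gene_id %in% g]))
    } else NA_real_
    data.frame(cluster = cl, n_genes = length(g), mean_expression = me,
               mean_abs_log2fc = ml)
  }
  report <- rbind(cbind(role = "HGP", panel_stats(hgp)),
                  cbind(role = "SGP", panel_stats(sgp)))
  list(hgp = hgp, sgp = sgp, report = report)
}

#' Build a correlation topology network for a panel
#'
#' All-pairs Pearson correlation of gene expression profiles across samples;
#' p-values from the t transform `t = r sqrt((m - 2) / (1 - r^2))` with `m`
#' samples. Edges with `r >= r_min` and `p <= p_max` are retained (the
#' signed rule: strong anti-correlations are excluded unless
#' `absolute = TRUE`). Zero-variance genes cannot be correlated and are kept
#' as isolated nodes, with a log message.
#'
#' @param expr_sub FPKM matrix (panel genes x >= 3 samples) or an
#'   [expression_set()] restricted to the panel.
#' @param r_min correlation threshold (default 0.9).
#' @param p_max p-value threshold (default 0.05).
#' @param absolute apply the threshold to |r| instead of signed r.
#' @return a `topology_network`: list with `nodes`, `edges` (data frame
#'   `from`, `to`, `r`, `p`), and the filter parameters.
#' @export
build_topology_network <- function(expr_sub, r_min = 0.9, p_max = 0.05,
                                   absolute = FALSE) {
  v <- if (inherits(expr_sub, "expr_set")) expr_sub$values else
    as.matrix(expr_sub)
  if (nrow(v) < 2) abort("panel must have >= 2 genes", "coexpanel_input_error")
  m <- ncol(v)
  if (m < 3) abort(">= 3 samples required for correlation p-values",
                   "coexpanel_input_error")
  sds <- apply(v, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    message(sprintf("excluding %d zero-variance gene(s) from correlation: %s",
                    sum(flat), paste(rownames(v)[flat], collapse = ", ")))
  }
  ok <- rownames(v)[!flat]
  edges <- data.frame(from = character(0), to = character(0), r = numeric(0),
                      p = numeric(0))
  if (length(ok) >= 2) {
    C <- stats::cor(t(v[ok, , drop = FALSE]))
    r <- C[upper.tri(C)]
    idx <- which(upper.tri(C), arr.ind = TRUE)
    r_c <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tstat <- r_c * sqrt((m - 2) / (1 - r_c^2))
    p <- 2 * stats::pt(-abs(tstat), df = m - 2)
    crit <- if (absolute) abs(r) else r
    keep <- crit >= r_min & p <= p_max
    edges <- data.frame(from = ok[idx[keep, 1]], to = ok[idx[keep, 2]],
                        r = r[keep], p = p[keep], stringsAsFactors = FALSE)
  }
  structure(list(nodes = rownames(v), edges = edges, r_min = r_min,
                 p_max = p_max, absolute = absolute),
            class = "topology_network")
}

#' @export
print.topology_network <- function(x, ...) {
  cat(sprintf("topology_network: %d nodes, %d edges (r >= %g, p <= %g%s)\n",
              length(x$nodes), nrow(x$edges), x$r_min, x$p_max,
              if (x$absolute) ", absolute" else ""))
  invisible(x)
}

topology_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = length(network$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = network$nodes)
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(network$edges$from, network$nodes),
                                    match(network$edges$to, network$nodes)))
    g <- igraph::set_edge_attr(g, "weight", value = network$edges$r)
  }
  g
}

#' Node metrics and modularity classes of a topology network
#'
#' Modularity classes come from Louvain modularity maximization on the edge
#' weights (seeded, resolution 1 by default). Degree and clustering
#' coefficient are unweighted; weighted degree sums edge correlations.
#' Path-based metrics (eccentricity, closeness, harmonic closeness,
#' betweenness) use unweighted shortest paths; for disconnected graphs,
#' eccentricity and closeness are computed within connected components,
#' harmonic closeness counts unreachable nodes as zero contribution, and
#' isolated nodes get 0 for all path metrics.
#'
#' @param network a `topology_network`.
#' @param seed RNG seed for Louvain.
#' @param resolution Louvain resolution (default 1).
#' @return the network with a `metrics` data frame attached (one row per
#'   node: degree, weighted_degree, modularity_class, eccentricity,
#'   closeness, harmonic_closeness, betweenness, clustering_coefficient).
#' @export
compute_topology_metrics <- function(network, seed = 0, resolution = 1) {
  g <- topology_igraph(network)
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) {
    warning("empty edge set: all topology metrics degenerate to 0")
    metrics <- data.frame(gene = network$nodes, degree = 0,
                          weighted_degree = 0,
                          modularity_class = seq_len(n), eccentricity = 0,
                          closeness = 0, harmonic_closeness = 0,
                          betweenness = 0, clustering_coefficient = 0)
    network$metrics <- metrics
    return(network)
  }
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                  resolution = resolution)
  deg <- igraph::degree(g)
  wdeg <- igraph::strength(g, weights = igraph::E(g)$weight)
  ecc <- igraph::eccentricity(g)  # within reachable set, i.e. per component
  clo <- suppressWarnings(igraph::closeness(g, weights = NA))
  clo[!is.finite(clo)] <- 0  # isolated nodes
  harm <- igraph::harmonic_centrality(g, weights = NA, normalized = TRUE)
  btw <- igraph::betweenness(g, weights = NA)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  network$metrics <- data.frame(
    gene = network$nodes, degree = as.numeric(deg),
    weighted_degree = as.numeric(wdeg),
    modularity_class = as.integer(igraph::membership(comm)),
    eccentricity = as.numeric(ecc), closeness = as.numeric(clo),
    harmonic_closeness = as.numeric(harm), betweenness = as.numeric(btw),
    clustering_coefficient = as.numeric(cc))
  network
}

#' Landmark genes per modularity class
#'
#' Within each modularity class, genes are ranked by their mean FPKM over
#' the light-exposed samples and the top `n_top` (default 3, or the whole
#' class if smaller) are the class's landmark genes. Ties are broken by gene
#' id ascending, with a log message.
#'
#' @param network a `topology_network` with metrics attached
#'   ([compute_topology_metrics()]).
#' @param expr an [expression_set()] or FPKM matrix covering the panel
#'   genes.
#' @param light_samples sample ids of the light-exposed samples (or a
#'   condition label when `expr` is an `expr_set`).
#' @param n_top landmarks per class (default 3).
#' @return data frame with `modularity_class`, `gene`, `mean_expression`,
#'   `rank`.
#' @export
landmark_genes <- function(network, expr, light_samples, n_top = 3) {
  if (is.null(network$metrics)) {
    abort("run compute_topology_metrics() first", "coexpanel_input_error")
  }
  v <- if (inherits(expr, "expr_set")) {
    smp <- if (all(light_samples %in% expr$condition)) {
      samples_of(expr, light_samples)
    } else light_samples
    expr$values[, smp, drop = FALSE]
  } else {
    as.matrix(expr)[, light_samples, drop = FALSE]
  }
  means <- rowMeans(v)
  met <- network$metrics
  out <- lapply(split(met$gene, met$modularity_class), function(genes) {
    mu <- means[genes]
    ord <- order(-mu, genes)
    top <- utils::head(ord, n_top)
    if (length(ord) > n_top &&
        mu[ord[n_top]] == mu[ord[n_top + 1]]) {
      message(sprintf(
        "landmark tie at rank %d (%s vs %s): lexicographically smaller id kept",
        n_top, genes[ord[n_top]], genes[ord[n_top + 1]]))
    }
    data.frame(gene = genes[top], mean_expression = unname(mu[top]),
               rank = seq_along(top), stringsAsFactors = FALSE)
  })
  classes <- rep(as.integer(names(out)), vapply(out, nrow, integer(1)))
  out <- do.call(rbind, out)
  out <- cbind(modularity_class = classes, out)
  rownames(out) <- NULL
  out
}

#' ROS production rate from DPBF absorbance decay
#'
#' Total reactive-oxygen-species production rate
#' `k = (1 - A_t / A_0) / OD600 * 1000`, where `A_t` and `A_0` are the
#' 410 nm absorbances at time t and time zero and OD600 normalizes for cell
#' density. Only timepoints with sufficient remaining substrate
#' (absorbance > 0.85) give reliable rates; lower values trigger a warning.
#'
#' @param A_t absorbance at time t (vectorized).
#' @param A_0 initial absorbance (> 0).
#' @param od600 optical density at 600 nm (> 0).
#' @return numeric vector of rates.
#' @export
ros_production_rate <- function(A_t, A_0, od600) {
  if (any(od600 <= 0)) abort("od600 must be > 0", "coexpanel_domain_error")
  if (any(A_0 <= 0)) abort("A_0 must be > 0", "coexpanel_domain_error")
  if (any(A_t <= 0.85)) {
    warning("absorbance <= 0.85: substrate depleted, rate unreliable")
  }
  (1 - A_t / A_0) / od600 * 1e3
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export a topology network to GEXF
#'
#' Writes a GEXF 1.3 file with all node metrics as attributes and edge
#' weights set to the correlation coefficients, round-trippable into
#' network GUIs.
#'
#' @param network a `topology_network` with metrics attached.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_gexf <- function(network, path) {
  if (is.null(network$metrics)) {
    abort("run compute_topology_metrics() first", "coexpanel_input_error")
  }
  met <- network$metrics
  attr_cols <- setdiff(names(met), "gene")
  header <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://gexf.net/1.3" version="1.3">',
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="node">',
    sprintf('      <attribute id="%d" title="%s" type="double"/>',
            seq_along(attr_cols) - 1L, attr_cols),
    '    </attributes>',
    '    <nodes>')
  nodes <- vapply(seq_len(nrow(met)), function(i) {
    vals <- sprintf('          <attvalue for="%d" value="%g"/>',
                    seq_along(attr_cols) - 1L,
                    as.numeric(met[i, attr_cols]))
    paste(c(sprintf('      <node id="%s" label="%s">',
                    xml_escape(met$gene[i]), xml_escape(met$gene[i])),
            "        <attvalues>", vals, "        </attvalues>",
            "      </node>"), collapse = "\n")
  }, character(1))
  e <- network$edges
  edges <- if (nrow(e) > 0) {
    sprintf('      <edge id="%d" source="%s" target="%s" weight="%g"/>',
            seq_len(nrow(e)) - 1L, xml_escape(e$from), xml_escape(e$to), e$r)
  } else character(0)
  footer <- c("    </nodes>", "    <edges>", edges, "    </edges>",
              "  </graph>", "</gexf>")
  writeLines(c(header, nodes, footer), path)
  invisible(path)
}

#' Export a topology network to GraphML
#'
#' @param network a `topology_network` (metrics attached if available).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  g <- topology_igraph(network)
  if (!is.null(network$metrics)) {
    met <- network$metrics
    for (col in setdiff(names(met), "gene")) {
      g <- igraph::set_vertex_attr(g, col,
                                   value = met[[col]][match(
                                     igraph::V(g)$name, met$gene)])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
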