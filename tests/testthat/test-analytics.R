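# panel_analytics: keyword genes, enrichment, designation, topology,
# landmarks, ROS.

test_that("keyword extraction matches descriptions and applies the expression filter", {
  annot <- make_annot(sprintf("g%02d", 1:15))
  annot$description[1:7] <- "Nitrate reductase alpha subunit"
  annot$description[8:11] <- "nitrite transporter"
  annot$description[12:15] <- "ATP synthase"
  expect_setequal(extract_function_genes(annot, c("nitrate", "nitrite")),
                  sprintf("g%02d", 1:11))

  # expression cutoff: 2 of the 11 matched genes below mean FPKM 1
  vals <- matrix(50, 15, 6, dimnames = list(annot$gene_id, NULL))
  vals[c(3, 9), ] <- 0.4
  expr <- make_expr(vals, rep(c("blue", "dark"), each = 3))
  got <- extract_function_genes(annot, c("nitrate", "nitrite"), expr)
  expect_length(got, 9)
  expect_false(any(c("g03", "g09") %in% got))

  # merged over datasets: eligible in either dataset qualifies
  vals2 <- vals; vals2[3, ] <- 80
  expr2 <- make_expr(vals2, rep(c("yellow", "dark"), each = 3))
  got2 <- extract_function_genes(annot, c("nitrate", "nitrite"),
                                 list(expr, expr2))
  expect_true("g03" %in% got2)
  expect_length(got2, 10)

  expect_error(extract_function_genes(annot, character(0)), "non-empty")
})

enrichment_fixture <- function() {
  ids <- sprintf("g%02d", 1:25)
  annot <- make_annot(ids)
  annot$pathway[1:10] <- "Nitrogen metabolism"
  annot$pathway[11:20] <- "Ribosome"
  annot$pathway[21:22] <- "Rare pathway"
  set.seed(31)
  dark <- matrix(10 * 10^rnorm(25 * 3, 0, 0.02), 25)
  light <- dark[, 1:3]
  light[1:10, ] <- light[1:10, ] * 4   # 4x up, mean ~40 FPKM
  vals <- cbind(light, dark)
  rownames(vals) <- ids
  expr <- make_expr(vals, rep(c("blue", "dark"), each = 3))
  list(ids = ids, annot = annot, expr = expr)
}

test_that("pathway enrichment applies the three filter clauses", {
  fx <- enrichment_fixture()
  enr <- suppress_all(enrich_pathways(fx$ids, fx$annot, fx$expr, "blue"))
  nit <- enr[enr$pathway == "Nitrogen metabolism", ]
  rib <- enr[enr$pathway == "Ribosome", ]
  rare <- enr[enr$pathway == "Rare pathway", ]

  # 4x-up pathway with ~40 FPKM means passes every clause
  expect_true(nit$passes_filter)
  expect_gt(nit$fold_change, 2)
  expect_gte(nit$mean_expression, 10)
  expect_lt(nit$p_value, 0.01)

  # unchanged pathway: fold change ~1 fails the FC clause
  expect_false(rib$passes_filter)
  expect_lt(abs(rib$fold_change - 1), 0.2)

  # < 3 genes: no p-value, never passes
  expect_true(is.na(rare$p_value))
  expect_false(rare$passes_filter)

  # member counts and means match a brute-force tally
  expect_equal(nit$n_genes, 10)
  light_s <- names(fx$expr$condition)[fx$expr$condition == "blue"]
  expect_equal(nit$mean_expression,
               mean(rowMeans(fx$expr$values[1:10, light_s])))
  # multi-pathway genes are counted once per pathway
  annot2 <- fx$annot
  annot2$pathway[1:10] <- "Nitrogen metabolism;Ribosome"
  enr2 <- suppress_all(enrich_pathways(fx$ids, annot2, fx$expr, "blue"))
  expect_equal(enr2$n_genes[enr2$pathway == "Ribosome"], 20)
  expect_equal(sum(enr2$n_genes),
               nrow(coexpanel:::pathway_pairs(
                 coexpanel:::align_annotations(fx$ids, annot2))))
})

test_that("HGP/SGP designation follows plurality with expression tie-breaks", {
  ids <- sprintf("g%02d", 1:20)
  labels <- rep(1:4, each = 5)
  a <- coexpanel:::new_panel_assignment(ids, labels, 4, "t")
  pd <- ids[16:20]          # 100% in cluster 4
  photo <- ids[1:4]         # cluster 1
  des <- suppress_all(designate_panels(a, pd, photo))
  expect_equal(des$hgp, 4)
  expect_equal(des$sgp, 1)

  # 5/5 tie across clusters 1 and 2, broken by higher summed expression
  photo_tie <- ids[c(1:5, 6:10)]
  vals <- matrix(1, 20, 3, dimnames = list(ids, NULL))
  vals[6:10, ] <- 100
  expr <- make_expr(vals, rep("blue", 3))
  expect_warning(
    des2 <- designate_panels(a, pd, photo_tie, expr = expr),
    "tie")
  expect_equal(des2$sgp, 2)

  # plurality matches a brute-force count on a random assignment
  set.seed(41)
  labels3 <- sample(1:5, 60, replace = TRUE)
  ids3 <- sprintf("h%02d", 1:60)
  a3 <- coexpanel:::new_panel_assignment(ids3, labels3, 5, "t")
  pdg <- ids3[sample(60, 21)]
  tab <- table(labels3[match(pdg, ids3)])
  if (sum(tab == max(tab)) == 1) {
    des3 <- suppress_all(designate_panels(a3, pdg, ids3[1:3]))
    expect_equal(des3$hgp, as.integer(names(which.max(tab))))
  }

  expect_warning(des4 <- designate_panels(a, character(0), photo),
                 "HGP not designated")
  expect_true(is.na(des4$hgp))
  expect_equal(des4$sgp, 1)
})

test_that("topology edges follow the signed correlation rule and the oracle", {
  set.seed(51)
  base <- 10^rnorm(6, 1, 0.3)
  vals <- rbind(base, base * 2,            # perfectly correlated pair
                rev(base) * 1.5)           # unrelated-ish
  vals <- rbind(vals, max(base) * 1.2 - base)  # anti-correlated with row 1
  rownames(vals) <- c("g1", "g2", "g3", "g4")
  net <- build_topology_network(vals, r_min = 0.9, p_max = 0.05)
  key <- paste(net$edges$from, net$edges$to)
  expect_true("g1 g2" %in% key)            # duplicated profile: r = 1
  expect_false(any(grepl("g4", key) & grepl("g1", key)))  # r = -1 excluded

  net_abs <- build_topology_network(vals, r_min = 0.9, p_max = 0.05,
                                    absolute = TRUE)
  key_abs <- paste(net_abs$edges$from, net_abs$edges$to)
  expect_true("g1 g4" %in% key_abs)        # signed rule lifted

  # 10-gene fixture: retained edges equal a cor.test loop oracle
  set.seed(52)
  m <- matrix(10^rnorm(80, 1, 0.5), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  m[2, ] <- m[1, ] * 3 + rnorm(8, 0, 0.1)
  m[4, ] <- m[3, ] * 0.5 + rnorm(8, 0, 0.1)
  net10 <- build_topology_network(m, r_min = 0.9, p_max = 0.05)
  expected <- character(0)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      ct <- cor.test(m[i, ], m[j, ])
      if (ct$estimate >= 0.9 && ct$p.value <= 0.05) {
        expected <- c(expected, paste(rownames(m)[i], rownames(m)[j]))
      }
    }
  }
  expect_setequal(paste(net10$edges$from, net10$edges$to), expected)

  # zero-variance genes are excluded from correlation but kept as nodes
  m2 <- m; m2[5, ] <- 7
  expect_message(net_zv <- build_topology_network(m2), "zero-variance")
  expect_false(any(grepl("g05", paste(net_zv$edges$from,
                                      net_zv$edges$to))))
  expect_true("g05" %in% net_zv$nodes)

  expect_error(build_topology_network(m[, 1:2]), ">= 3 samples")
  expect_error(build_topology_network(m[1, , drop = FALSE]), ">= 2 genes")
})

ring_network <- function(n) {
  # correlation network stub built directly from an edge list
  edges <- data.frame(from = sprintf("v%d", 1:n),
                      to = sprintf("v%d", c(2:n, 1)),
                      r = 1, p = 0)
  structure(list(nodes = sprintf("v%d", 1:n), edges = edges, r_min = 0.9,
                 p_max = 0.05, absolute = FALSE),
            class = "topology_network")
}

test_that("topology metrics match hand computations on canonical graphs", {
  sq <- compute_topology_metrics(ring_network(4))
  expect_equal(sq$metrics$degree, rep(2, 4))
  expect_equal(sq$metrics$clustering_coefficient, rep(0, 4))
  expect_equal(sq$metrics$eccentricity, rep(2, 4))

  tri <- compute_topology_metrics(ring_network(3))
  expect_equal(tri$metrics$clustering_coefficient, rep(1, 3))
  expect_equal(tri$metrics$betweenness, rep(0, 3))

  # two 5-cliques joined by a bridge: 2 modularity classes, bridge endpoints
  # carry the maximal betweenness
  nodes <- sprintf("v%02d", 1:10)
  pairs <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)), c(5, 6))
  edges <- data.frame(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
                      r = 1, p = 0)
  net <- structure(list(nodes = nodes, edges = edges, r_min = 0.9,
                        p_max = 0.05, absolute = FALSE),
                   class = "topology_network")
  met <- compute_topology_metrics(net, seed = 1)$metrics
  expect_equal(length(unique(met$modularity_class)), 2)
  expect_equal(met$modularity_class[1:5], rep(met$modularity_class[1], 5))
  bridge <- met$gene[order(-met$betweenness)][1:2]
  expect_setequal(bridge, c("v05", "v06"))
})

test_that("topology metrics agree with independent BFS/counting oracles", {
  for (s in 1:20) {
    n <- 15
    A <- random_adjacency(n, 0.25, seed = 60 + s)
    idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
    nodes <- sprintf("v%02d", 1:n)
    net <- structure(list(
      nodes = nodes,
      edges = data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                         r = 1, p = 0),
      r_min = 0.9, p_max = 0.05, absolute = FALSE),
      class = "topology_network")
    met <- compute_topology_metrics(net, seed = s)$metrics
    expect_equal(met$degree, unname(oracle_degree(A)))
    expect_equal(met$clustering_coefficient, oracle_clustering(A),
                 tolerance = 1e-12)
    expect_equal(met$betweenness, oracle_betweenness(A),
                 tolerance = 1e-9)
    expect_equal(met$eccentricity, oracle_eccentricity(A))
  }
})

test_that("landmark genes are the top-3 by light-condition mean, ties lexicographic", {
  nodes <- sprintf("v%02d", 1:7)
  net <- structure(list(
    nodes = nodes,
    edges = data.frame(from = nodes[c(1, 2, 3, 4, 5, 6)],
                       to = nodes[c(2, 3, 4, 5, 1, 7)], r = 1, p = 0),
    r_min = 0.9, p_max = 0.05, absolute = FALSE),
    class = "topology_network")
  net <- compute_topology_metrics(net, seed = 2)
  classes <- split(net$metrics$gene, net$metrics$modularity_class)

  vals <- matrix(rep(c(70, 10, 50, 30, 60, 20, 40), 6), 7,
                 dimnames = list(nodes, NULL))
  expr <- make_expr(vals, rep(c("blue", "dark"), each = 3))
  lmk <- landmark_genes(net, expr, "blue")
  for (cl in names(classes)) {
    members <- classes[[cl]]
    expected <- members[order(-vals[members, 1], members)]
    got <- lmk$gene[lmk$modularity_class == as.integer(cl)]
    expect_equal(got, head(expected, 3))     # brute-force sort, <= 3 kept
    expect_lte(length(got), 3)
  }

  # class of 2 genes returns both; row order of the table is irrelevant
  shuffled <- expr
  ord <- sample(7)
  shuffled$values <- shuffled$values[ord, ]
  lmk2 <- landmark_genes(net, shuffled, "blue")
  expect_equal(lmk2, lmk)

  # tie at rank 3 resolved toward the smaller gene id, with a log entry
  vals3 <- vals
  vals3[, ] <- rep(c(9, 9, 9, 9, 1, 1, 1), 6)
  expr3 <- make_expr(vals3, rep(c("blue", "dark"), each = 3))
  big_class <- names(classes)[lengths(classes) >= 4][1]
  if (!is.na(big_class)) {
    expect_message(landmark_genes(net, expr3, "blue"), "tie")
  }
})

test_that("ROS production rate follows the kinetic formula", {
  expect_equal(suppressWarnings(ros_production_rate(1, 1, 0.5)), 0)
  expect_equal(suppressWarnings(ros_production_rate(0.5, 1, 0.5)), 1000)
  expect_error(ros_production_rate(0.9, 1, 0), "od600")
  expect_warning(ros_production_rate(0.5, 1, 0.5), "0.85")

  # vectorized over a time series equals the scalar loop
  A_t <- seq(1.2, 0.9, length.out = 7)
  got <- ros_production_rate(A_t, 1.25, 0.4)
  expect_equal(got, sapply(A_t, ros_production_rate, A_0 = 1.25,
                           od600 = 0.4))
})

test_that("GEXF and GraphML exports carry nodes, edges and metrics", {
  skip_if_not_installed("xml2")
  net <- compute_topology_metrics(ring_network(5))
  path <- tempfile(fileext = ".gexf")
  export_gexf(net, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  expect_length(xml2::xml_find_all(doc, "//g:node", ns), 5)
  expect_length(xml2::xml_find_all(doc, "//g:edge", ns), 5)
  expect_gt(length(xml2::xml_find_all(doc, "//g:attvalue", ns)), 0)

  gml <- tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 5)
})
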