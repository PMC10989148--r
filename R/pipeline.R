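# pipeline_cli: end-to-end orchestration with a single seeded configuration.

#' Pipeline configuration
#'
#' Aggregates every stage's inputs and tunables with the pipeline defaults:
#' target mean degree 5, t-SNE perplexity 20 with 1000 iterations, self-loop
#' strength 0.8, candidate cluster numbers 24/10/7 with 7 as the working
#' default, FAS k = 2, enrichment thresholds p < 0.01 / fold change outside
#' 0.5-2 / >= 10 FPKM, and network thresholds r >= 0.9 / p <= 0.05. All
#' randomness flows from the single `seed`, expanded deterministically per
#' stage and condition.
#'
#' @param expression path to the expression TSV/CSV or an
#'   [expression_set()].
#' @param design path to the design TSV or a named sample -> condition
#'   vector (ignored when `expression` is already an `expr_set`).
#' @param annotations path to the annotation TSV or a `gene_annotation`.
#' @param out_dir output directory for run artifacts.
#' @param deg_tables optional named list (by test condition) of precomputed
#'   DEG tables or their paths, bypassing the built-in DE test.
#' @param test_conditions,control_condition condition labels.
#' @param target_mean_degree,perplexity,tsne_max_iter,theta graph stage
#'   parameters.
#' @param gcn a [gcn_config()].
#' @param n_candidates candidate cluster numbers.
#' @param default_n cluster number used for designation/analytics when the
#'   FAS-based selection is not overriding it (default 7).
#' @param select_n_by_fas if `TRUE` (default) the analytics stage uses the
#'   FAS-selected n, otherwise `default_n`.
#' @param pca_dims PCA dimensionality before K-means.
#' @param reference_pathway pathway whose FAS drives cluster-number choice.
#' @param fas_k FAS top-cluster count.
#' @param pd_keywords keywords for PD gene extraction.
#' @param min_mean_expression valid-DEG / keyword-gene FPKM floor.
#' @param enrichment list of `p_max`, `fc_bounds`, `min_mean_expression`.
#' @param network list of `r_min`, `p_max`, `absolute`.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression, design = NULL, annotations,
                            out_dir = tempfile("coexpanel_run_"),
                            deg_tables = NULL,
                            test_conditions = c("blue", "yellow"),
                            control_condition = "dark",
                            target_mean_degree = 5, perplexity = 20,
                            tsne_max_iter = 1000, theta = 0.4,
                            gcn = gcn_config(),
                            n_candidates = c(24, 10, 7), default_n = 7,
                            select_n_by_fas = TRUE, pca_dims = 16,
                            reference_pathway = "Phototransduction",
                            fas_k = 2,
                            pd_keywords = c("nitrate", "nitrite"),
                            min_mean_expression = 1,
                            enrichment = list(p_max = 0.01,
                                              fc_bounds = c(0.5, 2),
                                              min_mean_expression = 10),
                            network = list(r_min = 0.9, p_max = 0.05,
                                           absolute = FALSE),
                            seed = 0) {
  stopifnot(target_mean_degree > 0, perplexity > 0,
            all(n_candidates >= 2), enrichment$p_max > 0,
            network$r_min > 0, network$p_max > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, stage_idx, cond_idx = 0) {
  # Deterministic per-stage expansion, kept well below 2^31.
  (seed * 1000L + cond_idx * 100L + stage_idx) %% 2147483647L
}

run_stage <- function(manifest, name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full coexpression-panel pipeline
#'
#' For every test condition: differential expression against the control,
#' valid-DEG filtering, dataset split, node features, t-SNE layout,
#' degree-calibrated graph, DGI training, clustering at every candidate n,
#' silhouette + FAS evaluation, cluster-number selection, HGP/SGP
#' designation, pathway enrichment of the HGP, and its correlation topology
#' network with landmark genes. Artifacts are written under
#' `config$out_dir` (one subdirectory per condition) together with a
#' machine-readable `manifest.json` holding seeds, thresholds and the count
#' at every stage. Reruns with the same config and seed produce identical
#' manifests.
#'
#' @param config a [pipeline_config()].
#' @param stop_after optional stage name (`"preprocess"`, `"graph"`,
#'   `"train"`, `"cluster"`, `"evaluate"`, `"analyze"` = full run) at which
#'   to stop; earlier stages always run.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, stop_after = "analyze") {
  stages <- c("preprocess", "graph", "train", "cluster", "evaluate",
              "analyze")
  stop_after <- match.arg(stop_after, stages)
  stage_no <- match(stop_after, stages)
  # Validate file inputs up front so a bad path fails before any compute.
  for (field in c("expression", "annotations", "design")) {
    v <- config[[field]]
    if (is.character(v) && length(v) == 1 && !file.exists(v)) {
      abort(sprintf("input file for '%s' not found: %s", field, v),
            "coexpanel_io_error")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("coexpanel")),
                   seed = config$seed,
                   parameters = list(
                     target_mean_degree = config$target_mean_degree,
                     perplexity = config$perplexity,
                     tsne_max_iter = config$tsne_max_iter,
                     theta = config$theta, alpha = config$gcn$alpha,
                     n_candidates = config$n_candidates,
                     default_n = config$default_n, fas_k = config$fas_k,
                     enrichment = config$enrichment,
                     network = config$network),
                   conditions = list())

  expr <- if (inherits(config$expression, "expr_set")) config$expression else
    run_stage(manifest, "preprocess",
              read_expression_table(config$expression, config$design))
  annot <- if (inherits(config$annotations, "data.frame")) {
    config$annotations
  } else {
    run_stage(manifest, "preprocess",
              read_annotation_table(config$annotations))
  }
  manifest$n_genes_input <- nrow(expr$values)
  manifest$n_samples <- ncol(expr$values)

  for (ci in seq_along(config$test_conditions)) {
    cond <- config$test_conditions[ci]
    cdir <- file.path(config$out_dir, cond)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    m <- list(condition = cond)

    degs <- run_stage(manifest, "preprocess", {
      if (!is.null(config$deg_tables[[cond]])) {
        d <- config$deg_tables[[cond]]
        if (is.character(d)) read_deg_table(d) else d
      } else {
        differential_expression(expr, cond, config$control_condition)
      }
    })
    valid <- run_stage(manifest, "preprocess", suppressMessages(
      filter_valid_degs(degs, config$min_mean_expression)))
    dataset <- run_stage(manifest, "preprocess", split_condition_datasets(
      expr, stats::setNames(list(valid), cond),
      config$control_condition))[[cond]]
    write_deg_table(valid, file.path(cdir, "valid_degs.tsv"))
    m$n_degs <- sum(degs$is_deg)
    m$n_valid_degs <- nrow(valid)

    if (stage_no >= 2) {
      g <- run_stage(manifest, "graph", {
        X <- build_node_features(log_normalize(dataset$values), annot)
        layout <- embed_layout_2d(X, perplexity = config$perplexity,
                                  max_iter = config$tsne_max_iter,
                                  theta = config$theta,
                                  seed = stage_seed(config$seed, 2, ci))
        cal <- calibrate_threshold(layout, config$target_mean_degree)
        gg <- build_graph(rownames(X), X, layout, cal$threshold)
        attr(gg, "calibration") <- cal
        gg
      })
      write_graph_files(g, cdir)
      m$n_features <- ncol(g$X)
      m$n_edges <- nrow(g$edges)
      m$mean_degree <- attr(g, "calibration")$mean_degree
      m$threshold <- attr(g, "calibration")$threshold
    }

    if (stage_no >= 3) {
      fit <- run_stage(manifest, "train", {
        cfg <- config$gcn
        cfg$seed <- stage_seed(config$seed, 3, ci)
        train_and_embed(g, cfg)
      })
      write_embedding_files(fit, cdir)
      m$train_epochs <- nrow(fit$state$log)
      m$best_objective <- max(fit$state$log$objective)
    }

    assignments <- NULL
    if (stage_no >= 4) {
      assignments <- run_stage(manifest, "cluster", {
        lapply(config$n_candidates, function(n)
          cluster_panels(fit$embeddings, n, pca_dims = config$pca_dims,
                         seed = stage_seed(config$seed, 4, ci)))
      })
      names(assignments) <- as.character(config$n_candidates)
      adf <- do.call(rbind, lapply(assignments, function(a)
        data.frame(gene = a$node_ids, cluster = unname(a$labels),
                   method = a$method, n = a$n_clusters)))
      write_tsv(adf, file.path(cdir, "assignments.tsv"))
      m$panel_sizes <- lapply(assignments, function(a)
        as.integer(table(a$labels)))
    }

    chosen_n <- config$default_n
    if (stage_no >= 5) {
      eval_out <- run_stage(manifest, "evaluate", {
        al <- suppressMessages(align_annotations(rownames(dataset$values),
                                                 annot))
        pp <- pathway_pairs(al)
        photo <- unique(pp$gene_id[pp$pathway == config$reference_pathway])
        lognorm <- log_normalize(dataset$values)
        sci <- vapply(assignments, function(a)
          silhouette_index(lognorm, a$labels), numeric(1))
        fas <- vapply(assignments, function(a)
          functional_assignment_score(a, photo, k = config$fas_k),
          numeric(1))
        sel <- if (length(photo) > 0) {
          select_cluster_number(assignments, photo, k = config$fas_k)
        } else list(n = config$default_n, report = NULL)
        list(photo = photo, sci = sci, fas = fas, sel = sel)
      })
      report <- data.frame(n = config$n_candidates,
                           sci = unname(eval_out$sci),
                           fas = unname(eval_out$fas))
      utils::write.csv(report, file.path(cdir, "evaluation.csv"),
                       row.names = FALSE)
      m$evaluation <- report
      m$selected_n <- eval_out$sel$n
      if (config$select_n_by_fas) chosen_n <- eval_out$sel$n
    }

    if (stage_no >= 6) {
      analytics <- run_stage(manifest, "analyze", {
        assignment <- assignments[[as.character(chosen_n)]] %||%
          cluster_panels(fit$embeddings, chosen_n,
                         pca_dims = config$pca_dims,
                         seed = stage_seed(config$seed, 4, ci))
        al <- suppressMessages(align_annotations(rownames(dataset$values),
                                                 annot))
        pd <- extract_function_genes(al, config$pd_keywords, dataset,
                                     config$min_mean_expression)
        des <- suppressWarnings(designate_panels(
          assignment, pd, eval_out$photo, expr = dataset, degs = valid))
        hgp_genes <- if (!is.na(des$hgp)) {
          names(assignment$labels)[assignment$labels == des$hgp]
        } else character(0)
        enr <- if (!is.na(des$hgp)) {
          suppressMessages(enrich_pathways(
            hgp_genes, annot, dataset, cond, config$control_condition,
            p_max = config$enrichment$p_max,
            fc_bounds = config$enrichment$fc_bounds,
            min_mean_expression = config$enrichment$min_mean_expression))
        } else NULL
        net <- if (!is.na(des$hgp) && length(hgp_genes) >= 2) {
          nn <- suppressMessages(build_topology_network(
            subset_expr(dataset, genes = hgp_genes)$values,
            r_min = config$network$r_min, p_max = config$network$p_max,
            absolute = isTRUE(config$network$absolute)))
          compute_topology_metrics(nn, seed = stage_seed(config$seed, 6, ci))
        } else NULL
        lmk <- if (!is.null(net)) {
          landmark_genes(net, dataset, cond)
        } else NULL
        list(pd = pd, des = des, enr = enr, net = net, lmk = lmk)
      })
      if (!is.null(analytics$enr)) {
        utils::write.csv(analytics$enr, file.path(cdir, "enrichment.csv"),
                         row.names = FALSE)
      }
      if (!is.null(analytics$net)) {
        export_gexf(analytics$net, file.path(cdir, "topology.gexf"))
        export_graphml(analytics$net, file.path(cdir, "topology.graphml"))
      }
      if (!is.null(analytics$lmk)) {
        write_tsv(analytics$lmk, file.path(cdir, "landmarks.tsv"))
      }
      m$n_pd_genes <- length(analytics$pd)
      m$hgp <- analytics$des$hgp
      m$sgp <- analytics$des$sgp
      m$analysis_n <- chosen_n
      if (!is.null(analytics$net)) {
        m$n_network_edges <- nrow(analytics$net$edges)
        m$n_modularity_classes <-
          length(unique(analytics$net$metrics$modularity_class))
      }
    }
    manifest$conditions[[cond]] <- m
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
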