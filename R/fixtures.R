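# synthetic_fixtures: self-contained generators with planted structure.

#' Specification of a synthetic planted-panel dataset
#'
#' Describes the generative model used throughout the test suite: genes are
#' grouped into coexpression panels; for gene g in panel b and condition c,
#' log10 FPKM is drawn as Normal(mu_b + delta_bc, sigma) per replicate and
#' exponentiated back to FPKM. Condition effects `delta` are specified on the
#' log2 scale so they compare directly with DEG fold-change thresholds.
#' Annotations plant a "Phototransduction" pathway concentrated in one panel
#' (the signaling-like panel) and nitrate/nitrite keyword descriptions in
#' another (the hub-like panel), plus Bernoulli subcellular flags at
#' panel-specific rates.
#'
#' @param n_genes total gene count (default 2000).
#' @param n_panels number of planted panels (default 3; panel sizes must end
#'   up >= 10).
#' @param replicates named integer vector of replicates per condition; the
#'   first name is the control (default dark/blue/yellow triplicates).
#' @param baseline_log10 per-panel baseline mean of log10 FPKM under the
#'   control condition.
#' @param effect_log2 matrix (n_panels x non-control conditions) of planted
#'   log2 fold changes relative to the control.
#' @param noise_sd replicate noise sd on the log10 scale (default 0.15).
#' @param sp_rate,tm_rate per-panel Bernoulli rates of the signal-peptide and
#'   transmembrane flags.
#' @param photo_panel,pd_panel panel indices hosting the planted
#'   phototransduction pathway and the nitrate/nitrite (partial
#'   denitrification) genes.
#' @param photo_size,pd_size gene counts of the two planted functional sets.
#' @param photo_conc fraction of phototransduction genes drawn from
#'   `photo_panel` (default 0.9, i.e. >= 80% concentrated).
#' @param seed RNG seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 2000,
                         n_panels = 3,
                         replicates = c(dark = 3, blue = 3, yellow = 3),
                         baseline_log10 = c(2, 1, 1.5),
                         effect_log2 = rbind(c(3, 0), c(0, 3), c(-3, -3)),
                         noise_sd = 0.15,
                         sp_rate = c(0.6, 0.2, 0.1),
                         tm_rate = c(0.3, 0.1, 0.5),
                         photo_panel = 2, pd_panel = 1,
                         photo_size = min(30, max(5, n_genes %/% 10)),
                         pd_size = min(40, max(5, n_genes %/% 8)),
                         photo_conc = 0.9,
                         seed = 0) {
  if (is.null(names(replicates)) || any(names(replicates) == "")) {
    abort("'replicates' must be a named vector of conditions",
          "coexpanel_input_error")
  }
  baseline_log10 <- rep_len(baseline_log10, n_panels)
  sp_rate <- rep_len(sp_rate, n_panels)
  tm_rate <- rep_len(tm_rate, n_panels)
  effect_log2 <- matrix(effect_log2, nrow = n_panels,
                        ncol = length(replicates) - 1)
  if (any(!is.finite(effect_log2))) {
    abort("effect sizes must be finite", "coexpanel_input_error")
  }
  if (any(sp_rate < 0 | sp_rate > 1 | tm_rate < 0 | tm_rate > 1)) {
    abort("subcellular flag rates must be in [0, 1]", "coexpanel_input_error")
  }
  if (floor(n_genes / n_panels) < 10) {
    abort("panel sizes must be >= 10 genes", "coexpanel_input_error")
  }
  if (photo_size + pd_size > n_genes / 2) {
    abort("planted functional sets exceed half the gene count",
          "coexpanel_input_error")
  }
  structure(list(n_genes = n_genes, n_panels = n_panels,
                 replicates = replicates, baseline_log10 = baseline_log10,
                 effect_log2 = effect_log2, noise_sd = noise_sd,
                 sp_rate = sp_rate, tm_rate = tm_rate,
                 photo_panel = photo_panel, pd_panel = pd_panel,
                 photo_size = photo_size, pd_size = pd_size,
                 photo_conc = photo_conc, seed = seed),
            class = "fixture_spec")
}

panel_labels_of <- function(spec) {
  sizes <- rep(floor(spec$n_genes / spec$n_panels), spec$n_panels)
  sizes[1] <- sizes[1] + spec$n_genes - sum(sizes)
  rep(seq_len(spec$n_panels), sizes)
}

#' Generate a synthetic expression matrix with planted panels
#'
#' @param spec a [fixture_spec()].
#' @return list with `expr` (an [expression_set()]) and `panels` (named
#'   integer vector of ground-truth panel labels).
#' @export
generate_expression <- function(spec) {
  set.seed(spec$seed)
  conds <- names(spec$replicates)
  sample_ids <- unlist(lapply(conds, function(cc)
    paste(cc, seq_len(spec$replicates[[cc]]), sep = "_")))
  cond_of <- stats::setNames(rep(conds, spec$replicates), sample_ids)
  labels <- panel_labels_of(spec)
  gene_ids <- sprintf("gene_%04d", seq_len(spec$n_genes))
  # Mean of log10 FPKM per panel x condition; control effect is 0.
  delta_log10 <- cbind(0, spec$effect_log2 * log10(2))
  colnames(delta_log10) <- conds
  mu <- spec$baseline_log10[labels]
  vals <- matrix(0, spec$n_genes, length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (s in sample_ids) {
    m <- mu + delta_log10[cbind(labels, match(cond_of[[s]], conds))]
    vals[, s] <- 10^(stats::rnorm(spec$n_genes, mean = m, sd = spec$noise_sd))
  }
  list(expr = expression_set(vals, cond_of),
       panels = stats::setNames(labels, gene_ids))
}

#' Generate synthetic gene annotations for a planted fixture
#'
#' Plants a "Phototransduction" pathway concentrated in `spec$photo_panel`,
#' nitrate/nitrite Swiss-Prot-style descriptions concentrated in
#' `spec$pd_panel`, filler pathways/descriptions elsewhere, and Bernoulli
#' subcellular flags at the panel rates.
#'
#' @param spec a [fixture_spec()].
#' @param panels named integer vector of panel labels as returned by
#'   [generate_expression()].
#' @return a `gene_annotation` data frame covering every gene.
#' @export
generate_annotations <- function(spec, panels) {
  set.seed(spec$seed + 1L)
  gene_ids <- names(panels)
  n <- length(gene_ids)
  sp <- stats::rbinom(n, 1, spec$sp_rate[panels])
  tm <- stats::rbinom(n, 1, spec$tm_rate[panels])

  filler_paths <- c("Glycolysis / Gluconeogenesis", "Oxidative phosphorylation",
                    "Two-component system", "ABC transporters",
                    "Butanoate metabolism", "Ribosome")
  pathway <- sample(filler_paths, n, replace = TRUE)
  description <- rep("hypothetical protein", n)

  in_photo <- which(panels == spec$photo_panel)
  out_photo <- which(panels != spec$photo_panel)
  n_in <- min(length(in_photo), round(spec$photo_conc * spec$photo_size))
  photo_idx <- c(sample(in_photo, n_in),
                 sample(out_photo, spec$photo_size - n_in))
  pathway[photo_idx] <- "Phototransduction"
  description[photo_idx] <- "blue-light photoreceptor protein"

  pd_desc <- c("nitrate reductase alpha subunit",
               "nitrite reductase (NADH) large subunit",
               "nitrate/nitrite transporter NarK")
  in_pd <- setdiff(which(panels == spec$pd_panel), photo_idx)
  out_pd <- setdiff(which(panels != spec$pd_panel), photo_idx)
  n_in <- min(length(in_pd), round(0.9 * spec$pd_size))
  pd_idx <- c(sample(in_pd, n_in), sample(out_pd, spec$pd_size - n_in))
  pathway[pd_idx] <- "Nitrogen metabolism"
  description[pd_idx] <- rep_len(pd_desc, length(pd_idx))

  out <- data.frame(gene_id = gene_ids, signal_peptide = sp,
                    transmembrane = tm, pathway = pathway,
                    description = description, stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Deterministic toy layouts with enumerable edge sets
#'
#' Small geometric point sets whose threshold graphs can be enumerated by
#' hand, used as oracles for graph construction and calibration.
#'
#' @param n_nodes number of points.
#' @param geometry `"line"` (points on a line at cumulative `gaps`),
#'   `"hexagon"` (regular hexagon with unit side, `n_nodes` fixed at 6) or
#'   `"blocks"` (two Gaussian blobs separated by `separation`).
#' @param seed RNG seed (used by `"blocks"` only).
#' @param gaps inter-point gaps for `"line"` (recycled).
#' @param separation centroid distance for `"blocks"` (default 10; blob sd
#'   0.5).
#' @return matrix of 2D coordinates with an attribute `geometry`.
#' @export
generate_graph_toy <- function(n_nodes, geometry = c("line", "hexagon",
                                                     "blocks"),
                               seed = 0, gaps = 1, separation = 10) {
  geometry <- match.arg(geometry)
  if (n_nodes < 2) abort("need >= 2 nodes", "coexpanel_input_error")
  coords <- switch(geometry,
    line = cbind(c(0, cumsum(rep_len(gaps, n_nodes - 1))), 0),
    hexagon = {
      ang <- (0:5) * pi / 3
      cbind(cos(ang), sin(ang))  # circumradius 1 => unit side length
    },
    blocks = {
      set.seed(seed)
      n1 <- floor(n_nodes / 2)
      rbind(matrix(stats::rnorm(2 * n1, 0, 0.5), ncol = 2),
            matrix(stats::rnorm(2 * (n_nodes - n1), separation, 0.5),
                   ncol = 2))
    })
  rownames(coords) <- sprintf("node_%02d", seq_len(nrow(coords)))
  attr(coords, "geometry") <- geometry
  coords
}

#' Write fixture files in the formats the readers consume
#'
#' Emits `expression.tsv`, `design.tsv`, `annotations.tsv` and
#' `truth_panels.tsv` under `dir`, round-trippable through
#' [read_expression_table()] and [read_annotation_table()].
#'
#' @param dir output directory (created if needed).
#' @param expr an [expression_set()].
#' @param annot a `gene_annotation` data frame.
#' @param panels optional named ground-truth panel labels.
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(dir, expr, annot, panels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(expr, file.path(dir, "expression.tsv"))
  write_tsv(data.frame(sample = names(expr$condition),
                       condition = unname(expr$condition)),
            file.path(dir, "design.tsv"))
  write_tsv(as.data.frame(annot), file.path(dir, "annotations.tsv"))
  if (!is.null(panels)) {
    write_tsv(data.frame(gene_id = names(panels), panel = unname(panels)),
              file.path(dir, "truth_panels.tsv"))
  }
  invisible(dir)
}
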