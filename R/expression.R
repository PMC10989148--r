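# core_data: expression containers, normalization, differential expression.

#' Construct an expression set
#'
#' Container for a gene x sample FPKM matrix together with the experimental
#' design (condition of each sample and replicate index within condition).
#' This is the object the rest of the pipeline consumes.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Values are FPKM and must be >= 0.
#' @param condition named character vector mapping every sample id to a
#'   condition label (e.g. `"dark"`, `"blue"`, `"yellow"`).
#' @return an object of class `expr_set`: a list with elements `values`,
#'   `condition` and `replicate` (index of each sample within its condition).
#' @export
expression_set <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("'values' must be a numeric matrix", "coexpanel_input_error")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      is.null(colnames(values))) {
    abort("'values' must have gene ids as rownames and sample ids as colnames",
          "coexpanel_input_error")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  dup <- duplicated(rownames(values))
  if (any(dup)) {
    abort(sprintf("duplicate gene ids: %s",
                  paste(unique(rownames(values)[dup]), collapse = ", ")),
          "coexpanel_validation_error")
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("negative expression value at gene '%s', sample '%s'",
                  rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
          "coexpanel_validation_error")
  }
  missing <- setdiff(colnames(values), names(condition))
  if (length(missing) > 0) {
    abort(sprintf("samples without a condition label: %s",
                  paste(missing, collapse = ", ")),
          "coexpanel_input_error")
  }
  condition <- condition[colnames(values)]
  replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  names(replicate) <- names(condition)
  structure(list(values = values, condition = condition,
                 replicate = replicate),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions:", paste(sprintf("%s (n=%d)", names(table(x$condition)),
                                   table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

# Subset an expr_set by gene ids and/or sample ids.
subset_expr <- function(expr, genes = NULL, samples = NULL) {
  v <- expr$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_set(v, expr$condition[colnames(v)])
}

samples_of <- function(expr, conditions) {
  names(expr$condition)[expr$condition %in% conditions]
}

#' Read a sample design table
#'
#' Two-column (sample, condition) tab-delimited file with a header row.
#'
#' @param path path to the design file.
#' @return named character vector mapping sample id to condition.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("design file not found: %s", path), "coexpanel_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    abort("design file must have two columns: sample, condition",
          "coexpanel_parse_error")
  }
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a gene x sample expression table
#'
#' Tab- or comma-delimited, first column gene id, header row of sample ids.
#' Values are FPKM; negative values and duplicated gene ids are rejected.
#'
#' @param path path to the expression table.
#' @param design named character vector (sample -> condition), or the path of
#'   a design file readable by [read_design_table()].
#' @return an [expression_set()].
#' @export
read_expression_table <- function(path, design) {
  if (!file.exists(path)) {
    abort(sprintf("expression file not found: %s", path), "coexpanel_io_error")
  }
  if (is.character(design) && length(design) == 1 && is.null(names(design))) {
    design <- read_design_table(design)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) {
    abort("malformed header: expected gene id column plus >= 1 sample column",
          "coexpanel_parse_error")
  }
  gene_ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    abort("malformed expression table: non-numeric values",
          "coexpanel_parse_error")
  }
  rownames(mat) <- gene_ids
  expression_set(mat, design)
}

#' Write an expression set to a TSV file
#'
#' @param expr an [expression_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Log-normalize FPKM values
#'
#' Elementwise `x = log10(fpkm + 1)`. Maps 0 to 0, preserves ordering and
#' shape, and is inverted exactly by `10^x - 1`.
#'
#' @param values non-negative numeric vector or matrix of FPKM values.
#' @return object of the same shape on the log10 scale.
#' @export
log_normalize <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    abort("log_normalize requires non-negative FPKM values",
          "coexpanel_domain_error")
  }
  log10(values + 1)
}

# Row-wise Welch two-sample t-test, vectorized over genes.
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # Degenerate rows: both groups constant -> se 0, t undefined.
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  p
}

#' Differential expression between two conditions
#'
#' A lightweight, auditable stand-in for a negative-binomial DE package:
#' the log2 fold change is computed on condition-mean FPKM with a pseudocount
#' and the p-value from a two-sided Welch t-test on log10(FPKM + 1) replicate
#' values. A precomputed DE table from an external tool can be used instead
#' via [read_deg_table()].
#'
#' @param expr an [expression_set()].
#' @param test_condition,control_condition condition labels present in the
#'   design, each with >= 2 replicates.
#' @param epsilon pseudocount added to both condition means for the fold
#'   change (default `1e-6`).
#' @param adjust_p if `TRUE`, add a Benjamini-Hochberg adjusted p-value
#'   column and use it for the DEG flag (default `FALSE`: raw p < 0.05).
#' @return a `deg_table` data frame with columns `gene_id`,
#'   `log2_fold_change`, `p_value`, `mean_expression` (mean FPKM over the
#'   test + control samples) and `is_deg` (`|log2FC| > 1` and `p < 0.05`).
#' @export
differential_expression <- function(expr, test_condition, control_condition,
                                    epsilon = 1e-6, adjust_p = FALSE) {
  for (cond in c(test_condition, control_condition)) {
    n <- sum(expr$condition == cond)
    if (n == 0) {
      abort(sprintf("condition '%s' not present in design", cond),
            "coexpanel_config_error")
    }
    if (n < 2) {
      abort(sprintf("condition '%s' has %d replicate(s); >= 2 required", cond,
                    n), "coexpanel_stats_error")
    }
  }
  test_s <- samples_of(expr, test_condition)
  ctrl_s <- samples_of(expr, control_condition)
  vt <- expr$values[, test_s, drop = FALSE]
  vc <- expr$values[, ctrl_s, drop = FALSE]
  lfc <- log2((rowMeans(vt) + epsilon) / (rowMeans(vc) + epsilon))
  p <- welch_rows(log_normalize(vt), log_normalize(vc))
  out <- data.frame(gene_id = rownames(expr$values),
                    log2_fold_change = unname(lfc),
                    p_value = unname(p),
                    mean_expression = unname(rowMeans(cbind(vt, vc))),
                    stringsAsFactors = FALSE)
  p_used <- out$p_value
  if (adjust_p) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    p_used <- out$p_adjusted
  }
  out$is_deg <- abs(out$log2_fold_change) > 1 & p_used < 0.05
  attr(out, "test_condition") <- test_condition
  attr(out, "control_condition") <- control_condition
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Filter low-expression DEGs
#'
#' Retains flagged DEGs whose mean FPKM (over the dataset's samples) is at
#' least `min_mean_expression`; genes with mean expression below the cutoff
#' are dropped ("filter < 1" rule, so a mean of exactly 1 is retained).
#'
#' @param degs a `deg_table` from [differential_expression()] or
#'   [read_deg_table()].
#' @param min_mean_expression FPKM cutoff, default 1.
#' @return the subset of `degs` that are valid DEGs.
#' @export
filter_valid_degs <- function(degs, min_mean_expression = 1) {
  keep <- degs$is_deg & degs$mean_expression >= min_mean_expression
  out <- degs[keep, , drop = FALSE]
  message(sprintf("filter_valid_degs: %d of %d genes are valid DEGs",
                  nrow(out), nrow(degs)))
  if (nrow(out) == 0) warning("no valid DEGs after filtering")
  out
}

#' Split valid DEGs into per-condition model datasets
#'
#' Each light condition gets its own dataset: its valid DEGs only, with the
#' expression columns of that condition's replicates plus the control
#' replicates (triplicates on both sides give the 6 expression feature
#' columns used downstream).
#'
#' @param expr an [expression_set()] covering all samples.
#' @param valid_degs named list (by test condition) of valid `deg_table`s, or
#'   of gene id vectors.
#' @param control_condition label of the control condition (default
#'   `"dark"`).
#' @return named list of [expression_set()] objects, one per test condition.
#' @export
split_condition_datasets <- function(expr, valid_degs,
                                     control_condition = "dark") {
  out <- list()
  for (cond in names(valid_degs)) {
    d <- valid_degs[[cond]]
    genes <- if (is.data.frame(d)) d$gene_id else as.character(d)
    if (length(genes) == 0) {
      warning(sprintf("condition '%s' has no valid DEGs; empty dataset", cond))
    }
    smp <- samples_of(expr, c(cond, control_condition))
    out[[cond]] <- subset_expr(expr, genes = genes, samples = smp)
  }
  out
}

#' Read / write DEG tables
#'
#' Tab-delimited tables with the `deg_table` schema (`gene_id`,
#' `log2_fold_change`, `p_value`, `mean_expression`, `is_deg`), e.g. exported
#' from an external DE tool to bypass the built-in test.
#'
#' @param path file path.
#' @return `read_deg_table` returns a `deg_table` data frame.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("DEG table not found: %s", path), "coexpanel_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "log2_fold_change", "p_value", "mean_expression")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf("DEG table missing columns: %s",
                  paste(missing, collapse = ", ")), "coexpanel_parse_error")
  }
  if (is.null(df$is_deg)) {
    df$is_deg <- abs(df$log2_fold_change) > 1 & df$p_value < 0.05
  }
  df$is_deg <- as.logical(df$is_deg)
  class(df) <- c("deg_table", "data.frame")
  df
}

#' @rdname read_deg_table
#' @param degs a `deg_table`.
#' @export
write_deg_table <- function(degs, path) {
  write_tsv(as.data.frame(degs), path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-delimited with columns `gene_id`, `signal_peptide` (0/1),
#' `transmembrane` (0/1), `pathway` (semicolon-separated KEGG level-3 style
#' names) and `description` (Swiss-Prot style free text). An optional `brite`
#' column carries a higher-level category.
#'
#' @param path file path.
#' @return a `gene_annotation` data frame.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path), "coexpanel_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "signal_peptide", "transmembrane", "pathway",
              "description")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf("annotation table missing columns: %s",
                  paste(missing, collapse = ", ")), "coexpanel_parse_error")
  }
  df$signal_peptide <- as.integer(df$signal_peptide)
  df$transmembrane <- as.integer(df$transmembrane)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

# Align annotations to a gene id vector; genes without an annotation row get
# zero flags / empty pathway, and the coverage gap is logged.
align_annotations <- function(gene_ids, annot, default_missing = TRUE) {
  idx <- match(gene_ids, annot$gene_id)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    if (!default_missing) {
      abort(sprintf("%d genes lack annotations and defaulting is disabled",
                    n_missing), "coexpanel_input_error")
    }
    message(sprintf(
      "annotation coverage: %d/%d genes annotated; %d defaulted to 0/empty",
      length(gene_ids) - n_missing, length(gene_ids), n_missing))
  }
  out <- data.frame(gene_id = gene_ids,
                    signal_peptide = ifelse(is.na(idx), 0L,
                                            annot$signal_peptide[idx]),
                    transmembrane = ifelse(is.na(idx), 0L,
                                           annot$transmembrane[idx]),
                    pathway = ifelse(is.na(idx), "", annot$pathway[idx]),
                    description = ifelse(is.na(idx), "",
                                         annot$description[idx]),
                    stringsAsFactors = FALSE)
  if (!is.null(annot$brite)) {
    out$brite <- ifelse(is.na(idx), "", annot$brite[idx])
  }
  out
}

# Expand the semicolon-separated pathway column into (gene_id, pathway) pairs.
pathway_pairs <- function(annot) {
  spl <- strsplit(annot$pathway, ";", fixed = TRUE)
  n <- lengths(spl)
  df <- data.frame(gene_id = rep(annot$gene_id, n),
                   pathway = trimws(unlist(spl)),
                   stringsAsFactors = FALSE)
  df[df$pathway != "", , drop = FALSE]
}
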