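# Projection-barcode (UPB) classification: QC filtering, damaged-cluster
# flagging, per-cell barcode calls, organ-pair correlation and cluster-level
# barcode statistics.
#
# A cell table is a data.frame with one row per cell and columns:
#   cell_id, cluster, emb_1, emb_2, n_genes, mito_fraction,
#   upb_<organ> ... (processed-scale barcode expression),
#   marker_<gene> ... (processed-scale marker expression).

upb_columns <- function(cells) {
  setdiff(grep("^upb_", names(cells), value = TRUE),
          c("upb_category", "upb_organs", "upb_sphincter"))
}

upb_organs <- function(cells) sub("^upb_", "", upb_columns(cells))

marker_column <- function(cells, gene) {
  col <- paste0("marker_", gene)
  stop_if(!col %in% names(cells),
          sprintf("marker '%s' absent from cell table", gene))
  col
}

#' Quality-control filter on per-cell metrics
#'
#' Retains cells with `n_genes` strictly greater than `min_genes`, strictly
#' less than `max_genes`, and mitochondrial fraction strictly less than
#' `max_mito`. Defaults follow standard single-cell practice for sensory
#' ganglia: more than 500 and fewer than 8,000 genes per cell, under 10%
#' mitochondrial reads.
#'
#' @param cells Cell table.
#' @param min_genes,max_genes Gene-count bounds (exclusive).
#' @param max_mito Mitochondrial-fraction bound (exclusive), in \[0, 1\].
#' @return The retained cell table, with an attribute `removed` giving
#'   per-rule removal counts (a cell can violate several rules).
#' @export
qc_filter <- function(cells, min_genes = 500, max_genes = 8000,
                      max_mito = 0.10) {
  stop_if(nrow(cells) == 0, "empty cell table")
  stop_if(min_genes <= 0 || max_genes <= 0 || max_mito <= 0,
          "thresholds must be positive")
  stop_if(min_genes >= max_genes, "min_genes must be below max_genes")
  low <- !(cells$n_genes > min_genes)
  high <- !(cells$n_genes < max_genes)
  mito <- !(cells$mito_fraction < max_mito)
  keep <- !(low | high | mito)
  out <- cells[keep, , drop = FALSE]
  attr(out, "removed") <- c(low_genes = sum(low), high_genes = sum(high),
                            high_mito = sum(mito), total = sum(!keep))
  out
}

#' Flag clusters of damaged cells
#'
#' Dissociation- and tracing-induced damage produces a distinct
#' transcriptional state marked by injury genes such as Sprr1a and Ecel1.
#' Clusters whose mean marker expression exceeds `multiple` times the grand
#' mean (over all cells, averaged across markers) are flagged; flagged
#' clusters are conventionally removed before projection analysis.
#'
#' @param cells Cell table.
#' @param markers Character vector of damage marker genes (default Sprr1a,
#'   Ecel1); each must be present as a `marker_<gene>` column.
#' @param multiple Flagging threshold as a multiple of the grand mean
#'   marker expression; default 5.
#' @return Named logical vector over clusters (TRUE = flagged).
#' @export
flag_damaged <- function(cells, markers = c("Sprr1a", "Ecel1"), multiple = 5) {
  stop_if(length(markers) == 0, "markers must be nonempty")
  cols <- vapply(markers, marker_column, character(1), cells = cells)
  expr <- as.matrix(cells[, cols, drop = FALSE])
  # per-cell damage score: mean over markers
  score <- rowMeans(expr)
  grand <- mean(score)
  cl_means <- tapply(score, cells$cluster, mean)
  flags <- as.vector(cl_means) > multiple * grand & grand > 0
  setNames(flags, names(cl_means))
}

#' Remove cells in damage-flagged clusters
#'
#' @param cells Cell table.
#' @param flags Output of [flag_damaged()].
#' @return Cell table without cells in flagged clusters.
#' @export
drop_damaged <- function(cells, flags) {
  bad <- names(flags)[flags]
  cells[!(cells$cluster %in% bad), , drop = FALSE]
}

#' Classify a cell's projection target from barcode expression
#'
#' Organs whose barcode expression is strictly above `threshold` form the
#' positive set. No positive barcode: unlabelled. One: organ-specific
#' (single). The stomach/oesophagus pair marks oesophageal-sphincter
#' projecting neurons and the stomach/duodenum pair pyloric-sphincter
#' projecting neurons; other pairs are dual. Three or more: multi.
#'
#' @param upb_expr Named numeric vector of barcode expression per organ
#'   (processed scale).
#' @param threshold Positivity cutoff (strict), default 0.8.
#' @return List with `category` (one of "single", "dual", "sphincter",
#'   "multi", "unlabelled"), `organs` (character vector of positive organs)
#'   and, for sphincters, `sphincter` ("oesophageal" or "pyloric").
#' @export
#' @examples
#' classify_upb(c(lung = 1.2, heart = 0))$category            # "single"
#' classify_upb(c(stomach = 0.9, duodenum = 0.85))$sphincter  # "pyloric"
classify_upb <- function(upb_expr, threshold = 0.8) {
  stop_if(threshold < 0, "threshold must be nonnegative")
  stop_if(is.null(names(upb_expr)), "upb_expr must be named by organ")
  pos <- sort(names(upb_expr)[upb_expr > threshold])
  n <- length(pos)
  if (n == 0) return(list(category = "unlabelled", organs = character(0)))
  if (n == 1) return(list(category = "single", organs = pos))
  if (n == 2) {
    if (setequal(pos, c("stomach", "oesophagus")))
      return(list(category = "sphincter", organs = pos,
                  sphincter = "oesophageal"))
    if (setequal(pos, c("stomach", "duodenum")))
      return(list(category = "sphincter", organs = pos,
                  sphincter = "pyloric"))
    return(list(category = "dual", organs = pos))
  }
  list(category = "multi", organs = pos)
}

#' Classify every cell in a table
#'
#' Applies [classify_upb()] to each row's `upb_*` columns and appends the
#' call to the table.
#'
#' @param cells Cell table.
#' @param threshold Positivity cutoff (strict), default 0.8.
#' @return The cell table with added columns `upb_category`, `upb_organs`
#'   (positive organs, "+"-separated) and `upb_sphincter` (NA when not a
#'   sphincter pair).
#' @export
classify_cells <- function(cells, threshold = 0.8) {
  cols <- upb_columns(cells)
  stop_if(length(cols) == 0, "cell table has no upb_* columns")
  organs <- sub("^upb_", "", cols)
  expr <- as.matrix(cells[, cols, drop = FALSE])
  colnames(expr) <- organs
  calls <- apply(expr, 1, classify_upb, threshold = threshold)
  cells$upb_category <- vapply(calls, `[[`, character(1), "category")
  cells$upb_organs <- vapply(calls, function(x)
    paste(x$organs, collapse = "+"), character(1))
  cells$upb_sphincter <- vapply(calls, function(x)
    if (is.null(x$sphincter)) NA_character_ else x$sphincter, character(1))
  cells
}

#' Organ-pair correlation matrix from single and dual barcode counts
#'
#' Summarises how often organ pairs share projection neurons. The
#' off-diagonal entry for organs i, j is the dual-labelled count for the
#' pair divided by the geometric mean of the two single-labelled counts:
#' `N_dual(i,j) / sqrt(N_single(i) * N_single(j))`. Sphincter pairs count
#' as dual labels of their two organs. The diagonal is 1. An organ with no
#' single-labelled cells yields `NA` entries rather than zero.
#'
#' @param cells Cell table after [classify_cells()].
#' @return Symmetric numeric matrix over the table's organs.
#' @export
organ_correlation_matrix <- function(cells) {
  stop_if(!"upb_category" %in% names(cells),
          "run classify_cells() first")
  organs <- upb_organs(cells)
  singles <- cells[cells$upb_category == "single", "upb_organs"]
  n_single <- table(factor(singles, levels = organs))
  duals <- cells[cells$upb_category %in% c("dual", "sphincter"),
                 "upb_organs"]
  m <- matrix(0, length(organs), length(organs),
              dimnames = list(organs, organs))
  if (length(duals) > 0) {
    pairs <- strsplit(duals, "+", fixed = TRUE)
    for (p in pairs) {
      m[p[1], p[2]] <- m[p[1], p[2]] + 1
      m[p[2], p[1]] <- m[p[2], p[1]] + 1
    }
  }
  denom <- sqrt(outer(as.numeric(n_single), as.numeric(n_single)))
  out <- ifelse(denom > 0, m / denom, NA_real_)
  dimnames(out) <- list(organs, organs)
  diag(out) <- 1
  out
}

#' Cluster share of an organ's barcode-labelled cells
#'
#' `P_organ_cluster`: the number of single-labelled cells for the organ in
#' the cluster divided by the number of single-labelled cells for the organ
#' overall. Sums to 1 over clusters for every organ.
#'
#' @param cells Cell table after [classify_cells()].
#' @param organ Organ name.
#' @param cluster Cluster label; if NULL, returns the vector over all
#'   clusters present in the table.
#' @return Fraction(s) in \[0, 1\].
#' @export
cluster_upb_percentage <- function(cells, organ, cluster = NULL) {
  stop_if(!"upb_category" %in% names(cells), "run classify_cells() first")
  lab <- cells$upb_category == "single" & cells$upb_organs == organ
  total <- sum(lab)
  stop_if(total == 0, sprintf("no single-labelled cells for organ '%s'", organ))
  clusters <- sort(unique(cells$cluster))
  counts <- table(factor(cells$cluster[lab], levels = clusters))
  p <- as.numeric(counts) / total
  names(p) <- clusters
  if (is.null(cluster)) p else unname(p[as.character(cluster)])
}

#' Per-organ cluster weights for organ position scoring
#'
#' For one cluster, the share `P_organ_cluster` of every organ's
#' single-labelled cells found in that cluster — the weight vector consumed
#' by [organ_position_score()].
#'
#' @param cells Cell table after [classify_cells()].
#' @param cluster Cluster label.
#' @param organs Organs to include; defaults to all with at least one
#'   single-labelled cell.
#' @return Named numeric vector of weights.
#' @export
cluster_organ_weights <- function(cells, cluster, organs = NULL) {
  stop_if(!"upb_category" %in% names(cells), "run classify_cells() first")
  if (is.null(organs)) {
    singles <- cells$upb_organs[cells$upb_category == "single"]
    organs <- intersect(upb_organs(cells), unique(singles))
  }
  vapply(organs, function(o)
    cluster_upb_percentage(cells, o, cluster), numeric(1))
}

#' Fold enrichment of a gene in a cluster
#'
#' Fraction of gene-positive cells in the cluster divided by the overall
#' fraction of gene-positive cells.
#'
#' @param cells Cell table.
#' @param gene Gene with a `marker_<gene>` column.
#' @param cluster Cluster label.
#' @param expr_threshold Positivity cutoff on expression (strict), default 0.
#' @return Nonnegative ratio; 1 means no enrichment.
#' @export
fold_enrichment <- function(cells, gene, cluster, expr_threshold = 0) {
  col <- marker_column(cells, gene)
  pos <- cells[[col]] > expr_threshold
  overall <- mean(pos)
  stop_if(overall == 0, sprintf("no cells positive for '%s'", gene))
  in_cl <- cells$cluster == cluster
  stop_if(!any(in_cl), sprintf("cluster '%s' not found", cluster))
  mean(pos[in_cl]) / overall
}
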