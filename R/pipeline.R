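# End-to-end orchestration: run selected stages in dependency order against
# a single declarative configuration, writing each stage's outputs and a
# manifest with seeds and input digests so a rerun is verifiably identical.

#' Default pipeline configuration
#'
#' All analysis thresholds live here, never hard-coded in the stages: the
#' barcode positivity cutoff (0.8 on processed expression), the QC window
#' (more than 500 and fewer than 8,000 genes per cell, under 10%
#' mitochondrial reads), the responsiveness cutoff (delta-F/F strictly
#' above 1.0), and the enrichment rules (share strictly above 4%, margin of
#' 5 percentage points).
#'
#' @param out_dir Run directory.
#' @param stages Stages to run, in any order; executed in dependency
#'   order. Available: "simulate", "classify", "trajectory", "activity",
#'   "register", "endings", "correlate", "brainstem".
#' @param seed Master seed for the synthetic stage.
#' @param n_cells,n_clusters Synthetic cell-table size.
#' @param upb_threshold Barcode positivity cutoff.
#' @param qc_min_genes,qc_max_genes,qc_max_mito QC thresholds.
#' @param response_threshold Responsiveness cutoff on delta-F/F.
#' @param enrich_threshold,enrich_margin Enrichment rules (percent,
#'   percentage points).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("vagalseq_run_"),
                       stages = c("simulate", "classify", "trajectory"),
                       seed = 1L, n_cells = 2000, n_clusters = 12,
                       upb_threshold = 0.8, qc_min_genes = 500,
                       qc_max_genes = 8000, qc_max_mito = 0.10,
                       response_threshold = 1.0,
                       enrich_threshold = 4, enrich_margin = 5) {
  stop_if(upb_threshold < 0, "upb_threshold must be nonnegative")
  stop_if(qc_min_genes >= qc_max_genes, "QC gene bounds inverted")
  stop_if(!is_fraction(qc_max_mito), "qc_max_mito must lie in [0, 1]")
  known <- c("simulate", "classify", "trajectory", "activity", "register",
             "endings", "correlate", "brainstem")
  bad <- setdiff(stages, known)
  stop_if(length(bad) > 0, paste("unknown stage(s):", paste(bad, collapse = ", ")))
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 n_cells = n_cells, n_clusters = n_clusters,
                 upb_threshold = upb_threshold,
                 qc_min_genes = qc_min_genes, qc_max_genes = qc_max_genes,
                 qc_max_mito = qc_max_mito,
                 response_threshold = response_threshold,
                 enrich_threshold = enrich_threshold,
                 enrich_margin = enrich_margin),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), paste("config file not found:", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the pipeline
#'
#' Executes the selected stages in dependency order, each reading its
#' inputs from and writing its outputs to the run directory, and writes a
#' `manifest.json` recording the package version, seed, stage list and an
#' md5 digest of every output file. Rerunning the same configuration
#' reproduces the digests.
#'
#' Stage outputs (all plain text under `out_dir`):
#' * `simulate` — cell table (matrix-market + metadata), trace set,
#'   landmark scene, ending tables, ground-truth JSON sidecar.
#' * `classify` — QC-filtered, damage-filtered, barcode-labelled cell
#'   table and organ correlation matrix.
#' * `trajectory` — per-cluster organ position and mean trajectory scores
#'   with their regression summary.
#' * `activity` — per-cell response table (responder flag, peak,
#'   activation kinetics).
#' * `register` — transform parameters (JSON) and correspondence table.
#' * `endings` — best assignment and its discrepancy (JSON).
#' * `correlate` — correlation indices for anchor connection patterns.
#' * `brainstem` — percentage-innervation matrix, discrepancy matrix and
#'   newick tree for the synthetic pathways.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return Invisibly, the manifest (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  order_all <- c("simulate", "classify", "trajectory", "activity",
                 "register", "endings", "correlate", "brainstem")
  stages <- order_all[order_all %in% config$stages]
  needs_sim <- setdiff(stages, "simulate")
  if (length(needs_sim) > 0 && !"simulate" %in% stages &&
      !file.exists(file.path(out, "cells.mtx"))) {
    stop("downstream stages need the simulate stage (or its outputs) first",
         call. = FALSE)
  }
  for (stage in stages) {
    switch(stage,
      simulate = stage_simulate(config, out),
      classify = stage_classify(config, out),
      trajectory = stage_trajectory(config, out),
      activity = stage_activity(config, out),
      register = stage_register(config, out),
      endings = stage_endings(config, out),
      correlate = stage_correlate(config, out),
      brainstem = stage_brainstem(config, out))
  }
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "vagalseq",
    version = as.character(utils::packageVersion("vagalseq")),
    seed = config$seed, stages = stages,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config, out) {
  sc <- synth_config(n_cells = config$n_cells,
                     n_clusters = config$n_clusters, seed = config$seed)
  sim <- simulate_cell_table(sc)
  write_cell_table(sim$cells, out)
  ts <- simulate_trace_set(seed = config$seed)
  write_trace_set(ts, out)
  scene <- simulate_landmark_scene(
    rigid_transform(rotation_about_axis(pi / 6), c(20, -10, 5)),
    seed = config$seed)
  write_landmark_scene(scene, out)
  free <- paste0("free", 1:4)
  truth_assign <- setNames(ending_types()[c(1, 3, 4, 2)], free)
  et <- simulate_ending_tables(truth_assign, seed = config$seed)
  write_matrix(et$af, file.path(out, "af.tsv"))
  utils::write.table(et$labels, file.path(out, "cluster_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cell_truth = sim$truth,
         trace_truth = as.list(ts$truth),
         ending_truth = as.list(et$truth),
         ending_fixed = as.list(et$fixed_map)),
    file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_classify <- function(config, out) {
  cells <- read_cell_table(out)
  cells <- qc_filter(cells, config$qc_min_genes, config$qc_max_genes,
                     config$qc_max_mito)
  flags <- flag_damaged(cells)
  cells <- drop_damaged(cells, flags)
  cells <- classify_cells(cells, threshold = config$upb_threshold)
  utils::write.table(cells, file.path(out, "cells_labelled.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- organ_correlation_matrix(cells)
  write_matrix(cm, file.path(out, "organ_correlation.tsv"))
  invisible(NULL)
}

stage_trajectory <- function(config, out) {
  cells <- utils::read.delim(file.path(out, "cells_labelled.tsv"),
                             stringsAsFactors = FALSE)
  clusters <- sort(unique(cells$cluster))
  pos <- vapply(clusters, function(cl)
    organ_position_score(cluster_organ_weights(cells, cl)), numeric(1))
  keep <- !is.na(pos)   # clusters with no single-labelled cells drop out
  clusters <- clusters[keep]
  pos <- pos[keep]
  cent <- t(vapply(clusters, function(cl)
    colMeans(cells[cells$cluster == cl, c("emb_1", "emb_2")]), numeric(2)))
  ord <- order(pos)
  path <- fit_principal_path(cent[ord, , drop = FALSE])
  traj <- trajectory_score(as.matrix(cells[, c("emb_1", "emb_2")]), path)
  mean_traj <- tapply(traj, factor(cells$cluster, levels = clusters), mean)
  fit <- score_position_regression(as.numeric(mean_traj), pos)
  tab <- data.frame(cluster = clusters, organ_position_score = pos,
                    mean_trajectory_score = as.numeric(mean_traj))
  utils::write.table(tab, file.path(out, "trajectory_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fit, file.path(out, "trajectory_regression.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_activity <- function(config, out) {
  ts <- read_trace_set(out)
  rows <- lapply(rownames(ts$traces), function(id) {
    dff <- delta_f_over_f(ts$traces[id, ], ts$onset)
    resp <- is_responsive(dff, ts$window, config$response_threshold)
    if (resp) {
      m <- activation_metrics(dff, ts$window)
      data.frame(cell_id = id, responsive = TRUE, peak = m$peak,
                 peak_frame = m$peak_frame,
                 activation_frame = m$activation_frame,
                 activation_duration = m$activation_duration,
                 censored = m$censored)
    } else {
      data.frame(cell_id = id, responsive = FALSE, peak = NA_real_,
                 peak_frame = NA_integer_, activation_frame = NA_integer_,
                 activation_duration = NA_integer_, censored = NA)
    }
  })
  utils::write.table(do.call(rbind, rows),
                     file.path(out, "responses.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

stage_register <- function(config, out) {
  scene <- read_landmark_scene(out)
  reg <- register_scene(scene)
  utils::write.table(reg$outcomes, file.path(out, "registration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(rotation = reg$transform$rotation,
         translation = reg$transform$translation,
         scale = reg$transform$scale,
         rmsd = attr(reg$transform, "rmsd"),
         registration_rate = registration_rate(reg$outcomes)),
    file.path(out, "transform.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_endings <- function(config, out) {
  af <- read_matrix(file.path(out, "af.tsv"))
  labels <- utils::read.delim(file.path(out, "cluster_labels.tsv"),
                              stringsAsFactors = FALSE,
                              check.names = FALSE)
  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                               simplifyVector = TRUE)
  fixed <- unlist(truth$ending_fixed)
  free <- setdiff(labels$cluster, names(fixed))
  best <- best_assignment(af, labels, free, fixed_map = fixed)
  jsonlite::write_json(
    list(assignment = as.list(best$assignment),
         variance = best$variance, n_evaluated = best$n_evaluated),
    file.path(out, "best_assignment.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_correlate <- function(config, out) {
  one <- connection_map(paste0("a", 1:3), paste0("b", 1:3),
                        cbind(paste0("a", 1:3), paste0("b", 1:3)))
  all_ <- connection_map(paste0("a", 1:3), paste0("b", 1:4),
                         expand.grid(paste0("a", 1:3), paste0("b", 1:4)))
  jsonlite::write_json(
    list(one_to_one = correlation_index(one),
         all_to_all = correlation_index(all_)),
    file.path(out, "correlation_indices.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(NULL)
}

stage_brainstem <- function(config, out) {
  # small synthetic innervation table over three pathways
  set.seed(config$seed)
  grid <- expand.grid(bregma = c(-7.48, -7.76), subnucleus = c("cNTS", "mNTS"),
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(c("lung", "stomach", "colon"), function(p)
    data.frame(pathway = p, grid,
               mean_fluorescence = runif(nrow(grid), 10, 100),
               background_fluorescence = 5, area = runif(nrow(grid), 50, 150))))
  vm <- correlation_variance_matrix(tab)
  write_matrix(vm, file.path(out, "brainstem_variance.tsv"))
  ape::write.tree(linkage_tree(vm), file.path(out, "brainstem_tree.nwk"))
  invisible(NULL)
}
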