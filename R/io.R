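# Reading and writing the pipeline's table formats: matrix-market sparse
# expression + delimited metadata for cell tables, delimited text for
# traces, coordinates and ending tables, JSON for ground truth and
# transforms, newick for trees.

#' Write a cell table as matrix-market expression plus metadata
#'
#' Expression columns (`upb_*`, `marker_*`) go to a sparse matrix-market
#' file (cells x features); the remaining columns go to a tab-delimited
#' metadata table. Feature names are written alongside.
#'
#' @param cells Cell table.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; default "cells".
#' @return Invisibly, the paths written.
#' @export
write_cell_table <- function(cells, dir, prefix = "cells") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_cols <- grep("^(upb|marker)_", names(cells), value = TRUE)
  meta_cols <- setdiff(names(cells), expr_cols)
  mtx <- Matrix::Matrix(as.matrix(cells[, expr_cols, drop = FALSE]),
                        sparse = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_features.tsv",
                                           "_meta.tsv")))
  Matrix::writeMM(mtx, paths[1])
  writeLines(expr_cols, paths[2])
  utils::write.table(cells[, meta_cols, drop = FALSE], paths[3],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a cell table written by [write_cell_table()]
#'
#' @param dir Directory holding the three files.
#' @param prefix File-name prefix; default "cells".
#' @return Cell table data.frame.
#' @export
read_cell_table <- function(dir, prefix = "cells") {
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_features.tsv",
                                           "_meta.tsv")))
  stop_if(!all(file.exists(paths)),
          paste("missing cell table file(s) under", dir))
  expr <- as.matrix(Matrix::readMM(paths[1]))
  features <- readLines(paths[2])
  colnames(expr) <- features
  meta <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  stop_if(nrow(meta) != nrow(expr),
          "metadata and expression matrix disagree on cell count")
  cbind(meta, as.data.frame(expr))
}

#' Write a trace set as delimited text
#'
#' @param trace_set Output of [simulate_trace_set()] (or a compatible
#'   list with `traces`, `onset`, `window`, `frame_interval`).
#' @param dir Output directory.
#' @param prefix File-name prefix; default "traces".
#' @return Invisibly, the paths written.
#' @export
write_trace_set <- function(trace_set, dir, prefix = "traces") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c(".csv", "_stimuli.json")))
  utils::write.table(data.frame(cell_id = rownames(trace_set$traces),
                                trace_set$traces, check.names = FALSE),
                     paths[1], sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(onset = trace_set$onset,
                            window = trace_set$window,
                            frame_interval = trace_set$frame_interval),
                       paths[2], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a trace set written by [write_trace_set()]
#' @param dir Directory holding the files.
#' @param prefix File-name prefix; default "traces".
#' @return List with `traces`, `onset`, `window`, `frame_interval`.
#' @export
read_trace_set <- function(dir, prefix = "traces") {
  paths <- file.path(dir, paste0(prefix, c(".csv", "_stimuli.json")))
  stop_if(!all(file.exists(paths)), paste("missing trace file(s) under", dir))
  tab <- utils::read.delim(paths[1], sep = ",", check.names = FALSE)
  traces <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(traces) <- list(tab[[1]], NULL)
  meta <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  list(traces = traces, onset = meta$onset, window = meta$window,
       frame_interval = meta$frame_interval)
}

#' Write a landmark scene as delimited coordinate tables
#'
#' @param scene A `landmark_scene`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_landmark_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("invivo.csv", "sections.csv",
                            "scene_truth.json"))
  utils::write.table(scene$invivo, paths[1], sep = ",", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scene$section, paths[2], sep = ",", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(rotation = scene$transform$rotation,
                            translation = scene$transform$translation,
                            scale = scene$transform$scale,
                            correspondence = as.list(scene$correspondence)),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a landmark scene written by [write_landmark_scene()]
#' @param dir Directory holding the files.
#' @return A `landmark_scene` (without ground truth unless the sidecar is
#'   present).
#' @export
read_landmark_scene <- function(dir) {
  paths <- file.path(dir, c("invivo.csv", "sections.csv",
                            "scene_truth.json"))
  stop_if(!all(file.exists(paths[1:2])),
          paste("missing coordinate table(s) under", dir))
  invivo <- utils::read.delim(paths[1], sep = ",")
  section <- utils::read.delim(paths[2], sep = ",")
  out <- list(invivo = invivo, section = section)
  if (file.exists(paths[3])) {
    truth <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
    out$transform <- rigid_transform(matrix(unlist(truth$rotation), 3, 3),
                                     truth$translation, truth$scale)
    out$correspondence <- unlist(truth$correspondence)
  }
  structure(out, class = "landmark_scene")
}

#' Write a square matrix as delimited text with row names
#' @param m Matrix with dimnames.
#' @param path Output file.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(data.frame(name = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a matrix written by [write_matrix()]
#' @param path Input file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
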