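# Brainstem innervation profiling: percentage innervation of NTS subnuclei
# per bregma level for each vagal pathway, pairwise profile discrepancy, and
# an average-linkage tree over pathways.

#' Percentage-innervation profile of one pathway
#'
#' For each (bregma level, subnucleus) cell of the measurement grid:
#' background-subtracted fluorescence `FI = max(mean - background, 0)`,
#' total fluorescence `TF = sum(FI * area)` over the whole grid, and
#' percentage innervation `PI = FI * area / TF * 100`. Grid cells with no
#' record for the pathway are treated as no signal (`FI = 0`).
#'
#' @param table data.frame with columns `pathway`, `bregma`, `subnucleus`,
#'   `mean_fluorescence`, `background_fluorescence`, `area` (area > 0).
#' @param pathway Pathway name to profile.
#' @param grid Optional data.frame with columns `bregma`, `subnucleus`
#'   defining the common measurement grid; defaults to all combinations
#'   present in `table` (any pathway), so that profiles of different
#'   pathways are comparable.
#' @return data.frame `bregma`, `subnucleus`, `pi`; `pi` sums to 100.
#' @export
percentage_innervation <- function(table, pathway, grid = NULL) {
  req <- c("pathway", "bregma", "subnucleus", "mean_fluorescence",
           "background_fluorescence", "area")
  stop_if(!all(req %in% names(table)),
          paste("table must have columns:", paste(req, collapse = ", ")))
  stop_if(any(table$area <= 0), "areas must be positive")
  stop_if(any(table$mean_fluorescence < 0 | table$background_fluorescence < 0),
          "fluorescence values must be nonnegative")
  if (is.null(grid)) {
    grid <- unique(table[, c("bregma", "subnucleus")])
    grid <- grid[order(grid$bregma, grid$subnucleus), , drop = FALSE]
  }
  rows <- table[table$pathway == pathway, , drop = FALSE]
  stop_if(nrow(rows) == 0, sprintf("no records for pathway '%s'", pathway))
  key <- function(b, s) paste(format(b, digits = 12), s, sep = "\r")
  fi <- pmax(rows$mean_fluorescence - rows$background_fluorescence, 0)
  sig <- fi * rows$area
  signal <- setNames(sig, key(rows$bregma, rows$subnucleus))
  gk <- key(grid$bregma, grid$subnucleus)
  fia <- ifelse(gk %in% names(signal), signal[gk], 0)
  tf <- sum(fia)
  stop_if(tf <= 0, "total fluorescence is zero; cannot normalise")
  data.frame(bregma = grid$bregma, subnucleus = grid$subnucleus,
             pi = as.numeric(fia) / tf * 100, stringsAsFactors = FALSE)
}

#' Discrepancy between two percentage-innervation profiles
#'
#' Sum over all (bregma, subnucleus) grid cells of the squared difference in
#' percentage innervation. Zero iff the profiles coincide; symmetric in its
#' arguments.
#'
#' @param profile1,profile2 Outputs of [percentage_innervation()] on the
#'   same grid (same rows in the same order).
#' @return Nonnegative scalar.
#' @export
correlation_variance <- function(profile1, profile2) {
  stop_if(nrow(profile1) != nrow(profile2) ||
            !all(profile1$bregma == profile2$bregma) ||
            !all(profile1$subnucleus == profile2$subnucleus),
          "profiles must be on identical (bregma, subnucleus) grids")
  sum((profile1$pi - profile2$pi)^2)
}

#' Pairwise discrepancy matrix over pathways
#'
#' @param table Innervation table (see [percentage_innervation()]).
#' @param pathways Pathways to include; default all in `table`.
#' @return Symmetric matrix of [correlation_variance()] values with zero
#'   diagonal.
#' @export
correlation_variance_matrix <- function(table, pathways = NULL) {
  if (is.null(pathways)) pathways <- unique(table$pathway)
  grid <- unique(table[, c("bregma", "subnucleus")])
  grid <- grid[order(grid$bregma, grid$subnucleus), , drop = FALSE]
  profs <- lapply(pathways, function(p)
    percentage_innervation(table, p, grid = grid))
  n <- length(pathways)
  m <- matrix(0, n, n, dimnames = list(pathways, pathways))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    m[i, j] <- m[j, i] <- correlation_variance(profs[[i]], profs[[j]])
  }
  m
}

#' Average-linkage tree over pathways
#'
#' Builds a UPGMA (agglomerative average-linkage) tree from a symmetric
#' discrepancy matrix, as produced by [correlation_variance_matrix()].
#' Tip-to-node heights are half the linkage distances, so two pathways at
#' distance d join at height d/2.
#'
#' @param variance_matrix Square symmetric nonnegative matrix with zero
#'   diagonal and row/column names.
#' @param method Agglomeration method passed to [stats::hclust()];
#'   default "average" (UPGMA).
#' @return An [ape::as.phylo()] tree ("phylo" object); serialise with
#'   [ape::write.tree()].
#' @export
linkage_tree <- function(variance_matrix, method = "average") {
  m <- as.matrix(variance_matrix)
  stop_if(nrow(m) != ncol(m), "matrix must be square")
  stop_if(max(abs(m - t(m))) > 1e-8, "matrix must be symmetric")
  stop_if(any(diag(m) != 0), "diagonal must be zero")
  stop_if(any(m < 0), "distances must be nonnegative")
  stop_if(is.null(rownames(m)), "matrix must have row names")
  hc <- stats::hclust(stats::as.dist(m), method = method)
  ape::as.phylo(hc)
}
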