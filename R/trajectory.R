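# Trajectory scoring: organ-position scores, arc-length projection onto a
# polyline in embedding space, tissue-layer indices, and their linear
# relationship.

#' Normalised rostro-caudal positions of the visceral organs
#'
#' Mean distance from the vagal ganglia to each organ, normalised to body
#' length (neck to rectum), as a fraction in \[0, 1\]. These are the default
#' `Position_organ` values used by [organ_position_score()] and by the
#' synthetic-data generators.
#'
#' @return Named numeric vector of positions.
#' @export
organ_positions <- function() {
  c(lung = 0.241, heart = 0.280, oesophagus = 0.228, stomach = 0.469,
    duodenum = 0.567, colon = 0.589, pancreas = 0.545)
}

#' Organ position score of a cluster
#'
#' Weighted average of organ positions with the cluster's share of each
#' organ's barcode-labelled cells as weights:
#' `sum(P_organ_cluster * Position_organ) / sum(P_organ_cluster)`.
#' A cluster containing only lung-labelled cells scores the lung position.
#'
#' @param upb_percentages Named numeric vector: for each organ, the fraction
#'   of that organ's single-barcode cells that fall in this cluster
#'   (see [cluster_upb_percentage()]).
#' @param positions Named numeric vector of organ positions in \[0, 1\];
#'   default [organ_positions()]. Names must cover `upb_percentages`.
#' @return Score in \[0, 1\], or `NA_real_` when all weights are zero.
#' @export
#' @examples
#' organ_position_score(c(lung = 1))              # 0.241
#' organ_position_score(c(lung = 0.5, stomach = 0.5))  # 0.355
organ_position_score <- function(upb_percentages, positions = organ_positions()) {
  stop_if(is.null(names(upb_percentages)) || any(names(upb_percentages) == ""),
          "upb_percentages must be a named vector")
  missing <- setdiff(names(upb_percentages), names(positions))
  stop_if(length(missing) > 0,
          paste("no position for organ(s):", paste(missing, collapse = ", ")))
  stop_if(any(upb_percentages < 0), "weights must be nonnegative")
  w <- upb_percentages
  if (sum(w) == 0) return(NA_real_)
  sum(w * positions[names(w)]) / sum(w)
}

#' Polyline trajectory through ordered cluster centroids
#'
#' Represents a genetic trajectory on a 2-D embedding as a polyline through
#' cluster centroids in a caller-declared order, with cumulative arc length.
#'
#' @param centroids Numeric matrix (or data.frame) with 2 columns, one row
#'   per centroid, in path order; at least 2 rows, no duplicate consecutive
#'   rows.
#' @return An `embedding_path`: list with `vertices` (n x 2 matrix) and
#'   `cumulative_length` (length n, starting at 0, strictly increasing).
#' @export
fit_principal_path <- function(centroids) {
  v <- as.matrix(centroids)
  stop_if(ncol(v) != 2, "centroids must have 2 columns")
  stop_if(nrow(v) < 2, "need at least 2 centroids")
  stop_if(any(!is.finite(v)), "centroids must be finite")
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  stop_if(any(seg == 0), "duplicate consecutive centroids")
  structure(list(vertices = unname(v),
                 cumulative_length = c(0, cumsum(seg))),
            class = "embedding_path")
}

#' @export
print.embedding_path <- function(x, ...) {
  cat(sprintf("embedding_path: %d vertices, total length %.4g\n",
              nrow(x$vertices), max(x$cumulative_length)))
  invisible(x)
}

#' Normalised arc-length position of a point along a trajectory
#'
#' Orthogonally projects the point onto every segment of the path (clamped
#' to segment endpoints), takes the globally nearest projection, and returns
#' its cumulative arc length divided by the total path length. Ties between
#' equidistant segments resolve to the smaller arc length.
#'
#' @param point Numeric length-2 vector, or an n x 2 matrix of points.
#' @param path An `embedding_path` from [fit_principal_path()].
#' @return Score(s) in \[0, 1\]: 0 at the first vertex, 1 at the last.
#' @export
trajectory_score <- function(point, path) {
  stopifnot(inherits(path, "embedding_path"))
  v <- path$vertices
  cl <- path$cumulative_length
  total <- cl[length(cl)]
  stop_if(total <= 0, "degenerate zero-length path")
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  stop_if(ncol(pts) != 2, "points must be 2-D")
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  scores <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    # clamped projection parameter on each segment
    t <- pmin(1, pmax(0, ((p[1] - a[, 1]) * d[, 1] + (p[2] - a[, 2]) * d[, 2]) / len2))
    px <- a[, 1] + t * d[, 1]
    py <- a[, 2] + t * d[, 2]
    dist2 <- (p[1] - px)^2 + (p[2] - py)^2
    arc <- cl[-length(cl)] + t * sqrt(len2)
    best <- which(dist2 == min(dist2))
    min(arc[best]) / total
  }, numeric(1))
  if (is.matrix(point)) scores else scores[[1]]
}

#' Tissue layer index map
#'
#' Inner-to-outer index scores for gut tissue layers: mucosa (or inner
#' epithelium) 0, muscle 1, connective tissue 2.
#'
#' @return Named numeric vector.
#' @export
layer_index_map <- function() {
  c(mucosa = 0, muscle = 1, connective = 2)
}

#' Tissue layer index from ending counts
#'
#' Count-weighted mean of layer index scores:
#' `sum((endings in layer / total endings) * index_layer)`. Lies between the
#' smallest and largest index present; equals a layer's index when all
#' endings fall in that layer.
#'
#' @param ending_counts Named numeric vector of nonnegative ending counts
#'   per tissue layer.
#' @param index_map Named numeric vector of layer indices; default
#'   [layer_index_map()].
#' @return Weighted-mean index score.
#' @export
#' @examples
#' tissue_layer_index(c(mucosa = 5, connective = 5))  # 1
tissue_layer_index <- function(ending_counts, index_map = layer_index_map()) {
  stop_if(is.null(names(ending_counts)), "ending_counts must be named")
  missing <- setdiff(names(ending_counts), names(index_map))
  stop_if(length(missing) > 0,
          paste("no index for layer(s):", paste(missing, collapse = ", ")))
  stop_if(any(ending_counts < 0), "counts must be nonnegative")
  total <- sum(ending_counts)
  stop_if(total == 0, "zero total endings")
  sum(ending_counts / total * index_map[names(ending_counts)])
}

#' Ordinary least-squares fit between scores and positions
#'
#' Plain linear regression of `y` on `x` with the coefficient of
#' determination, used to relate trajectory scores to anatomical positions
#' or layer indices.
#'
#' @param x,y Paired numeric vectors, at least 3 complete pairs, `x` not
#'   constant.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
score_position_regression <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  stop_if(length(x) < 3, "need at least 3 paired points")
  stop_if(stats::var(x) == 0, "x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = r2,
       n = length(x))
}
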