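# Bipartite correlation index between two sets of categorical characteristics
# (e.g. visceral organs vs ending types), computed from the pattern of
# observed connections.

#' Build a bipartite connection map
#'
#' A connection map records which variables of one characteristic (side 1)
#' were observed connected to which variables of a second characteristic
#' (side 2), e.g. which visceral organs are innervated by which ending types.
#'
#' @param side1,side2 Character vectors of variable names for each side.
#' @param edges Two-column data.frame (or matrix) of connections; first
#'   column refers to side-1 variables, second to side-2 variables.
#' @return An object of class `connection_map` with elements `side1`,
#'   `side2` and `edges` (deduplicated).
#' @seealso [correlation_index()]
#' @export
#' @examples
#' connection_map(c("a1", "a2"), c("b1", "b2"),
#'                data.frame(v1 = c("a1", "a2"), v2 = c("b1", "b2")))
connection_map <- function(side1, side2, edges) {
  stop_if(!is.character(side1) || !is.character(side2),
          "side1 and side2 must be character vectors")
  stop_if(anyDuplicated(side1) > 0 || anyDuplicated(side2) > 0,
          "variable names must be unique within a side")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stop_if(ncol(edges) < 2, "edges must have two columns")
  edges <- edges[, 1:2]
  names(edges) <- c("v1", "v2")
  edges$v1 <- as.character(edges$v1)
  edges$v2 <- as.character(edges$v2)
  bad <- !(edges$v1 %in% side1) | !(edges$v2 %in% side2)
  stop_if(any(bad), "edges reference undeclared variables")
  edges <- unique(edges)
  structure(list(side1 = side1, side2 = side2, edges = edges),
            class = "connection_map")
}

#' @export
print.connection_map <- function(x, ...) {
  cat(sprintf("connection_map: %d x %d variables, %d connections\n",
              length(x$side1), length(x$side2), nrow(x$edges)))
  invisible(x)
}

#' Drop variables with no connections
#'
#' Variables on either side that take part in no connection are removed
#' before the index is computed; they carry no information about the pairing
#' structure.
#'
#' @param map A [connection_map()].
#' @return A pruned `connection_map`. Pruning is idempotent.
#' @export
prune_unconnected <- function(map) {
  stopifnot(inherits(map, "connection_map"))
  s1 <- intersect(map$side1, map$edges$v1)
  s2 <- intersect(map$side2, map$edges$v2)
  stop_if(length(s1) == 0 || length(s2) == 0,
          "all variables are unconnected; nothing to analyse")
  connection_map(s1, s2, map$edges)
}

#' Normalised number of connections
#'
#' Scales the observed connection count between the one-to-one minimum and
#' the all-to-all maximum: `C = (n_conn - min) / (max - min)` where, after
#' pruning, every retained variable has at least one connection, so the
#' minimum possible count is `max(n1, n2)` and the maximum is `n1 * n2`.
#'
#' @param map A pruned [connection_map()].
#' @return `C` in `[0, 1]`; a degenerate map where max equals min returns 0.
#' @export
normalized_connections <- function(map) {
  map <- prune_unconnected(map)
  n1 <- length(map$side1)
  n2 <- length(map$side2)
  n_conn <- nrow(map$edges)
  cmin <- max(n1, n2)
  cmax <- n1 * n2
  if (cmax == cmin) return(0)
  (n_conn - cmin) / (cmax - cmin)
}

#' Variance of per-variable connection counts
#'
#' Population variance (divide by n) of the number of connections incident
#' to each variable on one side of the map. An even spread of connections
#' (as in one-to-one or all-to-all patterns) gives zero variance.
#'
#' @param map A pruned [connection_map()].
#' @param side 1 or 2.
#' @return Nonnegative scalar.
#' @export
connection_variance <- function(map, side = 1) {
  map <- prune_unconnected(map)
  stop_if(!side %in% c(1, 2), "side must be 1 or 2")
  vars <- if (side == 1) map$side1 else map$side2
  col <- if (side == 1) map$edges$v1 else map$edges$v2
  counts <- as.numeric(table(factor(col, levels = vars)))
  mean((counts - mean(counts))^2)
}

#' Correlation index between two characteristics
#'
#' Quantifies how tightly two categorical characteristics are paired, from
#' the bipartite map of their observed connections. Two ingredients: the
#' normalised connection count `C` ([normalized_connections()]) and the
#' per-side connection-count variances `v1`, `v2`
#' ([connection_variance()]). The index is
#' \deqn{(1 - C) / ((v_1 + 1)(v_2 + 1))}
#' A one-to-one pattern scores exactly 1 (perfect correlation); an
#' all-to-all pattern scores exactly 0 (no correlation). With equal
#' connection counts, more evenly distributed connections score higher.
#'
#' @param map A [connection_map()]; pruned automatically.
#' @return A list with `index`, `C`, `v1`, `v2`, `n1`, `n2`, `n_connections`.
#' @export
#' @examples
#' m <- connection_map(c("a1", "a2", "a3"), c("b1", "b2", "b3"),
#'                     cbind(paste0("a", 1:3), paste0("b", 1:3)))
#' correlation_index(m)$index  # exactly 1
correlation_index <- function(map) {
  map <- prune_unconnected(map)
  C <- normalized_connections(map)
  v1 <- connection_variance(map, 1)
  v2 <- connection_variance(map, 2)
  list(index = (1 - C) / ((v1 + 1) * (v2 + 1)),
       C = C, v1 = v1, v2 = v2,
       n1 = length(map$side1), n2 = length(map$side2),
       n_connections = nrow(map$edges))
}

#' Read a connection map from an edge-list file
#'
#' @param path Delimited text file with two columns (side-1 variable,
#'   side-2 variable), with header.
#' @param sep Field separator, default tab.
#' @return A [connection_map()] whose sides are the distinct names seen.
#' @export
read_connection_map <- function(path, sep = "\t") {
  edges <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stop_if(nrow(edges) == 0, "edge list is empty")
  connection_map(unique(as.character(edges[[1]])),
                 unique(as.character(edges[[2]])), edges)
}
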