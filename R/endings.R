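# Sensory ending annotation: innervation intensities, anatomical (AF) and
# projection-barcode-derived (SF) fold changes over stomach regions, the
# exhaustive cluster-to-ending-type assignment search, and enriched-cluster
# identification.
#
# Conventions:
#   * ending types (fixed order):  ME < pIMA < cIMA < IGLE
#   * stomach regions compared:    4, 6, 7, 8
#   * ME/pIMA/cIMA are measured by area covered, IGLE by terminal count;
#     both become an intensity after division by sample area.

#' Ending types, in canonical order
#' @export
ending_types <- function() c("ME", "pIMA", "cIMA", "IGLE")

#' Stomach regions used for fold-change comparison
#' @export
stomach_regions <- function() c("4", "6", "7", "8")

#' Innervation intensity from ending measurements
#'
#' Measure (area covered for ME/IMA-type endings, terminal count for
#' IGLE-type endings) divided by the total sample area.
#'
#' @param measure Nonnegative measurement(s).
#' @param total_area Positive total sample area(s).
#' @return Intensity, same length as `measure`.
#' @export
innervation_intensity <- function(measure, total_area) {
  stop_if(any(total_area <= 0), "total area must be positive")
  stop_if(any(measure < 0), "measures must be nonnegative")
  measure / total_area
}

#' Anatomical fold change (AF) per ending type and region
#'
#' Region-level innervation intensity of an ending type divided by its
#' whole-organ intensity (reference genotype). A uniformly innervating
#' type has AF = 1 in every region.
#'
#' @param intensity Matrix of intensities, rows = ending types, columns =
#'   regions (dimnames required).
#' @param whole Named vector of whole-organ intensities per ending type;
#'   types with zero whole-organ intensity get `NA` rows.
#' @return AF matrix, same shape as `intensity`.
#' @export
anatomical_fold_change <- function(intensity, whole) {
  intensity <- as.matrix(intensity)
  stop_if(is.null(rownames(intensity)), "intensity needs ending-type rownames")
  stop_if(!all(rownames(intensity) %in% names(whole)),
          "whole-organ intensity missing for some ending type")
  w <- whole[rownames(intensity)]
  sweep(intensity, 1, ifelse(w > 0, w, NA_real_), `/`)
}

#' Projection-derived fold change (SF) under a cluster assignment
#'
#' For each ending type and stomach region, the ratio of summed
#' dual-labelled percentages to summed stomach-single-labelled percentages
#' over all clusters assigned to that type (a ratio of sums, not a sum of
#' ratios):
#' `SF(type, region) = sum(dual[clusters of type, region]) /
#'                     sum(single[clusters of type])`.
#'
#' @param assignment Named character vector cluster -> ending type,
#'   covering both pre-annotated and free clusters.
#' @param labels Cluster label table: data.frame with `cluster`, `single`
#'   (percentage of stomach single-labelled cells) and one `dual_<region>`
#'   column per region.
#' @param regions Region names; default [stomach_regions()].
#' @param types Ending types; default [ending_types()].
#' @return SF matrix (types x regions); a type whose assigned clusters sum
#'   to zero single percentage, or with no assigned cluster, gets `NA`.
#' @export
projection_fold_change <- function(assignment, labels,
                                   regions = stomach_regions(),
                                   types = ending_types()) {
  stop_if(is.null(names(assignment)), "assignment must be named by cluster")
  stop_if(!all(assignment %in% types), "assignment uses unknown ending type")
  stop_if(!all(names(assignment) %in% labels$cluster),
          "assignment names unknown cluster")
  dual_cols <- paste0("dual_", regions)
  stop_if(!all(c("cluster", "single", dual_cols) %in% names(labels)),
          "labels must have cluster, single and dual_<region> columns")
  sf <- matrix(NA_real_, length(types), length(regions),
               dimnames = list(types, regions))
  idx <- match(names(assignment), labels$cluster)
  for (ty in types) {
    rows <- idx[assignment == ty]
    if (length(rows) == 0) next
    den <- sum(labels$single[rows])
    if (den <= 0) next
    sf[ty, ] <- colSums(labels[rows, dual_cols, drop = FALSE]) / den
  }
  sf
}

#' Discrepancy between projection-derived and anatomical fold changes
#'
#' Objective of the assignment search: the sum over all ending types and
#' regions of squared differences `(SF - AF)^2`. Invariant to the
#' iteration order over the grid.
#'
#' @param assignment Named cluster -> type vector (fixed plus free).
#' @param af AF matrix (types x regions), see [anatomical_fold_change()].
#' @param labels Cluster label table, see [projection_fold_change()].
#' @return Nonnegative scalar; `NA` entries in either grid propagate.
#' @export
assignment_variance <- function(assignment, af, labels) {
  types <- rownames(af); regions <- colnames(af)
  sf <- projection_fold_change(assignment, labels, regions = regions,
                               types = types)
  total <- 0
  for (ty in types) for (rg in regions) {
    total <- total + (sf[ty, rg] - af[ty, rg])^2
  }
  total
}

#' Enumerate all cluster-to-type assignments
#'
#' All `m^k` ways of assigning `k` free clusters independently to `m`
#' ending types, in deterministic lexicographic order: the first cluster
#' varies slowest, types cycle in their canonical order. Seven free
#' clusters and four types give 16,384 assignments.
#'
#' @param free_clusters Character vector of free cluster names (k).
#' @param types Ending types (m); default [ending_types()].
#' @return Character matrix, `m^k` rows x `k` columns (columns named by
#'   cluster); `k = 0` yields a single empty assignment.
#' @export
enumerate_assignments <- function(free_clusters, types = ending_types()) {
  k <- length(free_clusters)
  m <- length(types)
  stop_if(m < 1, "need at least one ending type")
  if (k == 0) {
    return(matrix(character(0), nrow = 1, ncol = 0))
  }
  # odometer with the last cluster fastest
  grid <- rev(expand.grid(rev(replicate(k, types, simplify = FALSE)),
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  out <- as.matrix(grid)
  dimnames(out) <- list(NULL, free_clusters)
  out
}

#' Best cluster-to-ending-type assignment by exhaustive search
#'
#' Evaluates the discrepancy objective ([assignment_variance()]) for every
#' enumerated assignment of the free clusters (pre-annotated clusters are
#' held fixed) and returns the minimiser. Ties resolve deterministically
#' to the lexicographically first assignment (cluster order as given,
#' type order ME < pIMA < cIMA < IGLE). The evaluation is vectorised
#' across assignments but agrees exactly with per-assignment recomputation.
#'
#' @param af AF matrix (types x regions).
#' @param labels Cluster label table (see [projection_fold_change()]).
#' @param free_clusters Free cluster names.
#' @param fixed_map Named cluster -> type vector for pre-annotated
#'   clusters (may be empty).
#' @param types Ending types; default the AF rownames.
#' @return List: `assignment` (full named map, fixed + free), `variance`,
#'   `free` (the free part), and `n_evaluated`.
#' @export
best_assignment <- function(af, labels, free_clusters,
                            fixed_map = character(0),
                            types = rownames(af)) {
  regions <- colnames(af)
  enum <- enumerate_assignments(free_clusters, types)
  n <- nrow(enum)
  dual_cols <- paste0("dual_", regions)
  li <- match(c(names(fixed_map), free_clusters), labels$cluster)
  stop_if(anyNA(li), "assignment names unknown cluster")
  fixed_idx <- match(names(fixed_map), labels$cluster)
  free_idx <- match(free_clusters, labels$cluster)
  dual <- as.matrix(labels[, dual_cols, drop = FALSE])   # clusters x regions
  single <- labels$single
  variance <- numeric(n)
  # per-type fixed contributions
  for (ty in types) {
    fx <- fixed_idx[fixed_map == ty]
    num_fixed <- if (length(fx)) colSums(dual[fx, , drop = FALSE]) else
      rep(0, length(regions))
    den_fixed <- sum(single[fx])
    ind <- (enum == ty) * 1                               # n x k
    num <- ind %*% dual[free_idx, , drop = FALSE]         # n x regions
    num <- sweep(num, 2, num_fixed, `+`)
    den <- as.numeric(ind %*% single[free_idx]) + den_fixed
    sf <- num / den                                       # NaN/Inf if den 0
    sf[den == 0, ] <- NA_real_
    diff2 <- sweep(sf, 2, af[ty, ], `-`)^2
    variance <- variance + rowSums(diff2)
  }
  best <- which(variance == min(variance, na.rm = TRUE))[1]
  free_part <- setNames(enum[best, ], free_clusters)
  full <- c(fixed_map, free_part)
  list(assignment = full, variance = variance[best],
       free = free_part, n_evaluated = n)
}

#' Identify clusters enriched for an organ or region
#'
#' Three rules, matching how primary and region-enriched clusters are
#' defined from barcode percentages:
#' * `mode = "single"`: clusters with a single-barcode share strictly above
#'   `primary_threshold` (default 4%).
#' * `mode = "dual"` (sphincter/region clusters): dual share strictly above
#'   `primary_threshold` AND at least `margin` percentage points (default 5)
#'   above both single-organ shares.
#' * `mode = "region5"` (stomach fundus): stomach single share strictly
#'   above `primary_threshold` AND at least `margin` points above each of
#'   the four dual shares.
#'
#' @param shares data.frame with a `cluster` column plus, depending on
#'   mode: `single` (mode "single"); `dual`, `single_1`, `single_2`
#'   (mode "dual"); `single`, `dual_1` .. `dual_4` (mode "region5").
#'   All values are percentages in \[0, 100\].
#' @param mode One of "single", "dual", "region5".
#' @param primary_threshold Percentage threshold, strict; default 4.
#' @param margin Percentage-point margin (inclusive); default 5.
#' @return Character vector of enriched cluster names.
#' @export
identify_enriched_clusters <- function(shares,
                                       mode = c("single", "dual", "region5"),
                                       primary_threshold = 4, margin = 5) {
  mode <- match.arg(mode)
  hit <- switch(mode,
    single = shares$single > primary_threshold,
    dual = shares$dual > primary_threshold &
      shares$dual >= shares$single_1 + margin &
      shares$dual >= shares$single_2 + margin,
    region5 = {
      duals <- as.matrix(shares[, grep("^dual_", names(shares)),
                                drop = FALSE])
      shares$single > primary_threshold &
        apply(shares$single >= duals + margin, 1, all)
    })
  shares$cluster[hit]
}

#' Innervation normalised to a reference genotype
#'
#' Intensity of an ending type in a Cre-driver line divided by its
#' intensity in the pan-neuronal reference.
#'
#' @param cre_intensity Nonnegative intensity in the Cre line.
#' @param reference_intensity Positive reference intensity.
#' @return Nonnegative ratio.
#' @export
normalized_innervation <- function(cre_intensity, reference_intensity) {
  stop_if(any(reference_intensity <= 0), "reference intensity must be positive")
  stop_if(any(cre_intensity < 0), "intensity must be nonnegative")
  cre_intensity / reference_intensity
}
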