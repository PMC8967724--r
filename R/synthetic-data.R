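# Synthetic-data generators. Every pipeline input can be fabricated with
# known ground truth: barcode expression around the detection threshold,
# cluster-structured embeddings spanning an organ axis and a tissue-layer
# axis, damaged-cell clusters, archetypal calcium responses, rigid-transform
# landmark scenes, and ending tables consistent with a chosen
# cluster-to-ending-type assignment.
#
# All randomness flows from one integer seed: each generator derives
# independent substreams deterministically, so a multi-table scene is
# reproducible end to end.

#' Default organ adjacency weights
#'
#' Symmetric organ-pair weights in \[0, 1\] governing the probability that a
#' dual-labelled cell is generated for a pair. Nonzero weights are assigned
#' only to physically adjacent organs (thoracic neighbours, and the stomach
#' with the organs bordering its regions), reflecting that dual barcode
#' labels arise from endings near organ boundaries rather than at random.
#'
#' @param organs Organ names; default `names(organ_positions())`.
#' @return Symmetric matrix with zero diagonal.
#' @export
default_adjacency <- function(organs = names(organ_positions())) {
  m <- matrix(0, length(organs), length(organs),
              dimnames = list(organs, organs))
  link <- function(a, b, w) {
    if (a %in% organs && b %in% organs) {
      m[a, b] <<- w; m[b, a] <<- w
    }
  }
  link("lung", "heart", 0.5)
  link("lung", "oesophagus", 0.3)
  link("heart", "oesophagus", 0.3)
  link("oesophagus", "stomach", 0.6)
  link("stomach", "duodenum", 0.6)
  link("stomach", "pancreas", 0.4)
  link("stomach", "colon", 0.4)
  link("duodenum", "pancreas", 0.4)
  link("duodenum", "colon", 0.3)
  m
}

#' Configuration for the synthetic-data generators
#'
#' @param n_cells Number of cells to simulate.
#' @param n_clusters Number of non-damaged clusters.
#' @param organs Named numeric vector: organ -> position (fraction of body
#'   length in \[0, 1\]); default [organ_positions()].
#' @param adjacency Symmetric organ-pair weight matrix in \[0, 1\] with
#'   zero diagonal; default [default_adjacency()].
#' @param upb_noise_sd Barcode expression noise (processed-expression
#'   units); 0 gives perfectly separable barcode calls.
#' @param dual_fraction Overall fraction of labelled cells that carry two
#'   barcodes (split over pairs proportional to adjacency); default 0.16.
#' @param damage_fraction Fraction of cells placed in the damaged cluster;
#'   default 0.10.
#' @param seed Integer master seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_cells = 2000, n_clusters = 12,
                         organs = organ_positions(),
                         adjacency = default_adjacency(names(organs)),
                         upb_noise_sd = 0.1, dual_fraction = 0.16,
                         damage_fraction = 0.10, seed = 1L) {
  stop_if(!is_count(n_cells) || n_cells <= 0, "n_cells must be positive")
  stop_if(!is_count(n_clusters) || n_clusters <= 0,
          "n_clusters must be positive")
  stop_if(length(organs) == 0, "empty organ list")
  stop_if(is.null(names(organs)), "organs must be a named position vector")
  stop_if(any(organs < 0 | organs > 1), "organ positions must lie in [0, 1]")
  adjacency <- as.matrix(adjacency)
  stop_if(!all(dim(adjacency) == length(organs)),
          "adjacency must be square over the organ set")
  stop_if(max(abs(adjacency - t(adjacency))) > 0,
          "adjacency must be symmetric")
  stop_if(any(diag(adjacency) != 0), "adjacency diagonal must be zero")
  stop_if(any(adjacency < 0 | adjacency > 1),
          "adjacency weights must lie in [0, 1]")
  stop_if(upb_noise_sd < 0, "upb_noise_sd must be nonnegative")
  stop_if(!is_fraction(dual_fraction), "dual_fraction must lie in [0, 1]")
  stop_if(!is_fraction(damage_fraction), "damage_fraction must lie in [0, 1]")
  structure(list(n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 organs = organs, adjacency = adjacency,
                 upb_noise_sd = upb_noise_sd,
                 dual_fraction = dual_fraction,
                 damage_fraction = damage_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# derive an independent substream seed from the master seed (kept < 2^31)
substream <- function(seed, stream) {
  (as.numeric(seed) * 1103L + stream * 12347) %% 2147483647
}

#' Simulate a per-cell table with ground truth
#'
#' Cells are assigned a true organ (or adjacent organ pair, with pair
#' probability proportional to the adjacency weight), a cluster, an
#' embedding position and QC metrics:
#'
#' * Barcode expression for the true organ(s) is drawn above the 0.8
#'   detection threshold (1.5 plus half-normal noise, truncated just above
#'   the threshold); all other barcodes get half-normal noise near zero.
#'   At `upb_noise_sd = 0` calls are exactly separable.
#' * Clusters are laid out on two orthogonal latent axes: the x axis orders
#'   clusters by the body position of their dominant organ, the y axis by a
#'   tissue-layer index cycling through mucosa/muscle/connective.
#' * A `damage_fraction` of cells forms a dedicated extra cluster with
#'   strongly elevated damage-marker expression (Sprr1a, Ecel1).
#' * `n_genes` is drawn inside the usual QC window with a small contaminant
#'   tail outside it; mitochondrial fractions likewise.
#'
#' @param config A [synth_config()].
#' @return List with `cells` (cell table, see [classify_cells()]) and
#'   `truth` (per-cell true organs, per-cluster organ/layer, damage
#'   cluster name).
#' @export
simulate_cell_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream(config$seed, 1))
  n <- config$n_cells
  organs <- names(config$organs)
  n_org <- length(organs)

  # damaged cells live in their own cluster
  damaged <- runif(n) < config$damage_fraction
  damage_cluster <- "E1"

  # true labels: single organ, or an adjacent pair for dual cells
  pair_w <- config$adjacency[upper.tri(config$adjacency)]
  pairs_idx <- which(upper.tri(config$adjacency), arr.ind = TRUE)
  can_dual <- sum(pair_w) > 0
  is_dual <- !damaged & can_dual & runif(n) < config$dual_fraction
  true_organs <- vector("list", n)
  single_pick <- sample(organs, n, replace = TRUE)
  if (any(is_dual)) {
    pick <- sample(nrow(pairs_idx), sum(is_dual), replace = TRUE,
                   prob = pair_w)
    true_organs[is_dual] <- lapply(pick, function(k)
      sort(c(organs[pairs_idx[k, 1]], organs[pairs_idx[k, 2]])))
  }
  true_organs[!is_dual] <- as.list(single_pick[!is_dual])

  # clusters: each non-damaged cluster has a dominant organ and a layer
  k <- config$n_clusters
  cl_names <- paste0("C", seq_len(k))
  cl_organ <- organs[1 + (seq_len(k) - 1) %% n_org]
  cl_layer <- names(layer_index_map())[1 + (seq_len(k) - 1) %/% n_org %%
                                         length(layer_index_map())]
  # cells join a cluster whose dominant organ is (one of) their true organ(s)
  cluster <- character(n)
  for (i in seq_len(n)) {
    if (damaged[i]) { cluster[i] <- damage_cluster; next }
    cand <- which(cl_organ %in% true_organs[[i]])
    if (length(cand) == 0) cand <- seq_len(k)
    cluster[i] <- cl_names[cand[sample.int(length(cand), 1)]]
  }

  # embedding: organ position on x, layer index on y, cluster-local scatter
  cl_pos <- config$organs[cl_organ]
  cl_y <- layer_index_map()[cl_layer]
  centx <- c(setNames(cl_pos * 10, cl_names),
             setNames(5, damage_cluster))
  centy <- c(setNames(as.numeric(cl_y), cl_names),
             setNames(-2, damage_cluster))
  emb_1 <- centx[cluster] + rnorm(n, 0, 0.08)
  emb_2 <- centy[cluster] + rnorm(n, 0, 0.08)

  # barcode expression around the 0.8 threshold
  upb <- matrix(0, n, n_org, dimnames = list(NULL, organs))
  noise <- config$upb_noise_sd
  for (i in seq_len(n)) {
    pos <- true_organs[[i]]
    upb[i, pos] <- 1.5 + abs(rnorm(length(pos), 0, noise))
    neg <- setdiff(organs, pos)
    upb[i, neg] <- abs(rnorm(length(neg), 0, noise))
  }

  # damage markers: high in the damage cluster, near zero elsewhere
  sprr1a <- ifelse(damaged, 5 + abs(rnorm(n, 0, 0.5)),
                   abs(rnorm(n, 0, 0.05)))
  ecel1 <- ifelse(damaged, 4 + abs(rnorm(n, 0, 0.5)),
                  abs(rnorm(n, 0, 0.05)))

  # QC metrics with a contaminant tail
  contaminant <- runif(n) < 0.05
  n_genes <- ifelse(contaminant,
                    sample(c(100, 9000), n, replace = TRUE),
                    round(runif(n, 1500, 6000)))
  mito <- ifelse(runif(n) < 0.03, runif(n, 0.12, 0.4), runif(n, 0, 0.08))

  cells <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                      cluster = cluster, emb_1 = emb_1, emb_2 = emb_2,
                      n_genes = n_genes, mito_fraction = mito,
                      stringsAsFactors = FALSE)
  for (o in organs) cells[[paste0("upb_", o)]] <- upb[, o]
  cells$marker_Sprr1a <- sprr1a
  cells$marker_Ecel1 <- ecel1

  truth <- list(
    organs = vapply(true_organs, paste, character(1), collapse = "+"),
    is_dual = is_dual, damaged = damaged,
    damage_cluster = damage_cluster,
    cluster_organ = setNames(cl_organ, cl_names),
    cluster_layer = setNames(cl_layer, cl_names))
  list(cells = cells, truth = truth)
}

#' Simulate a set of calcium traces with known response archetypes
#'
#' Traces are raw GCaMP-like fluorescence around a baseline of 100 a.u.
#' with a stimulus window and one of four archetypes:
#' * `sustained` — plateau at `amplitude` (in delta-F/F units) for the
#'   whole stimulus window;
#' * `transient` — short pulse of `transient_frames` frames at `amplitude`
#'   starting at onset;
#' * `polymodal` — sustained response in the stimulus window plus a second
#'   response after it;
#' * `non_responder` — flat at baseline.
#'
#' Gaussian noise of standard deviation `noise_sd` (delta-F/F units) is
#' added per frame. Frame interval is 1.72 s.
#'
#' @param n_traces Number of cells.
#' @param archetypes Archetype per cell, recycled; default all four.
#' @param n_frames Trace length; default 200.
#' @param onset Stimulus onset frame; default 60 (>= 21 so the baseline
#'   window exists).
#' @param window_frames Stimulus window length; default 30.
#' @param amplitude Peak delta-F/F of responders; default 2.
#' @param transient_frames Pulse length of transient cells; default 5.
#' @param noise_sd Noise standard deviation (delta-F/F units); default 0.02.
#' @param baseline Baseline fluorescence (a.u.); default 100.
#' @param seed Integer seed.
#' @return List: `traces` (cells x frames matrix), `onset`, `window`
#'   (frame indices), `frame_interval`, `truth` (archetype per cell).
#' @export
simulate_trace_set <- function(n_traces = 100,
                               archetypes = c("sustained", "transient",
                                              "polymodal", "non_responder"),
                               n_frames = 200, onset = 60,
                               window_frames = 30, amplitude = 2,
                               transient_frames = 5, noise_sd = 0.02,
                               baseline = 100, seed = 1L) {
  stop_if(onset < 21, "onset must be >= 21")
  stop_if(onset + window_frames > n_frames, "window outside trace extent")
  set.seed(substream(seed, 2))
  arch <- rep_len(archetypes, n_traces)
  window <- seq.int(onset, onset + window_frames)
  second <- seq.int(min(onset + window_frames + 20, n_frames),
                    min(onset + window_frames + 20 + transient_frames,
                        n_frames))
  traces <- matrix(0, n_traces, n_frames)
  for (i in seq_len(n_traces)) {
    dff <- numeric(n_frames)
    if (arch[i] == "sustained") {
      dff[window] <- amplitude
    } else if (arch[i] == "transient") {
      dff[seq.int(onset, onset + transient_frames - 1)] <- amplitude
    } else if (arch[i] == "polymodal") {
      dff[window] <- amplitude
      dff[second] <- amplitude
    }
    dff <- dff + rnorm(n_frames, 0, noise_sd)
    traces[i, ] <- baseline * (1 + dff)
  }
  rownames(traces) <- sprintf("cell%04d", seq_len(n_traces))
  list(traces = traces, onset = onset, window = window,
       frame_interval = FRAME_INTERVAL_S,
       truth = setNames(arch, rownames(traces)))
}

#' Simulate a landmark registration scene
#'
#' Generates well-separated in vivo 3-D cell coordinates (landmarks plus
#' non-landmark cells), applies a known rigid transform, adds isotropic
#' Gaussian jitter to the transformed (section-side) coordinates, and
#' records the ground-truth correspondence. Section-side cells carry the
#' index of the 10-micrometre section slab they fall in together with
#' their exact coordinates.
#'
#' @param transform A [rigid_transform()]; the ground truth to recover.
#' @param n_landmarks Number of landmark cells (>= 3).
#' @param n_cells Number of non-landmark cells.
#' @param noise_sd Coordinate jitter on the section side (same units as
#'   the coordinates, micrometres by convention); default 0.
#' @param extent Cube side length of the sampled volume; default 300.
#' @param min_spacing Minimum distance between generated cells; default 40.
#' @param section_thickness Slab thickness for the section index;
#'   default 10.
#' @param seed Integer seed.
#' @return A `landmark_scene`: list with `invivo` and `section`
#'   data.frames (`cell_id`, `x`, `y`, `z`, `section` (section side only),
#'   `landmark`), `transform`, and `correspondence` (named vector
#'   section id -> in vivo id).
#' @export
simulate_landmark_scene <- function(transform = rigid_transform(),
                                    n_landmarks = 10, n_cells = 40,
                                    noise_sd = 0, extent = 300,
                                    min_spacing = 40,
                                    section_thickness = 10, seed = 1L) {
  stop_if(n_landmarks < 3, "need at least 3 landmarks")
  set.seed(substream(seed, 3))
  n <- n_landmarks + n_cells
  # rejection-sample points with minimum spacing
  pts <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(pts) < n && tries < 20000) {
    cand <- runif(3, 0, extent)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= min_spacing) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1
  }
  stop_if(nrow(pts) < n,
          "could not place cells with the requested spacing; lower n or min_spacing")
  landmark <- c(rep(TRUE, n_landmarks), rep(FALSE, n_cells))
  ids <- sprintf("cell%04d", seq_len(n))
  sec_pts <- apply_transform(transform, pts)
  if (noise_sd > 0) {
    sec_pts <- sec_pts + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  }
  invivo <- data.frame(cell_id = ids, x = pts[, 1], y = pts[, 2],
                       z = pts[, 3], landmark = landmark,
                       stringsAsFactors = FALSE)
  section <- data.frame(cell_id = paste0("s_", ids),
                        x = sec_pts[, 1], y = sec_pts[, 2], z = sec_pts[, 3],
                        section = floor(sec_pts[, 3] / section_thickness),
                        landmark = landmark, stringsAsFactors = FALSE)
  structure(list(invivo = invivo, section = section, transform = transform,
                 correspondence = setNames(ids, paste0("s_", ids))),
            class = "landmark_scene")
}

#' Simulate ending tables consistent with a known assignment
#'
#' Builds a cluster label table with random single/dual barcode
#' percentages, computes the projection-derived fold changes (SF) under
#' the supplied true assignment, and fabricates an anatomical fold-change
#' grid equal to SF plus optional Gaussian noise. At `noise_sd = 0` the
#' true assignment attains discrepancy exactly 0 and (generically) every
#' other assignment scores strictly worse, so the exhaustive search must
#' recover it.
#'
#' @param true_assignment Named cluster -> ending type vector covering the
#'   free clusters.
#' @param fixed_map Named cluster -> type vector for pre-annotated
#'   clusters; default one anchor cluster per ending type, which keeps
#'   every type's SF defined in all candidate assignments.
#' @param noise_sd Gaussian noise added to the AF grid; default 0.
#' @param regions Region names; default [stomach_regions()].
#' @param types Ending types; default [ending_types()].
#' @param seed Integer seed.
#' @return List: `af` (types x regions), `labels` (cluster label table
#'   covering free + fixed clusters), `fixed_map`, `truth` (the full true
#'   assignment).
#' @export
simulate_ending_tables <- function(true_assignment,
                                   fixed_map = NULL,
                                   noise_sd = 0,
                                   regions = stomach_regions(),
                                   types = ending_types(), seed = 1L) {
  stop_if(is.null(names(true_assignment)),
          "true_assignment must be named by cluster")
  stop_if(!all(true_assignment %in% types),
          "true_assignment uses unknown ending type")
  set.seed(substream(seed, 4))
  if (is.null(fixed_map)) {
    fixed_map <- setNames(types, paste0("fixed_", types))
  }
  clusters <- c(names(fixed_map), names(true_assignment))
  stop_if(anyDuplicated(clusters) > 0,
          "fixed and free cluster names overlap")
  # free clusters are primary clusters for the organ: each holds more than
  # 4% of the organ's single-labelled cells, so shares start above 4
  labels <- data.frame(cluster = clusters,
                       single = runif(length(clusters), 4, 12),
                       stringsAsFactors = FALSE)
  # ending types are differentially enriched across stomach regions (the
  # anatomical structure that makes the assignment identifiable), so a
  # cluster's dual-label profile follows its true type's preferred region:
  # high dual share there, low elsewhere
  full_truth <- c(fixed_map, true_assignment)
  preferred <- rep_len(seq_along(regions),
                       length(types))[match(full_truth, types)]
  for (j in seq_along(regions)) {
    labels[[paste0("dual_", regions[j])]] <-
      ifelse(preferred == j, runif(length(clusters), 6, 12),
             runif(length(clusters), 0, 2))
  }
  sf <- projection_fold_change(full_truth, labels, regions = regions,
                               types = types)
  af <- sf + matrix(rnorm(length(sf), 0, noise_sd), nrow(sf), ncol(sf))
  dimnames(af) <- dimnames(sf)
  list(af = af, labels = labels, fixed_map = fixed_map,
       truth = full_truth)
}
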