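# Landmark-based registration between an in vivo 3-D imaging stack and
# post-hoc serial 2-D sections. Landmark cells (e.g. tdTomato+ neurons
# present in both modalities) anchor a least-squares rigid transform; the
# remaining cells are then matched under that transform with an explicit
# ambiguity criterion.

#' Construct a rigid (optionally similarity) transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric length-3 vector.
#' @param scale Positive isotropic scale, default 1 (rigid).
#' @return A `rigid_transform` object. Applied as `scale * R %*% x + t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- as.matrix(rotation)
  stop_if(!all(dim(rotation) == c(3, 3)), "rotation must be 3x3")
  stop_if(max(abs(crossprod(rotation) - diag(3))) > 1e-6,
          "rotation must be orthonormal")
  stop_if(det(rotation) < 0, "rotation must have determinant +1")
  stop_if(length(translation) != 3, "translation must be length 3")
  stop_if(scale <= 0, "scale must be positive")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 numeric matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  p <- as.matrix(points)
  stop_if(ncol(p) != 3, "points must be n x 3")
  t(transform$scale * transform$rotation %*% t(p) + transform$translation)
}

#' Rotation matrix about a coordinate axis
#'
#' @param angle Angle in radians.
#' @param axis "x", "y" or "z".
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(angle, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  switch(axis,
    z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE))
}

#' Least-squares rigid transform between paired point sets
#'
#' Estimates the rotation, translation (and optionally isotropic scale)
#' minimising the sum of squared distances between transformed source
#' points and their paired targets (Kabsch/Umeyama). The rotation is
#' constrained to be proper (determinant +1): point sets related by a
#' reflection are fitted with the best proper rotation instead, which
#' shows up as a large residual.
#'
#' @param source,target Paired n x 3 matrices (row i of `source`
#'   corresponds to row i of `target`); n >= 3, not collinear.
#' @param allow_scale Estimate an isotropic scale (similarity transform);
#'   default FALSE (rigid). Useful for shrinkage between live tissue and
#'   processed sections.
#' @return A [rigid_transform()] with attribute `rmsd` (root-mean-square
#'   residual over the pairs).
#' @export
estimate_transform <- function(source, target, allow_scale = FALSE) {
  src <- as.matrix(source); tgt <- as.matrix(target)
  stop_if(nrow(src) != nrow(tgt), "point sets must be paired")
  stop_if(nrow(src) < 3, "need at least 3 pairs")
  mu_s <- colMeans(src); mu_t <- colMeans(tgt)
  xs <- sweep(src, 2, mu_s); xt <- sweep(tgt, 2, mu_t)
  h <- crossprod(xs, xt)     # 3x3 covariance
  sv <- svd(h)
  stop_if(sv$d[2] < 1e-12 * max(sv$d[1], 1),
          "degenerate (collinear) landmark configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  s_diag <- diag(c(1, 1, d))
  r <- sv$v %*% s_diag %*% t(sv$u)
  scale <- if (allow_scale) {
    sum(diag(s_diag) * sv$d) / sum(xs^2)
  } else 1
  tr <- mu_t - scale * as.numeric(r %*% mu_s)
  out <- rigid_transform(r, tr, scale)
  res <- apply_transform(out, src) - tgt
  attr(out, "rmsd") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Mutual-nearest-neighbour landmark pairing
#'
#' Pairs landmarks across modalities: under the current transform of the
#' in vivo points, a pair is kept when each point is the other's nearest
#' neighbour and their distance is within the gate radius.
#'
#' @param invivo_landmarks,section_landmarks n x 3 matrices (section
#'   points carry their reconstructed depth as the third coordinate).
#' @param initial_transform Transform applied to `invivo_landmarks` before
#'   matching; default identity.
#' @param gate_radius Maximum pairing distance (same length units as the
#'   coordinates), default Inf.
#' @return Two-column integer matrix (`invivo`, `section`) of paired row
#'   indices.
#' @export
match_landmarks <- function(invivo_landmarks, section_landmarks,
                            initial_transform = rigid_transform(),
                            gate_radius = Inf) {
  a <- apply_transform(initial_transform, as.matrix(invivo_landmarks))
  b <- as.matrix(section_landmarks)
  stop_if(nrow(a) < 3 || nrow(b) < 3, "need at least 3 landmarks per side")
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  nn_ab <- apply(d2, 1, which.min)
  nn_ba <- apply(d2, 2, which.min)
  i <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab] == i
  within <- sqrt(d2[cbind(i, nn_ab)]) <= gate_radius
  pairs <- cbind(invivo = i[mutual & within],
                 section = nn_ab[mutual & within])
  stop_if(nrow(pairs) < 3, "fewer than 3 mutual landmark pairs")
  pairs
}

#' Best-fit plane through a 3-D point set
#'
#' Least-squares virtual plane: the plane through the centroid whose normal
#' is the smallest-spread direction of the centred points, minimising the
#' total squared point-to-plane projection distance. Used to correct for
#' sectioning planes that are not axis-aligned in the transformed stack.
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @return List with `point` (centroid), `normal` (unit vector) and
#'   `residual` (sum of squared distances).
#' @export
fit_virtual_plane <- function(points) {
  p <- as.matrix(points)
  stop_if(nrow(p) < 3, "need at least 3 points")
  ctr <- colMeans(p)
  x <- sweep(p, 2, ctr)
  sv <- svd(x)
  stop_if(sv$d[2] < 1e-12 * max(sv$d[1], 1), "collinear points")
  normal <- sv$v[, 3]
  residual <- sum((x %*% normal)^2)
  list(point = ctr, normal = as.numeric(normal), residual = residual)
}

#' Register a non-landmark cell with an ambiguity gate
#'
#' After the landmark-based transform, each section cell is matched to the
#' transformed in vivo candidates: it is `registered` to the nearest
#' candidate when that candidate lies within radius `r` and the
#' second-nearest candidate is more than `rho` times farther away;
#' `ambiguous` when a competitor is too close; `unmatched` when nothing
#' lies within `r`. Unregistered cells are conventionally dropped from
#' downstream analysis.
#'
#' @param cell Length-3 coordinate of the section cell.
#' @param candidates n x 3 matrix of transformed in vivo cell coordinates.
#' @param r Gate radius; default 15 (one cell diameter in micrometres).
#' @param rho Ambiguity ratio (second-nearest / nearest must strictly
#'   exceed it); default 1.5.
#' @return List with `status` ("registered", "ambiguous" or "unmatched")
#'   and `match` (candidate row index, NA unless registered).
#' @export
register_nonlandmark <- function(cell, candidates, r = 15, rho = 1.5) {
  cand <- as.matrix(candidates)
  stop_if(nrow(cand) == 0, "no candidates")
  d <- sqrt(colSums((t(cand) - as.numeric(cell))^2))
  ord <- order(d)
  nearest <- d[ord[1]]
  if (nearest > r) return(list(status = "unmatched", match = NA_integer_))
  if (length(d) > 1 && d[ord[2]] <= rho * nearest && d[ord[2]] > 0)
    return(list(status = "ambiguous", match = NA_integer_))
  if (length(d) > 1 && nearest == 0 && d[ord[2]] == 0)
    return(list(status = "ambiguous", match = NA_integer_))
  list(status = "registered", match = ord[1])
}

#' Register every cell of a scene
#'
#' End-to-end registration: pair landmarks (mutual nearest neighbours),
#' estimate the rigid transform from the pairs, then register each
#' non-landmark section cell against the transformed in vivo cells.
#'
#' @param scene A `landmark_scene` from [simulate_landmark_scene()], or any
#'   list with `invivo` and `section` data.frames carrying columns
#'   `cell_id`, `x`, `y`, `z`, `landmark`.
#' @param r,rho Gate radius and ambiguity ratio (see
#'   [register_nonlandmark()]).
#' @param landmark_pairing How landmark correspondence is established:
#'   `"id"` (default) pairs landmarks whose cell ids match (an optional
#'   `s_` prefix on section ids is ignored), reflecting that landmark
#'   cells are individually identified in both modalities;
#'   `"mutual_nn"` pairs by mutual nearest neighbour under
#'   `initial_transform` via [match_landmarks()], for use when a transform
#'   estimate already exists.
#' @param initial_transform Starting transform for `"mutual_nn"` pairing.
#' @param gate_radius Landmark pairing gate (see [match_landmarks()]).
#' @param allow_scale Estimate a similarity transform instead of rigid.
#' @return List: `transform`, `outcomes` (data.frame with `section_id`,
#'   `status`, `invivo_id`), `landmark_pairs`.
#' @export
register_scene <- function(scene, r = 15, rho = 1.5,
                           landmark_pairing = c("id", "mutual_nn"),
                           initial_transform = rigid_transform(),
                           gate_radius = Inf, allow_scale = FALSE) {
  landmark_pairing <- match.arg(landmark_pairing)
  iv <- scene$invivo; sc <- scene$section
  ivl <- iv[iv$landmark, c("x", "y", "z")]
  scl <- sc[sc$landmark, c("x", "y", "z")]
  if (landmark_pairing == "id") {
    iv_ids <- iv$cell_id[iv$landmark]
    sc_ids <- sub("^s_", "", sc$cell_id[sc$landmark])
    hit <- match(sc_ids, iv_ids)
    pairs <- cbind(invivo = hit[!is.na(hit)],
                   section = which(!is.na(hit)))
    stop_if(nrow(pairs) < 3,
            "fewer than 3 landmarks share ids; use landmark_pairing = 'mutual_nn'")
  } else {
    pairs <- match_landmarks(ivl, scl, initial_transform = initial_transform,
                             gate_radius = gate_radius)
  }
  tf <- estimate_transform(as.matrix(ivl)[pairs[, 1], , drop = FALSE],
                           as.matrix(scl)[pairs[, 2], , drop = FALSE],
                           allow_scale = allow_scale)
  cand_rows <- which(!iv$landmark)
  cand <- apply_transform(tf, as.matrix(iv[cand_rows, c("x", "y", "z")]))
  targets <- sc[!sc$landmark, , drop = FALSE]
  out <- lapply(seq_len(nrow(targets)), function(i) {
    reg <- register_nonlandmark(as.numeric(targets[i, c("x", "y", "z")]),
                                cand, r = r, rho = rho)
    data.frame(section_id = targets$cell_id[i], status = reg$status,
               invivo_id = if (is.na(reg$match)) NA_character_ else
                 iv$cell_id[cand_rows[reg$match]],
               stringsAsFactors = FALSE)
  })
  list(transform = tf, outcomes = do.call(rbind, out),
       landmark_pairs = pairs)
}

#' Fraction of cells unambiguously registered
#'
#' @param outcomes data.frame with a `status` column (as returned by
#'   [register_scene()]), or a character vector of statuses.
#' @return Registered count divided by total, in \[0, 1\].
#' @export
registration_rate <- function(outcomes) {
  status <- if (is.data.frame(outcomes)) outcomes$status else outcomes
  stop_if(length(status) == 0, "no outcomes")
  mean(status == "registered")
}
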