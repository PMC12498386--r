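# Exact geometric primitives used by every downstream stage: torsions,
# centers of mass, optimal (Kabsch) superposition, RMSD, radius of gyration.
# Coordinates are Angstrom throughout; angles are degrees on (-180, 180].

#' Wrap angles to (-180, 180] degrees
#' @param x Numeric vector of angles in degrees.
#' @export
wrap_angle <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

# circular distance between two angles in degrees, in [0, 180]
circular_distance <- function(a, b) {
  abs(wrap_angle(a - b))
}

vec_cross <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1, 3)
  if (is.null(dim(b))) b <- matrix(b, 1, 3)
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3, byrow = TRUE) else as.matrix(p)
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: the angle is 0 for an eclipsed (cis) arrangement and
#' positive when, looking from `p2` towards `p3`, the far bond `p3->p4` is
#' rotated clockwise from the near bond `p2->p1`. Degenerate geometry
#' (collinear `p1,p2,p3` or `p2,p3,p4`) is an error, never a silent 0.
#'
#' @param p1,p2,p3,p4 3-vectors, or n x 3 matrices of points (vectorized).
#' @return Torsion angle(s) in degrees on (-180, 180].
#' @examples
#' torsion_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)) # 0 (cis)
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  p1 <- as_point_matrix(p1); p2 <- as_point_matrix(p2)
  p3 <- as_point_matrix(p3); p4 <- as_point_matrix(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nb2 <- sqrt(rowSums(b2^2))
  if (any(nb2 < 1e-10)) abort("degenerate torsion: p2 and p3 coincide")
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  s1 <- sqrt(rowSums(n1^2)) / (sqrt(rowSums(b1^2)) * nb2)
  s2 <- sqrt(rowSums(n2^2)) / (sqrt(rowSums(b3^2)) * nb2)
  if (any(s1 < 1e-8)) abort("degenerate torsion: p1, p2, p3 are collinear")
  if (any(s2 < 1e-8)) abort("degenerate torsion: p2, p3, p4 are collinear")
  x <- rowSums(n1 * n2)
  y <- rowSums(vec_cross(n1, n2) * (b2 / nb2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Mass-weighted center of mass
#'
#' @param s A `gag_structure`.
#' @param sel Optional tidy selection over the atom table, e.g.
#'   `residue_index == 1`; default selects all atoms.
#' @return A length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(s, sel = NULL) {
  stopifnot(is_gag_structure(s))
  idx <- resolve_selection(topology_of(s), enquo(sel))
  weighted_centroid(coords(s)[idx, , drop = FALSE], s$mass[idx])
}

weighted_centroid <- function(xyz, w) {
  unname(colSums(xyz * w) / sum(w))
}

#' Radius of gyration
#'
#' Rg = sqrt(sum_i m_i |r_i - r_com|^2 / sum_i m_i), the mass-weighted RMS
#' distance of the selected atoms from their center of mass.
#'
#' @inheritParams center_of_mass
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(s, sel = NULL) {
  stopifnot(is_gag_structure(s))
  idx <- resolve_selection(topology_of(s), enquo(sel))
  rg_of(coords(s)[idx, , drop = FALSE], s$mass[idx])
}

rg_of <- function(xyz, w) {
  com <- weighted_centroid(xyz, w)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(w * d2) / sum(w))
}

# plain (unfitted) weighted RMSD between two coordinate matrices
rmsd_of <- function(x, y, w = rep(1, nrow(x))) {
  sqrt(sum(w * rowSums((x - y)^2)) / sum(w))
}

# Kabsch: rotation A (right action: centered_x %*% A) minimizing weighted RMSD
kabsch_rotation <- function(xc, yc, w) {
  m <- t(xc * w) %*% yc
  s <- svd(m)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Optimal rigid-body superposition of two structures
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' mass-weighted) RMSD between the selected atoms of `mobile` and
#' `reference`, using the closed-form Kabsch solution with a reflection
#' guard. Mass weighting defaults to on, mirroring the common MD-analysis
#' convention for trajectory RMSD.
#'
#' @param mobile,reference `gag_structure` objects with the same selection
#'   size (at least 3 non-collinear atoms).
#' @param sel Optional tidy atom selection applied to both structures.
#' @param mass_weighted Weight atoms by mass? Default `TRUE`.
#' @return A list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd` (Angstrom). The fitted mobile coordinates are
#'   `coords(mobile) %*% rotation + translation` (row vectors).
#' @export
optimal_superposition <- function(mobile, reference, sel = NULL,
                                  mass_weighted = TRUE) {
  stopifnot(is_gag_structure(mobile), is_gag_structure(reference))
  sel_quo <- enquo(sel)
  im <- resolve_selection(topology_of(mobile), sel_quo)
  ir <- resolve_selection(topology_of(reference), sel_quo)
  if (length(im) != length(ir)) {
    abort("selection resolves to different sizes in mobile and reference")
  }
  x <- coords(mobile)[im, , drop = FALSE]
  y <- coords(reference)[ir, , drop = FALSE]
  w <- if (mass_weighted) mobile$mass[im] else rep(1, length(im))
  fit <- superpose_xyz(x, y, w)
  fit
}

superpose_xyz <- function(x, y, w) {
  if (nrow(x) < 3) abort("superposition needs at least 3 atoms")
  cx <- weighted_centroid(x, w)
  cy <- weighted_centroid(y, w)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  # collinearity check: rank of the weighted covariance
  ev <- svd(xc * sqrt(w))$d
  if (ev[2] < 1e-8 * max(ev[1], 1)) {
    abort("superposition selection is collinear")
  }
  rot <- kabsch_rotation(xc, yc, w)
  fitted <- xc %*% rot
  list(
    rotation = rot,
    translation = as.numeric(cy - cx %*% rot),
    rmsd = rmsd_of(fitted, yc, w)
  )
}

#' Apply a rigid transform to a structure
#'
#' @param s A `gag_structure`.
#' @param rotation 3 x 3 rotation matrix (right action on row vectors).
#' @param translation Length-3 translation (Angstrom).
#' @export
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(is_gag_structure(s))
  set_coords(s, sweep(coords(s) %*% rotation, 2, -translation))
}
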