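# Synthetic conformer and ensemble generation: idealized pyranose rings at
# prescribed Cremer-Pople coordinates, heparin-like chains with prescribed
# glycosidic torsions, and stochastic ensembles with known pucker-state
# populations, torsion distributions and Cartesian noise.

RING_ATOMS <- c("O5", "C1", "C2", "C3", "C4", "C5")

# per-bond targets around the ring, O5-C1, C1-C2, ..., C5-O5 (Angstrom)
RING_BOND_TARGETS <- c(1.43, 1.52, 1.52, 1.52, 1.52, 1.44)

# Cremer-Pople z-pattern for a 6-ring, j = 1..6 corresponding to O5, C1..C5.
cp_z_pattern <- function(q, theta, phi2) {
  j <- 0:5
  q2 <- q * sin(theta * pi / 180)
  q3 <- q * cos(theta * pi / 180)
  sqrt(1 / 3) * q2 * cos(phi2 * pi / 180 + 2 * pi * 2 * j / 6) +
    q3 / sqrt(6) * (-1)^j
}

# Closed-form ring on per-atom radii/in-plane angles with the exact CP
# z-pattern, refined so bond lengths match RING_BOND_TARGETS. Because the
# z-pattern contains only m = 2, 3 Fourier components over the index grid,
# the CP mean-plane normal is exactly +z for any in-plane arrangement, so
# the refinement cannot perturb the puckering coordinates.
ring_xyz_cp <- function(q, theta, phi2) {
  z <- cp_z_pattern(q, theta, phi2)
  dz2 <- diff(c(z, z[1]))^2
  r0 <- sqrt(max(mean(RING_BOND_TARGETS)^2 - mean(dz2), 0.8))
  base_ang <- -(0:5) * pi / 3  # clockwise: CP normal = +z
  par0 <- c(rep(r0, 6), rep(0, 5))
  fn <- function(p) {
    r <- p[1:6]
    ang <- base_ang + c(0, p[7:11])
    x <- r * cos(ang); y <- r * sin(ang)
    dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
    bonds <- sqrt(dx^2 + dy^2 + dz2)
    sum((bonds - RING_BOND_TARGETS)^2) +
      1e-5 * sum(p[7:11]^2) + 1e-5 * sum((r - r0)^2)
  }
  opt <- optim(par0, fn, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  r <- opt$par[1:6]
  ang <- base_ang + c(0, opt$par[7:11])
  xyz <- cbind(r * cos(ang), r * sin(ang), z)
  rownames(xyz) <- RING_ATOMS
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

ring_cache <- new.env(parent = emptyenv())

ring_xyz_cached <- function(q, theta, phi2) {
  key <- sprintf("%.6f_%.6f_%.6f", q, theta, phi2 %% 360)
  if (is.null(ring_cache[[key]])) ring_cache[[key]] <- ring_xyz_cp(q, theta, phi2)
  ring_cache[[key]]
}

#' Build an idealized pyranose ring at given Cremer-Pople coordinates
#'
#' Constructs the six ring atoms (O5, C1..C5) of a pyranose at puckering
#' amplitude `q` (Angstrom), polar angle `theta` (0 and 180 degrees are the
#' 4C1 and 1C4 chairs) and pseudorotation phase `phi2` (the theta = 90
#' equator carries the boats and skew-boats). Out-of-plane displacements
#' follow the Cremer-Pople z-pattern exactly; in-plane positions are refined
#' so every ring bond falls in the 1.43-1.55 Angstrom range.
#'
#' @param q Puckering amplitude Q in Angstrom (0 < q <= 1).
#' @param theta Polar puckering angle in degrees, 0 to 180.
#' @param phi2 Pseudorotation phase in degrees.
#' @param residue_index,residue_type Residue labelling of the returned atoms.
#' @return A `gag_structure` of the six ring atoms.
#' @export
build_pyranose_ring <- function(q = 0.57, theta = 0, phi2 = 0,
                                residue_index = 1L,
                                residue_type = "GlcNS(6S)") {
  if (!is.finite(q) || q <= 0) abort("puckering amplitude q must be > 0")
  if (q > 1) abort("non-physical puckering amplitude (q > 1 Angstrom)")
  xyz <- ring_xyz_cached(q, theta, phi2)
  gag_structure(tibble(
    atom_name = RING_ATOMS,
    element = c("O", rep("C", 5)),
    mass = element_mass(c("O", rep("C", 5))),
    residue_index = as.integer(residue_index),
    residue_type = residue_type,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

# canonical Cremer-Pople coordinates of the four classified pucker states;
# phase assignments follow IUPAC twist-boat naming on the theta = 90 equator
# (see data-raw/derive-pucker-references.R for the audited derivation)
CANONICAL_CP <- data.frame(
  state = c("4C1", "1C4", "2SO", "1S3"),
  theta = c(0, 180, 90, 90),
  phi2 = c(0, 0, 150, 210)
)

#' Derive pucker-state reference angles from canonical ring geometry
#'
#' Builds idealized rings at the canonical Cremer-Pople coordinates of the
#' 4C1 and 1C4 chairs (theta = 0, 180) and the 2SO and 1S3 skew-boats
#' (theta = 90 equator at their IUPAC-named phases), computes each ring's
#' gamma (C1-C2-C3-C4) and delta (C1-O5-C5-C4) dihedrals, and returns them
#' as a classification reference set. The derivation is deterministic.
#'
#' @param q Puckering amplitude used for the canonical rings (Angstrom).
#' @param half_width Classification window half-width in degrees.
#' @return A `gag_pucker_refs` tibble with columns `state`, `gamma_ref`,
#'   `delta_ref`, `half_width`.
#' @export
derive_pucker_references <- function(q = 0.57, half_width = 23) {
  refs <- lapply(seq_len(nrow(CANONICAL_CP)), function(i) {
    ring <- build_pyranose_ring(q, CANONICAL_CP$theta[i], CANONICAL_CP$phi2[i])
    gd <- compute_gamma_delta(ring, 1L)
    tibble(state = CANONICAL_CP$state[i],
           gamma_ref = gd$gamma, delta_ref = gd$delta)
  })
  pucker_reference_set(dplyr::bind_rows(refs), half_width = half_width)
}

# ---- chain assembly ---------------------------------------------------------

unit3 <- function(v) v / sqrt(sum(v^2))

# NeRF placement: point D with |D-C| = bond, angle(D,C,B) = angle and
# torsion_angle(D, C, B, A) = torsion (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(vec_cross(b - a, bc)[1, ])
  m <- vec_cross(n, bc)[1, ]
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi), bond * sin(th) * sin(chi))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

rodrigues <- function(axis, angle_deg) {
  u <- unit3(axis)
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# rotation taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  v <- vec_cross(a, b)[1, ]
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rodrigues(vec_cross(a, p)[1, ], 180))
  }
  k <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + k + k %*% k * ((1 - cth) / s^2)
}

# side-chain pseudo-atom recipes per residue type: united atoms carrying the
# substituent masses, placed at staggered positions off the ring. The ring
# decoration is idealized; mass weighting, not substituent geometry, is what
# the descriptor and linkage analyses consume.
SIDE_ATOMS <- list(
  "GlcNS(6S)" = data.frame(
    atom_name = c("NS", "O3", "S6"),
    element   = c("N", "O", "S"),
    mass      = c(95.07, 17.01, 110.08),
    on        = c("C2", "C3", "C5"),
    bond      = c(1.45, 1.43, 1.53),
    offset    = c(120, -120, 120),
    stringsAsFactors = FALSE
  ),
  "IdoA(2S)" = data.frame(
    atom_name = c("S2", "O3", "C6A"),
    element   = c("S", "O", "C"),
    mass      = c(96.06, 17.01, 44.01),
    on        = c("C2", "C3", "C5"),
    bond      = c(1.45, 1.43, 1.52),
    offset    = c(120, -120, 120),
    stringsAsFactors = FALSE
  )
)

# glycosidic-oxygen stagger (deg) off the C2 substituent position at the
# donor anomeric carbon, per donor residue type
ANOMERIC_OFFSET <- list("GlcNS(6S)" = -120, "IdoA(2S)" = 120)

# Decorate a bare ring with O4 and united side-chain pseudo-atoms.
# Substituents are placed staggered (+120 deg) off the corresponding ring
# torsion so chains assemble clash-free at typical glycosidic torsions.
# Returns a plain list (names, elements, masses, xyz matrix) cached per
# (type, q, theta, phi2); chain assembly works on matrices for speed.
residue_template_raw <- function(residue_type, q, theta, phi2) {
  key <- sprintf("%s|%.6f|%.6f|%.6f", residue_type, q, theta, phi2 %% 360)
  hit <- template_cache[[key]]
  if (!is.null(hit)) return(hit)
  xyz <- ring_xyz_cached(q, theta, phi2)
  tors <- function(n1, n2, n3, n4) {
    torsion_angle(xyz[n1, ], xyz[n2, ], xyz[n3, ], xyz[n4, ])
  }
  place_sub <- function(on, bond, offset = 120) {
    nb <- switch(on, C2 = c("O5", "C1"), C3 = c("C1", "C2"),
                 C4 = c("C2", "C3"), C5 = c("C3", "C4"))
    ring_next <- switch(on, C2 = "C3", C3 = "C4", C4 = "C5", C5 = "O5")
    tau_ring <- tors(ring_next, on, nb[2], nb[1])
    place_atom(xyz[nb[1], ], xyz[nb[2], ], xyz[on, ],
               bond, 109.5, wrap_angle(tau_ring + offset))
  }
  extra <- SIDE_ATOMS[[residue_type]]
  if (is.null(extra)) {
    extra <- data.frame(atom_name = character(), element = character(),
                        mass = numeric(), on = character(), bond = numeric(),
                        offset = numeric())
  }
  # side pseudo-atoms sit radially outward in the ring mean plane (the
  # template frame's xy-plane), an equatorial-like orientation that stays
  # clash-free for every pucker state; only O4 is torsion-placed because the
  # glycosidic geometry depends on it
  place_radial <- function(on, bond) {
    p <- xyz[on, ]
    u <- c(p[1], p[2], 0)
    p + bond * u / sqrt(sum(u^2))
  }
  pos <- rbind(
    xyz,
    place_sub("C4", 1.43),
    do.call(rbind, lapply(seq_len(nrow(extra)), function(i) {
      place_radial(extra$on[i], extra$bond[i])
    }))
  )
  out <- list(
    atom_name = c(RING_ATOMS, "O4", extra$atom_name),
    element = c("O", rep("C", 5), "O", extra$element),
    mass = c(element_mass(c("O", rep("C", 5), "O")), extra$mass),
    xyz = unname(pos)
  )
  template_cache[[key]] <- out
  out
}

template_cache <- new.env(parent = emptyenv())

#' Build a heparin-like chain with prescribed glycosidic torsions
#'
#' Assembles `n_residues` pyranose residues (default alternating GlcNS(6S)
#' and IdoA(2S), residue 1 at the reducing end) by internal-coordinate
#' placement: residue n+1's C1 is bonded to residue n's O4 and the glycosidic
#' torsions phi = O5(n+1)-C1(n+1)-O4(n)-C4(n) and
#' psi = C1(n+1)-O4(n)-C4(n)-C3(n) take exactly the prescribed values.
#' Side-chain substituents (N-sulfo, O-sulfo, carboxylate, hydroxyl) are
#' represented as single united pseudo-atoms with the substituent masses.
#'
#' @param n_residues Number of residues (>= 2).
#' @param phi,psi Glycosidic torsions in degrees; length `n_residues - 1`
#'   vectors (recycled if length 1). Element n is the torsion of the linkage
#'   between residues n and n+1. The default (`NULL`) uses each linkage
#'   class's population maximum: (-70, 120) for GlcNS(6S)-IdoA(2S) donors
#'   and (60, 60) for IdoA(2S)-GlcNS(6S) donors.
#' @param residue_types Character vector of residue type labels; default
#'   alternates `"GlcNS(6S)"`, `"IdoA(2S)"` from the reducing end.
#' @param pucker_states Per-residue pucker state labels among `"4C1"`,
#'   `"1C4"`, `"2SO"`, `"1S3"` (recycled); default 4C1 for GlcNS(6S) and
#'   2SO for IdoA(2S).
#' @param q Puckering amplitude for the ring templates (Angstrom).
#' @param check_clash Error if any non-bonded inter-residue atom pair comes
#'   closer than 1.5 Angstrom.
#' @return A `gag_structure`.
#' @export
build_chain <- function(n_residues = 12, phi = NULL, psi = NULL,
                        residue_types = NULL, pucker_states = NULL,
                        q = 0.57, check_clash = TRUE) {
  if (n_residues < 2) abort("a chain needs at least 2 residues")
  if (is.null(residue_types)) {
    residue_types <- rep(c("GlcNS(6S)", "IdoA(2S)"),
                         length.out = n_residues)
  }
  stopifnot(length(residue_types) == n_residues)
  if (is.null(pucker_states)) {
    pucker_states <- ifelse(residue_types == "IdoA(2S)", "2SO", "4C1")
  }
  pucker_states <- rep(pucker_states, length.out = n_residues)
  bad <- setdiff(pucker_states, CANONICAL_CP$state)
  if (length(bad) > 0) {
    abort(paste0("unknown pucker state(s): ", paste(bad, collapse = ", ")))
  }
  n_link <- n_residues - 1
  if (is.null(phi) || is.null(psi)) {
    defaults <- default_linkage_torsions()
    cls <- linkage_class_of(residue_types)
    m <- match(cls, defaults$linkage_class)
    m[is.na(m)] <- 1L
    if (is.null(phi)) phi <- defaults$mean_phi[m]
    if (is.null(psi)) psi <- defaults$mean_psi[m]
  }
  phi <- rep(phi, length.out = n_link)
  psi <- rep(psi, length.out = n_link)

  templates <- lapply(seq_len(n_residues), function(k) {
    cp <- CANONICAL_CP[CANONICAL_CP$state == pucker_states[k], ]
    residue_template_raw(residue_types[k], q, cp$theta, cp$phi2)
  })

  n_per <- vapply(templates, function(t) length(t$atom_name), integer(1))
  placed <- vector("list", n_residues)
  placed[[1]] <- templates[[1]]$xyz
  for (k in 2:n_residues) {
    tpl <- templates[[k]]
    at <- function(res, name) {
      placed[[res]][templates[[res]]$atom_name == name, ]
    }
    p_c3 <- at(k - 1, "C3"); p_c4 <- at(k - 1, "C4"); p_o4 <- at(k - 1, "O4")
    t_o5 <- tpl$xyz[tpl$atom_name == "O5", ]
    t_c1 <- tpl$xyz[tpl$atom_name == "C1", ]
    d_o5c1 <- sqrt(sum((t_o5 - t_c1)^2))
    # place the anomeric carbon and ring oxygen from psi and phi
    c1 <- place_atom(p_c3, p_c4, p_o4, 1.42, 116, psi[k - 1])
    o5 <- place_atom(p_c4, p_o4, c1, d_o5c1, 109.5, phi[k - 1])
    # rigid-place the residue template onto (C1, O5), then fix the rotation
    # about the C1-O5 axis by the anomeric torsion C5-O5-C1-O4(prev)
    txyz <- sweep(tpl$xyz, 2, t_c1) %*% t(rotation_between(t_o5 - t_c1, o5 - c1))
    t_c5 <- txyz[tpl$atom_name == "C5", ]
    t_c2 <- txyz[tpl$atom_name == "C2", ]
    tau_ring <- torsion_angle(t_c5 + c1, o5, c1, t_c2 + c1)
    # the sign of the stagger encodes the anomeric configuration: alpha-D
    # for GlcNS(6S) donors, alpha-L for IdoA(2S) donors
    ano <- ANOMERIC_OFFSET[[residue_types[k]]]
    if (is.null(ano)) ano <- -120
    tau_target <- wrap_angle(tau_ring + ano)
    tau_cur <- torsion_angle(t_c5 + c1, o5, c1, p_o4)
    rot2 <- rodrigues(o5 - c1, tau_target - tau_cur)
    cand <- txyz %*% t(rot2)
    chk <- torsion_angle(cand[tpl$atom_name == "C5", ] + c1, o5, c1, p_o4)
    if (circular_distance(chk, tau_target) > 1e-6) {
      cand <- txyz %*% t(rodrigues(o5 - c1, tau_cur - tau_target))
    }
    placed[[k]] <- sweep(cand, 2, -c1)
  }
  res_idx <- rep(seq_len(n_residues), n_per)
  atoms <- tibble(
    atom_name = unlist(lapply(templates, `[[`, "atom_name")),
    element = unlist(lapply(templates, `[[`, "element")),
    mass = unlist(lapply(templates, `[[`, "mass")),
    residue_index = res_idx,
    residue_type = rep(residue_types, n_per),
    x = 0, y = 0, z = 0
  )
  xyz <- do.call(rbind, placed)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  s <- gag_structure(atoms)
  if (check_clash) check_chain_clashes(s)
  s
}

check_chain_clashes <- function(s, min_dist = 1.5) {
  xyz <- coords(s)
  d <- as.matrix(stats::dist(xyz))
  # ignore intra-residue pairs and the glycosidic bonds O4(n)-C1(n+1)
  d[outer(s$residue_index, s$residue_index, "==")] <- Inf
  o4 <- which(s$atom_name == "O4")
  c1 <- which(s$atom_name == "C1")
  for (i in o4) {
    j <- c1[s$residue_index[c1] == s$residue_index[i] + 1L]
    if (length(j) == 1) d[i, j] <- d[j, i] <- Inf
  }
  if (any(d < min_dist)) {
    abort(sprintf(
      paste0("inter-residue clash (%.2f Angstrom < %.2f) after placement; ",
             "revise the prescribed torsions"), min(d), min_dist))
  }
  invisible(s)
}

# ---- stochastic ensembles ---------------------------------------------------

default_linkage_torsions <- function() {
  tibble(
    linkage_class = c("GlcNS(6S)-IdoA(2S)", "IdoA(2S)-GlcNS(6S)"),
    mean_phi = c(-70, 60), mean_psi = c(120, 60),
    sd_phi = c(12, 12), sd_psi = c(12, 12), weight = c(1, 1)
  )
}

default_pucker_probs <- function() {
  list(
    "GlcNS(6S)" = c("4C1" = 1),
    "IdoA(2S)" = c("2SO" = 0.65, "1S3" = 0.35)
  )
}

#' Recipe for a synthetic conformer ensemble
#'
#' Describes the stochastic model a synthetic ensemble is drawn from:
#' per-residue pucker-state probabilities, per-linkage-class glycosidic
#' torsion distributions (wrapped normal, optionally a weighted mixture of
#' components) and iid Gaussian Cartesian noise added last. Defaults emulate
#' a heparin dodecamer: alternating GlcNS(6S)/IdoA(2S) residues, GlcNS rings
#' fixed in 4C1, IdoA split between 2SO and 1S3, and linkage torsions centred
#' on the phi/psi population maxima typical of heparin.
#'
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed (mandatory; the generator is reproducible).
#' @param n_residues Number of residues in the chain.
#' @param residue_types Residue type labels (default alternating from the
#'   reducing end).
#' @param pucker_probs Either a named list keyed by residue type, or a list
#'   of length `n_residues`, of named probability vectors over the states
#'   `4C1`, `1C4`, `2SO`, `1S3`. Probabilities must sum to 1.
#' @param linkage_torsions Tibble with columns `linkage_class`, `mean_phi`,
#'   `mean_psi`, `sd_phi`, `sd_psi`, `weight`; several rows per class define
#'   a mixture.
#' @param noise_sd Isotropic Cartesian noise sigma in Angstrom (>= 0).
#' @param frame_spacing Frame spacing in ps.
#' @param q Ring puckering amplitude for the templates.
#' @return A `gag_ensemble_recipe` list.
#' @export
ensemble_recipe <- function(n_frames, seed, n_residues = 12,
                            residue_types = NULL,
                            pucker_probs = default_pucker_probs(),
                            linkage_torsions = default_linkage_torsions(),
                            noise_sd = 0.05, frame_spacing = 100, q = 0.57) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (missing(seed) || !is.finite(seed)) abort("a seed is required")
  if (is.null(residue_types)) {
    residue_types <- rep(c("GlcNS(6S)", "IdoA(2S)"), length.out = n_residues)
  }
  stopifnot(length(residue_types) == n_residues)
  per_res <- resolve_pucker_probs(pucker_probs, residue_types)
  for (p in per_res) {
    if (abs(sum(p) - 1) > 1e-8) abort("pucker probabilities must sum to 1")
    if (!all(names(p) %in% CANONICAL_CP$state)) {
      abort("pucker probabilities name unknown states")
    }
  }
  linkage_torsions <- as_tibble(linkage_torsions)
  needed <- unique(linkage_class_of(residue_types))
  missing_cls <- setdiff(needed, linkage_torsions$linkage_class)
  if (length(missing_cls) > 0) {
    abort(paste0("linkage_torsions missing class(es): ",
                 paste(missing_cls, collapse = ", ")))
  }
  structure(
    list(n_frames = as.integer(n_frames), seed = as.integer(seed),
         n_residues = as.integer(n_residues), residue_types = residue_types,
         pucker_probs = per_res, linkage_torsions = linkage_torsions,
         noise_sd = noise_sd, frame_spacing = frame_spacing, q = q),
    class = "gag_ensemble_recipe"
  )
}

resolve_pucker_probs <- function(pucker_probs, residue_types) {
  n <- length(residue_types)
  if (!is.null(names(pucker_probs)) &&
      all(names(pucker_probs) %in% unique(residue_types))) {
    missing_t <- setdiff(unique(residue_types), names(pucker_probs))
    if (length(missing_t) > 0) {
      abort(paste0("pucker_probs missing residue type(s): ",
                   paste(missing_t, collapse = ", ")))
    }
    return(lapply(residue_types, function(t) pucker_probs[[t]]))
  }
  if (length(pucker_probs) != n) {
    abort("pucker_probs must be keyed by residue type or have one entry per residue")
  }
  pucker_probs
}

# linkage class labels donor(n+1)-acceptor(n) along a chain
linkage_class_of <- function(residue_types) {
  n <- length(residue_types)
  paste0(residue_types[2:n], "-", residue_types[1:(n - 1)])
}

#' Generate a stochastic synthetic ensemble
#'
#' Draws `n_frames` conformers: per-frame pucker states iid from the
#' per-residue probability vectors, glycosidic torsions from wrapped normal
#' (mixture) distributions per linkage class, chains assembled by
#' internal-coordinate placement, and iid Gaussian Cartesian noise added
#' last. Frames whose random torsions produce a steric clash are redrawn, so
#' every returned conformer is clash-free. Reproducible given the recipe
#' seed.
#'
#' @param recipe A `gag_ensemble_recipe`.
#' @return A `gag_ensemble`.
#' @export
generate_ensemble <- function(recipe) {
  stopifnot(inherits(recipe, "gag_ensemble_recipe"))
  set.seed(recipe$seed)
  classes <- linkage_class_of(recipe$residue_types)
  lt_by_class <- split(recipe$linkage_torsions,
                       recipe$linkage_torsions$linkage_class)
  frames <- vector("list", recipe$n_frames)
  for (f in seq_len(recipe$n_frames)) {
    # states are drawn once per frame and never resampled, so the generated
    # state marginals are exactly the recipe probabilities; only the torsion
    # draw is rejected on a steric clash
    states <- vapply(recipe$pucker_probs, function(p) {
      if (length(p) == 1) names(p) else sample(names(p), 1, prob = p)
    }, character(1))
    for (try in 1:50) {
      draw <- lapply(classes, function(cl) {
        comp <- lt_by_class[[cl]]
        i <- if (nrow(comp) > 1) {
          sample.int(nrow(comp), 1, prob = comp$weight)
        } else 1L
        c(phi = wrap_angle(rnorm(1, comp$mean_phi[i], comp$sd_phi[i])),
          psi = wrap_angle(rnorm(1, comp$mean_psi[i], comp$sd_psi[i])))
      })
      phi <- vapply(draw, `[[`, numeric(1), "phi")
      psi <- vapply(draw, `[[`, numeric(1), "psi")
      s <- tryCatch(
        build_chain(recipe$n_residues, phi, psi,
                    residue_types = recipe$residue_types,
                    pucker_states = states, q = recipe$q),
        error = function(e) NULL
      )
      if (!is.null(s)) break
    }
    if (is.null(s)) abort("could not draw a clash-free conformer in 50 tries")
    if (recipe$noise_sd > 0) {
      xyz <- coords(s)
      noise <- matrix(rnorm(length(xyz), 0, recipe$noise_sd), ncol = 3)
      s <- set_coords(s, xyz + noise)
    }
    frames[[f]] <- s
  }
  e <- gag_ensemble(frames, frame_spacing = recipe$frame_spacing)
  e
}
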