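# Pyranose ring pucker classification from the gamma/delta ring dihedrals.
#
# Each conformer of a residue's ring is assigned to 4C1, 1C4, 2SO, 1S3 or
# "other" by comparing gamma = C1-C2-C3-C4 and delta = C1-O5-C5-C4 against
# reference values inside circular windows of +/- half_width (default 23
# degrees, boundary inclusive). The references are derived geometrically
# from idealized rings at canonical Cremer-Pople coordinates, not read off
# a figure; see derive_pucker_references() and
# data-raw/derive-pucker-references.R.

#' Reference table for pucker classification
#'
#' Validates and labels a set of pucker-state references. Validation
#' requires every pair of reference points to be separated by more than
#' `half_width` degrees (circular) in at least one of the two coordinates,
#' so no reference lies inside another state's window. The 2SO and 1S3
#' skew-boats are adjacent on the pseudorotation equator and their +/-23
#' degree windows overlap in a corner region; points falling in more than
#' one window are resolved to the nearest reference (wrapped Euclidean
#' distance), so classification is always unique.
#'
#' @param refs Data frame with columns `state`, `gamma_ref`, `delta_ref`.
#' @param half_width Window half-width in degrees (default 23).
#' @return A `gag_pucker_refs` tibble.
#' @export
pucker_reference_set <- function(refs = gag_pucker_refs, half_width = 23) {
  refs <- as_tibble(refs)[c("state", "gamma_ref", "delta_ref")]
  if (anyDuplicated(refs$state)) abort("duplicate pucker state labels")
  refs$half_width <- half_width
  n <- nrow(refs)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dg <- circular_distance(refs$gamma_ref[i], refs$gamma_ref[j])
      dd <- circular_distance(refs$delta_ref[i], refs$delta_ref[j])
      if (max(dg, dd) <= half_width) {
        abort(sprintf(
          paste0("pucker references %s and %s are within one half-width in ",
                 "both coordinates (%.1f, %.1f deg); windows are ambiguous ",
                 "at the reference points themselves"),
          refs$state[i], refs$state[j], dg, dd))
      }
    }
  }
  class(refs) <- c("gag_pucker_refs", class(refs))
  refs
}

ring_atom_xyz <- function(s, residue_index) {
  rows <- s$residue_index == residue_index
  if (!any(rows)) abort(paste0("residue ", residue_index, " not found"))
  sub <- s[rows, ]
  missing <- setdiff(RING_ATOMS, sub$atom_name)
  if (length(missing) > 0) {
    abort(sprintf("residue %d (%s) is missing ring atom(s): %s",
                  residue_index, sub$residue_type[1],
                  paste(missing, collapse = ", ")))
  }
  xyz <- as.matrix(sub[match(RING_ATOMS, sub$atom_name), c("x", "y", "z")])
  rownames(xyz) <- RING_ATOMS
  xyz
}

#' Ring pucker dihedrals gamma and delta of one residue
#'
#' gamma is the ring torsion C1-C2-C3-C4 and delta the ring torsion
#' C1-O5-C5-C4, both in degrees on (-180, 180]. A perfectly planar ring has
#' gamma = delta = 0.
#'
#' @param s A `gag_structure`.
#' @param residue_index Residue whose ring to measure; must contain atoms
#'   C1..C5 and O5.
#' @return A one-row tibble with columns `gamma`, `delta`.
#' @export
compute_gamma_delta <- function(s, residue_index) {
  stopifnot(is_gag_structure(s))
  xyz <- ring_atom_xyz(s, residue_index)
  tibble(
    gamma = torsion_angle(xyz["C1", ], xyz["C2", ], xyz["C3", ], xyz["C4", ]),
    delta = torsion_angle(xyz["C1", ], xyz["O5", ], xyz["C5", ], xyz["C4", ])
  )
}

#' Classify ring pucker from gamma/delta dihedrals
#'
#' A conformer belongs to a state when both gamma and delta fall within the
#' state's circular window (reference +/- half_width, boundary inclusive).
#' Points inside no window are `"other"`; points inside more than one window
#' (possible only in the small 2SO/1S3 overlap corner) go to the nearest
#' reference.
#'
#' @param gamma,delta Numeric vectors of dihedrals in degrees.
#' @param refs A `gag_pucker_refs` table, by default the packaged derived
#'   references.
#' @return Character vector of state labels (`"other"` when unassigned).
#' @export
classify_pucker <- function(gamma, delta, refs = pucker_reference_set()) {
  stopifnot(inherits(refs, "gag_pucker_refs"), length(gamma) == length(delta))
  hw <- refs$half_width[1]
  dg <- outer(gamma, refs$gamma_ref, circular_distance)
  dd <- outer(delta, refs$delta_ref, circular_distance)
  inside <- dg <= hw & dd <= hw
  d2 <- dg^2 + dd^2
  d2[!inside] <- Inf
  hit <- apply(d2, 1, function(row) {
    if (all(is.infinite(row))) NA_integer_ else which.min(row)
  })
  out <- rep("other", length(gamma))
  out[!is.na(hit)] <- refs$state[hit[!is.na(hit)]]
  out
}

#' Per-residue pucker state populations over an ensemble
#'
#' Computes gamma/delta for every frame and residue, classifies each
#' conformer and tabulates state fractions per residue. Fractions per
#' residue sum to 1 (counts over frames), including the `"other"` category.
#'
#' @param e A `gag_ensemble`.
#' @param residues Residue indices to analyse; default all residues that
#'   carry a full set of ring atoms.
#' @param refs Classification references.
#' @return A `gag_pucker_populations` tibble with columns `residue_index`,
#'   `residue_type`, `state`, `count`, `fraction`, `n_frames`.
#' @export
pucker_populations <- function(e, residues = NULL,
                               refs = pucker_reference_set()) {
  stopifnot(is_gag_ensemble(e))
  topo <- e$topology
  if (is.null(residues)) {
    residues <- sort(unique(topo$residue_index[topo$atom_name %in% RING_ATOMS]))
    residues <- residues[vapply(residues, function(r) {
      all(RING_ATOMS %in% topo$atom_name[topo$residue_index == r])
    }, logical(1))]
  }
  if (length(residues) == 0) abort("no residues with complete rings")
  series <- pucker_series(e, residues, refs)
  levels_all <- c(refs$state, "other")
  out <- series |>
    group_by(.data$residue_index, .data$residue_type) |>
    count(state = factor(.data$state, levels = levels_all),
          .drop = FALSE, name = "count") |>
    ungroup() |>
    mutate(state = as.character(.data$state),
           n_frames = n_frames(e),
           fraction = .data$count / .data$n_frames)
  class(out) <- c("gag_pucker_populations", class(out))
  out
}

#' Per-frame pucker assignments for chosen residues
#'
#' @inheritParams pucker_populations
#' @return A tibble with columns `frame`, `residue_index`, `residue_type`,
#'   `gamma`, `delta`, `state`.
#' @export
pucker_series <- function(e, residues = NULL,
                          refs = pucker_reference_set()) {
  stopifnot(is_gag_ensemble(e))
  topo <- e$topology
  if (is.null(residues)) {
    residues <- sort(unique(topo$residue_index))
  }
  # resolve ring atom row indices once per residue
  ring_idx <- lapply(residues, function(r) {
    rows <- which(topo$residue_index == r)
    m <- match(RING_ATOMS, topo$atom_name[rows])
    if (anyNA(m)) {
      abort(sprintf("residue %d is missing ring atom(s): %s", r,
                    paste(RING_ATOMS[is.na(m)], collapse = ", ")))
    }
    rows[m]
  })
  nf <- n_frames(e)
  res <- lapply(seq_along(residues), function(ri) {
    idx <- ring_idx[[ri]]
    # frames x 3 coordinates of each named ring atom
    at <- lapply(seq_along(RING_ATOMS), function(a) t(e$xyz[idx[a], , ]))
    names(at) <- RING_ATOMS
    gamma <- torsion_angle(at$C1, at$C2, at$C3, at$C4)
    delta <- torsion_angle(at$C1, at$O5, at$C5, at$C4)
    rtype <- topo$residue_type[idx[1]]
    tibble(frame = seq_len(nf), residue_index = residues[ri],
           residue_type = rtype, gamma = gamma, delta = delta,
           state = classify_pucker(gamma, delta, refs))
  })
  dplyr::bind_rows(res)
}
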