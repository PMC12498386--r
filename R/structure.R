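#' Build a single-conformer structure
#'
#' A structure is a tidy atom table: one row per atom with its name, element,
#' mass, 1-based residue index, residue type label and Cartesian coordinates
#' in Angstrom. Residue 1 is the reducing end of a carbohydrate chain.
#'
#' @param atoms A data frame with columns `atom_name`, `element`, `mass`,
#'   `residue_index`, `residue_type`, `x`, `y`, `z`.
#' @return A `gag_structure` tibble.
#' @examples
#' s <- gag_structure(tibble::tibble(
#'   atom_name = c("C1", "O5"), element = c("C", "O"),
#'   mass = c(12.011, 15.999), residue_index = 1L,
#'   residue_type = "GlcNS(6S)", x = c(0, 1.4), y = 0, z = 0
#' ))
#' @export
gag_structure <- function(atoms) {
  required <- c("atom_name", "element", "mass", "residue_index",
                "residue_type", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(missing, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)[required]
  atoms$residue_index <- as.integer(atoms$residue_index)
  if (nrow(atoms) == 0) abort("structure must contain at least one atom")
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("all atom positions must be finite")
  if (!all(is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    abort("all atom masses must be positive and finite")
  }
  if (is.unsorted(atoms$residue_index)) {
    abort("residue_index must be non-decreasing along the atom list")
  }
  dup <- duplicated(atoms[c("residue_index", "atom_name")])
  if (any(dup)) {
    abort(paste0(
      "atom names must be unique within a residue; duplicated: ",
      paste(unique(paste0(atoms$residue_index[dup], "/", atoms$atom_name[dup])),
            collapse = ", ")
    ))
  }
  class(atoms) <- c("gag_structure", class(atoms))
  atoms
}

is_gag_structure <- function(x) inherits(x, "gag_structure")

#' Extract the coordinate matrix of a structure
#'
#' @param s A `gag_structure`.
#' @return An n x 3 numeric matrix (Angstrom), rows in atom order.
#' @export
coords <- function(s) {
  stopifnot(is_gag_structure(s))
  m <- as.matrix(s[c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

set_coords <- function(s, xyz) {
  s$x <- xyz[, 1]
  s$y <- xyz[, 2]
  s$z <- xyz[, 3]
  s
}

#' Build an ordered ensemble of conformers sharing one topology
#'
#' @param frames A list of `gag_structure` objects with identical topology
#'   (same atoms, order, names, masses), or a single structure.
#' @param frame_spacing Time between consecutive frames in ps.
#' @return A `gag_ensemble`: topology tibble plus an atoms x 3 x frames
#'   coordinate array.
#' @export
gag_ensemble <- function(frames, frame_spacing = 100) {
  if (is_gag_structure(frames)) frames <- list(frames)
  if (length(frames) < 1) abort("an ensemble needs at least one frame")
  if (!all(vapply(frames, is_gag_structure, logical(1)))) {
    abort("all frames must be gag_structure objects")
  }
  topo <- as_tibble(frames[[1]])[c("atom_name", "element", "mass",
                                   "residue_index", "residue_type")]
  for (i in seq_along(frames)) {
    ti <- as_tibble(frames[[i]])[names(topo)]
    if (!identical(dim(ti), dim(topo)) || !isTRUE(all.equal(ti, topo))) {
      abort(paste0("frame ", i, " does not share the ensemble topology"))
    }
  }
  xyz <- vapply(frames, coords, matrix(0, nrow(topo), 3))
  new_gag_ensemble(topo, xyz, frame_spacing)
}

new_gag_ensemble <- function(topology, xyz, frame_spacing) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  dimnames(xyz) <- NULL
  structure(
    list(topology = as_tibble(topology), xyz = xyz,
         frame_spacing = frame_spacing),
    class = "gag_ensemble"
  )
}

is_gag_ensemble <- function(x) inherits(x, "gag_ensemble")

#' Number of frames in an ensemble
#' @param e A `gag_ensemble`.
#' @export
n_frames <- function(e) {
  stopifnot(is_gag_ensemble(e))
  dim(e$xyz)[3]
}

#' Extract one frame of an ensemble as a structure
#' @param e A `gag_ensemble`.
#' @param i Frame index (1-based).
#' @export
ensemble_frame <- function(e, i) {
  stopifnot(is_gag_ensemble(e))
  if (i < 1 || i > n_frames(e)) abort(paste0("frame ", i, " out of range"))
  atoms <- e$topology
  atoms$x <- e$xyz[, 1, i]
  atoms$y <- e$xyz[, 2, i]
  atoms$z <- e$xyz[, 3, i]
  gag_structure(atoms)
}

#' Concatenate ensembles sharing one topology
#' @param ... `gag_ensemble` objects with identical topology.
#' @export
bind_ensembles <- function(...) {
  es <- list(...)
  stopifnot(length(es) >= 1)
  topo <- es[[1]]$topology
  for (e in es) {
    if (!isTRUE(all.equal(e$topology, topo))) {
      abort("ensembles do not share a topology")
    }
  }
  xyz <- array(
    unlist(lapply(es, function(e) e$xyz), use.names = FALSE),
    dim = c(nrow(topo), 3, sum(vapply(es, n_frames, integer(1))))
  )
  new_gag_ensemble(topo, xyz, es[[1]]$frame_spacing)
}

#' @export
print.gag_ensemble <- function(x, ...) {
  cat(sprintf(
    "<gag_ensemble> %d frames x %d atoms (%d residues), frame spacing %g ps\n",
    n_frames(x), nrow(x$topology), length(unique(x$topology$residue_index)),
    x$frame_spacing
  ))
  invisible(x)
}

# ---- atom selection ---------------------------------------------------------

# Resolve a tidy selection expression over the atom table to row indices.
# `sel_quo` is a quosure over (atom_name, element, mass, residue_index,
# residue_type); NULL selects every atom.
resolve_selection <- function(topology, sel_quo, allow_empty = FALSE) {
  if (quo_is_null(sel_quo)) {
    idx <- seq_len(nrow(topology))
  } else {
    keep <- eval_tidy(sel_quo, data = topology)
    if (!is.logical(keep) && !is.numeric(keep)) {
      abort("selection must evaluate to a logical or index vector")
    }
    idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  }
  if (!allow_empty && length(idx) == 0) {
    abort("atom selection resolved to an empty set")
  }
  idx
}

topology_of <- function(x) {
  if (is_gag_ensemble(x)) x$topology else as_tibble(x)
}
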