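# Glycosidic linkage analysis: phi/psi torsion extraction per the
# carbohydrate convention phi = O5(n+1)-C1(n+1)-O4(n)-C4(n),
# psi = C1(n+1)-O4(n)-C4(n)-C3(n), population heatmaps on the torus and
# mode (population maximum) location. Residue n is counted from the
# reducing end; residue n+1 is the glycosyl donor on the nonreducing side.

GLYCOSIDIC_BOND_MAX <- 1.8  # Angstrom, O4(n)-C1(n+1) bonded check

#' Detect glycosidic linkages in a chain
#'
#' Scans adjacent residue pairs and records a linkage wherever residue n's
#' O4 is bonded (distance < 1.8 Angstrom) to residue n+1's C1. The linkage
#' class is `"<donor type>-<acceptor type>"`, donor first.
#'
#' @param s A `gag_structure`.
#' @return A `gag_linkages` tibble with columns `donor_residue`,
#'   `acceptor_residue`, `linkage_class`.
#' @export
detect_linkages <- function(s) {
  stopifnot(is_gag_structure(s))
  res <- sort(unique(s$residue_index))
  out <- list()
  for (n in res) {
    if (!((n + 1) %in% res)) next
    o4 <- atom_xyz(s, n, "O4")
    c1 <- atom_xyz(s, n + 1, "C1")
    if (is.null(o4) || is.null(c1)) next
    if (sqrt(sum((o4 - c1)^2)) < GLYCOSIDIC_BOND_MAX) {
      out[[length(out) + 1]] <- tibble(
        donor_residue = n + 1L, acceptor_residue = as.integer(n),
        linkage_class = paste0(
          s$residue_type[s$residue_index == n + 1][1], "-",
          s$residue_type[s$residue_index == n][1]
        )
      )
    }
  }
  links <- if (length(out) > 0) dplyr::bind_rows(out) else {
    tibble(donor_residue = integer(), acceptor_residue = integer(),
           linkage_class = character())
  }
  class(links) <- c("gag_linkages", class(links))
  links
}

atom_xyz <- function(s, residue_index, atom_name) {
  i <- which(s$residue_index == residue_index & s$atom_name == atom_name)
  if (length(i) == 0) return(NULL)
  as.numeric(c(s$x[i], s$y[i], s$z[i]))
}

require_atom <- function(s, residue_index, atom_name, link_label) {
  p <- atom_xyz(s, residue_index, atom_name)
  if (is.null(p)) {
    abort(sprintf("linkage %s: residue %d is missing atom %s",
                  link_label, residue_index, atom_name))
  }
  p
}

#' Glycosidic phi/psi torsions of one linkage
#'
#' phi = torsion(O5(n+1), C1(n+1), O4(n), C4(n));
#' psi = torsion(C1(n+1), O4(n), C4(n), C3(n)), degrees on (-180, 180].
#'
#' @param s A `gag_structure`.
#' @param donor_residue Index n+1 of the glycosyl donor.
#' @param acceptor_residue Index n of the acceptor carrying O4; defaults to
#'   `donor_residue - 1`.
#' @return A one-row tibble with columns `phi`, `psi`.
#' @export
compute_phi_psi <- function(s, donor_residue,
                            acceptor_residue = donor_residue - 1L) {
  stopifnot(is_gag_structure(s))
  lab <- paste0(donor_residue, "->", acceptor_residue)
  o5 <- require_atom(s, donor_residue, "O5", lab)
  c1 <- require_atom(s, donor_residue, "C1", lab)
  o4 <- require_atom(s, acceptor_residue, "O4", lab)
  c4 <- require_atom(s, acceptor_residue, "C4", lab)
  c3 <- require_atom(s, acceptor_residue, "C3", lab)
  if (sqrt(sum((o4 - c1)^2)) >= GLYCOSIDIC_BOND_MAX) {
    abort(sprintf("linkage %s: O4 and C1 are not bonded (>= %.1f Angstrom)",
                  lab, GLYCOSIDIC_BOND_MAX))
  }
  tibble(
    phi = torsion_angle(o5, c1, o4, c4),
    psi = torsion_angle(c1, o4, c4, c3)
  )
}

#' Per-frame glycosidic torsion series for an ensemble
#'
#' Computes phi/psi for every linkage in every frame. With
#' `aggregate_by_class = TRUE` (the analysis default), linkages of the same
#' class are pooled so each class yields one series of length
#' frames x linkages-of-that-class.
#'
#' @param e A `gag_ensemble`.
#' @param links Linkage table from [detect_linkages()]; default detects
#'   linkages on the first frame.
#' @param aggregate_by_class Pool same-class linkages into one series?
#' @return A `gag_torsion_series` tibble with columns `frame`,
#'   `donor_residue`, `acceptor_residue`, `linkage_class`, `phi`, `psi`.
#' @export
linkage_series <- function(e, links = NULL, aggregate_by_class = TRUE) {
  stopifnot(is_gag_ensemble(e))
  if (is.null(links)) links <- detect_linkages(ensemble_frame(e, 1))
  if (nrow(links) == 0) abort("no glycosidic linkages to analyse")
  topo <- e$topology
  nf <- n_frames(e)
  row_of <- function(res, name) {
    i <- which(topo$residue_index == res & topo$atom_name == name)
    if (length(i) == 0) {
      abort(sprintf("linkage %d->%d: residue %d is missing atom %s",
                    res + 1L, res, res, name))
    }
    i
  }
  frames_xyz <- function(i) t(e$xyz[i, , , drop = TRUE])
  out <- lapply(seq_len(nrow(links)), function(k) {
    dn <- links$donor_residue[k]; ac <- links$acceptor_residue[k]
    o5 <- frames_xyz(row_of(dn, "O5")); c1 <- frames_xyz(row_of(dn, "C1"))
    o4 <- frames_xyz(row_of(ac, "O4")); c4 <- frames_xyz(row_of(ac, "C4"))
    c3 <- frames_xyz(row_of(ac, "C3"))
    if (nf == 1) {
      o5 <- matrix(o5, 1); c1 <- matrix(c1, 1); o4 <- matrix(o4, 1)
      c4 <- matrix(c4, 1); c3 <- matrix(c3, 1)
    }
    tibble(
      frame = seq_len(nf), donor_residue = dn, acceptor_residue = ac,
      linkage_class = links$linkage_class[k],
      phi = torsion_angle(o5, c1, o4, c4),
      psi = torsion_angle(c1, o4, c4, c3)
    )
  })
  series <- dplyr::bind_rows(out)
  if (!aggregate_by_class) {
    series <- arrange(series, .data$donor_residue, .data$frame)
  } else {
    series <- arrange(series, .data$linkage_class, .data$frame,
                      .data$donor_residue)
  }
  class(series) <- c("gag_torsion_series", class(series))
  series
}

#' 2D population histogram of phi/psi torsions on the torus
#'
#' Bins angle pairs over (-180, 180]^2 with periodic wrap-around. The bin
#' width must divide 360.
#'
#' @param data Data frame holding the torsion columns (e.g. the output of
#'   [linkage_series()], optionally filtered to one class).
#' @param phi,psi Columns holding the angles (tidy evaluation; default
#'   `phi`, `psi`).
#' @param bin_width Bin width in degrees (default 5).
#' @return A `gag_torsion_heatmap` with integer `counts`, normalized
#'   `fraction`, bin edges and centers.
#' @export
torsion_heatmap <- function(data, phi = phi, psi = psi, bin_width = 5) {
  phi_v <- wrap_angle(eval_tidy(enquo(phi), data = data))
  psi_v <- wrap_angle(eval_tidy(enquo(psi), data = data))
  if (length(phi_v) != length(psi_v)) abort("phi and psi differ in length")
  if (length(phi_v) == 0) abort("no angles to bin")
  nb <- 360 / bin_width
  if (abs(nb - round(nb)) > 1e-9) abort("bin_width must divide 360")
  nb <- as.integer(round(nb))
  ix <- bin_index(phi_v, bin_width, nb)
  iy <- bin_index(psi_v, bin_width, nb)
  counts <- matrix(0L, nb, nb)
  tab <- table(factor(ix, levels = seq_len(nb)),
               factor(iy, levels = seq_len(nb)))
  counts <- matrix(as.integer(tab), nb, nb)
  edges <- seq(-180, 180, by = bin_width)
  centers <- edges[-1] - bin_width / 2
  structure(
    list(counts = counts, fraction = counts / length(phi_v),
         phi_edges = edges, psi_edges = edges,
         phi_centers = centers, psi_centers = centers,
         bin_width = bin_width, n = length(phi_v)),
    class = "gag_torsion_heatmap"
  )
}

# bins are (edge, edge]; -180 wraps to +180 which lands in the last bin
bin_index <- function(ang, bin_width, nb) {
  i <- ceiling((ang + 180) / bin_width)
  i[i < 1] <- 1L
  i[i > nb] <- nb
  as.integer(i)
}

#' @export
print.gag_torsion_heatmap <- function(x, ...) {
  cat(sprintf("<gag_torsion_heatmap> %d x %d bins (%g deg), n = %d\n",
              nrow(x$counts), ncol(x$counts), x$bin_width, x$n))
  invisible(x)
}

#' Locate population modes of a torsion heatmap on the torus
#'
#' A mode is a bin whose fraction is strictly greater than each of its 8
#' neighbours under periodic wrap (so a peak straddling the +/-180 seam is
#' found exactly once), with fraction >= `min_fraction`. Modes are reported
#' at bin centers, sorted by descending fraction. An optional 3 x 3 periodic
#' mean filter can be applied for detection (off by default so results are
#' a deterministic function of the raw counts).
#'
#' @param h A `gag_torsion_heatmap`.
#' @param min_fraction Minimum bin fraction for a reported mode.
#' @param smooth Apply a 3 x 3 periodic mean filter before detection?
#' @return A tibble with columns `phi_mode`, `psi_mode`, `fraction`
#'   (fraction is the raw bin fraction at the mode).
#' @export
find_modes <- function(h, min_fraction = 0.01, smooth = FALSE) {
  stopifnot(inherits(h, "gag_torsion_heatmap"))
  if (h$n == 0 || sum(h$counts) == 0) abort("empty heatmap")
  f <- h$fraction
  det <- if (smooth) periodic_mean_filter(f) else f
  nb <- nrow(f)
  sh <- function(m, di, dj) {
    m[(seq_len(nb) - 1 + di) %% nb + 1, (seq_len(nb) - 1 + dj) %% nb + 1]
  }
  is_peak <- matrix(TRUE, nb, nb)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_peak <- is_peak & (det > sh(det, di, dj))
  }
  keep <- which(is_peak & f >= min_fraction, arr.ind = TRUE)
  out <- tibble(
    phi_mode = h$phi_centers[keep[, 1]],
    psi_mode = h$psi_centers[keep[, 2]],
    fraction = f[keep]
  )
  arrange(out, dplyr::desc(.data$fraction))
}

periodic_mean_filter <- function(m) {
  nb <- nrow(m)
  out <- matrix(0, nb, nb)
  for (di in -1:1) for (dj in -1:1) {
    out <- out + m[(seq_len(nb) - 1 + di) %% nb + 1,
                   (seq_len(nb) - 1 + dj) %% nb + 1]
  }
  out / 9
}
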