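# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a torsion heatmap into long format
#'
#' @param x A `gag_torsion_heatmap`.
#' @param ... Unused.
#' @return A tibble with columns `phi_center`, `psi_center`, `count`,
#'   `fraction`.
#' @method tidy gag_torsion_heatmap
#' @export
tidy.gag_torsion_heatmap <- function(x, ...) {
  grid <- expand.grid(phi_center = x$phi_centers, psi_center = x$psi_centers,
                      KEEP.OUT.ATTRS = FALSE)
  tibble(
    phi_center = grid$phi_center, psi_center = grid$psi_center,
    count = as.integer(x$counts), fraction = as.vector(x$fraction)
  )
}

#' Tidy a pairwise RMSD matrix into long format
#'
#' @param x A `gag_rmsd_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `frame_i`, `frame_j`, `rmsd`.
#' @method tidy gag_rmsd_matrix
#' @export
tidy.gag_rmsd_matrix <- function(x, ...) {
  n <- length(x$frames)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  tibble(
    frame_i = x$frames[grid$i], frame_j = x$frames[grid$j],
    rmsd = as.vector(x$values)
  )
}

#' Tidy an inter-residue distance map into long format
#'
#' @param x A `gag_distance_map`.
#' @param ... Unused.
#' @return A tibble with columns `residue_i`, `residue_j`, `distance`.
#' @method tidy gag_distance_map
#' @export
tidy.gag_distance_map <- function(x, ...) {
  n <- length(x$residues)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  tibble(
    residue_i = x$residues[grid$i], residue_j = x$residues[grid$j],
    distance = as.vector(x$values)
  )
}

#' Tidy a descriptor correlation matrix into long format
#'
#' @param x A `gag_correlation`.
#' @param ... Unused.
#' @return A tibble with columns `var_x`, `var_y`, `correlation`.
#' @method tidy gag_correlation
#' @export
tidy.gag_correlation <- function(x, ...) {
  m <- unclass(x)
  grid <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)),
                      KEEP.OUT.ATTRS = FALSE)
  tibble(
    var_x = rownames(m)[grid$i], var_y = colnames(m)[grid$j],
    correlation = as.vector(m)
  )
}

#' One-row summary of a descriptor table
#'
#' Means and standard deviations (sample, n - 1) of the RMSD, Rg and EED
#' series, in Angstrom.
#'
#' @param x A `gag_descriptors` table.
#' @param ... Unused.
#' @method glance gag_descriptors
#' @export
glance.gag_descriptors <- function(x, ...) {
  tibble(
    n_frames = nrow(x),
    rmsd_mean = mean(x$rmsd), rmsd_sd = sd(x$rmsd),
    rg_mean = mean(x$rg), rg_sd = sd(x$rg),
    eed_mean = mean(x$eed), eed_sd = sd(x$eed)
  )
}
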