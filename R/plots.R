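# ggplot2 visualisations of the result objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot descriptor time series
#'
#' RMSD, Rg and EED against simulation time, one facet per descriptor.
#'
#' @param object A `gag_descriptors` table.
#' @param ... Unused.
#' @method autoplot gag_descriptors
#' @export
autoplot.gag_descriptors <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("rmsd", "rg", "eed"),
                              names_to = "descriptor", values_to = "value")
  long$descriptor <- factor(long$descriptor, levels = c("rmsd", "rg", "eed"),
                            labels = c("RMSD (Å)", "Rg (Å)",
                                       "EED (Å)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ps / 1000,
                                     y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~descriptor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ns)", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot a glycosidic torsion population heatmap
#'
#' @param object A `gag_torsion_heatmap`.
#' @param ... Unused.
#' @method autoplot gag_torsion_heatmap
#' @export
autoplot.gag_torsion_heatmap <- function(object, ...) {
  d <- tidy(object)
  d$fraction[d$fraction == 0] <- NA
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phi_center, y = .data$psi_center,
                                  fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-180, 180),
                         expand = FALSE) +
    ggplot2::labs(x = expression(phi ~ "(deg)"), y = expression(psi ~ "(deg)"),
                  fill = "fraction") +
    ggplot2::theme_bw()
}

#' Plot a pairwise RMSD matrix
#'
#' @param object A `gag_rmsd_matrix`.
#' @param ... Unused.
#' @method autoplot gag_rmsd_matrix
#' @export
autoplot.gag_rmsd_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame_i, y = .data$frame_j,
                                  fill = .data$rmsd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "frame", y = "frame", fill = "RMSD (Å)") +
    ggplot2::theme_bw()
}

#' Plot per-residue pucker state populations
#'
#' Stacked per-residue fractions of the classified ring conformations.
#'
#' @param object A `gag_pucker_populations` table.
#' @param ... Unused.
#' @method autoplot gag_pucker_populations
#' @export
autoplot.gag_pucker_populations <- function(object, ...) {
  d <- as_tibble(object)
  d$state <- factor(d$state, levels = c("4C1", "1C4", "2SO", "1S3", "other"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$residue_index),
                                  y = .data$fraction, fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue", y = "fraction", fill = "pucker") +
    ggplot2::theme_bw()
}

#' Plot a descriptor correlation matrix
#'
#' @param object A `gag_correlation`.
#' @param ... Unused.
#' @method autoplot gag_correlation
#' @export
autoplot.gag_correlation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var_x, y = .data$var_y,
                                  fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$correlation))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
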