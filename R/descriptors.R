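# Global shape descriptors over an ensemble: RMSD time series against the
# first frame, pairwise RMSD matrices, radius of gyration, end-to-end
# distance between terminal residue centers of mass, inter-residue distance
# maps, summary statistics and descriptor correlations.

frame_xyz <- function(e, i) e$xyz[, , i]

#' RMSD time series relative to the first frame
#'
#' Each frame is optimally superposed (Kabsch, mass-weighted by default)
#' onto the reference frame before the RMSD is taken, so the series measures
#' internal deformation, not rigid-body motion. Element 1 is exactly 0.
#'
#' @param e A `gag_ensemble` (>= 2 frames for a meaningful series).
#' @param sel Optional tidy atom selection (default all atoms).
#' @param mass_weighted Mass-weight the fit and the RMSD? Default `TRUE`.
#' @param reference_frame Frame used as the reference (default 1).
#' @return Numeric vector of RMSD values in Angstrom, one per frame.
#' @export
rmsd_timeseries <- function(e, sel = NULL, mass_weighted = TRUE,
                            reference_frame = 1L) {
  stopifnot(is_gag_ensemble(e))
  idx <- resolve_selection(e$topology, enquo(sel))
  w <- if (mass_weighted) e$topology$mass[idx] else rep(1, length(idx))
  ref <- frame_xyz(e, reference_frame)[idx, , drop = FALSE]
  vapply(seq_len(n_frames(e)), function(i) {
    if (i == reference_frame) return(0)
    superpose_xyz(frame_xyz(e, i)[idx, , drop = FALSE], ref, w)$rmsd
  }, numeric(1))
}

#' Pairwise RMSD matrix over (strided) frames
#'
#' Entry (i, j) is the optimally superposed RMSD between strided frames i
#' and j; the matrix is symmetric with a zero diagonal. Because each pair is
#' fitted independently, the triangle inequality is not guaranteed. The
#' default stride keeps the matrix at most `max_dim` x `max_dim`.
#'
#' @inheritParams rmsd_timeseries
#' @param stride Keep every `stride`-th frame (default chosen so the matrix
#'   is at most `max_dim` on a side).
#' @param max_dim Cap on the matrix dimension used to pick the default
#'   stride.
#' @return A `gag_rmsd_matrix`: list with `values` (Angstrom), `frames`
#'   (original frame indices) and `stride`.
#' @export
rmsd_matrix <- function(e, sel = NULL, stride = NULL, mass_weighted = TRUE,
                        max_dim = 2000) {
  stopifnot(is_gag_ensemble(e))
  nf <- n_frames(e)
  if (is.null(stride)) stride <- max(1L, ceiling(nf / max_dim))
  if (stride < 1) abort("stride must be >= 1")
  if (stride > nf) abort("stride larger than the number of frames")
  keep <- seq(1L, nf, by = stride)
  idx <- resolve_selection(e$topology, enquo(sel))
  w <- if (mass_weighted) e$topology$mass[idx] else rep(1, length(idx))
  xs <- lapply(keep, function(i) frame_xyz(e, i)[idx, , drop = FALSE])
  m <- length(keep)
  vals <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      vals[i, j] <- vals[j, i] <- superpose_xyz(xs[[j]], xs[[i]], w)$rmsd
    }
  }
  structure(list(values = vals, frames = keep, stride = stride),
            class = "gag_rmsd_matrix")
}

#' @export
print.gag_rmsd_matrix <- function(x, ...) {
  cat(sprintf("<gag_rmsd_matrix> %d x %d frames (stride %d)\n",
              nrow(x$values), ncol(x$values), x$stride))
  invisible(x)
}

#' End-to-end distance series
#'
#' Per-frame Euclidean distance between the mass-weighted centers of mass
#' of the two terminal monosaccharide residues.
#'
#' @param e A `gag_ensemble`.
#' @param terminal_a,terminal_b Residue indices of the termini; default the
#'   first and last residues present.
#' @return Numeric vector in Angstrom, one value per frame.
#' @export
eed_series <- function(e, terminal_a = NULL, terminal_b = NULL) {
  stopifnot(is_gag_ensemble(e))
  res <- sort(unique(e$topology$residue_index))
  if (is.null(terminal_a)) terminal_a <- res[1]
  if (is.null(terminal_b)) terminal_b <- res[length(res)]
  ia <- which(e$topology$residue_index == terminal_a)
  ib <- which(e$topology$residue_index == terminal_b)
  if (length(ia) == 0) abort(paste0("residue ", terminal_a, " not found"))
  if (length(ib) == 0) abort(paste0("residue ", terminal_b, " not found"))
  wa <- e$topology$mass[ia]; wb <- e$topology$mass[ib]
  vapply(seq_len(n_frames(e)), function(i) {
    xyz <- frame_xyz(e, i)
    ca <- weighted_centroid(xyz[ia, , drop = FALSE], wa)
    cb <- weighted_centroid(xyz[ib, , drop = FALSE], wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
}

#' Radius of gyration series
#'
#' @inheritParams rmsd_timeseries
#' @return Numeric vector in Angstrom, one value per frame.
#' @export
rg_series <- function(e, sel = NULL) {
  stopifnot(is_gag_ensemble(e))
  idx <- resolve_selection(e$topology, enquo(sel))
  w <- e$topology$mass[idx]
  vapply(seq_len(n_frames(e)), function(i) {
    rg_of(frame_xyz(e, i)[idx, , drop = FALSE], w)
  }, numeric(1))
}

#' Mean inter-residue center-of-mass distance map
#'
#' Symmetric matrix of residue-residue COM distances averaged over frames.
#'
#' @param e A `gag_ensemble`.
#' @return A `gag_distance_map`: list with `values` (Angstrom, residues x
#'   residues) and `residues`.
#' @export
residue_distance_map <- function(e) {
  stopifnot(is_gag_ensemble(e))
  res <- sort(unique(e$topology$residue_index))
  idxs <- lapply(res, function(r) which(e$topology$residue_index == r))
  ws <- lapply(idxs, function(i) e$topology$mass[i])
  nr <- length(res)
  acc <- matrix(0, nr, nr)
  for (f in seq_len(n_frames(e))) {
    xyz <- frame_xyz(e, f)
    coms <- t(vapply(seq_len(nr), function(k) {
      weighted_centroid(xyz[idxs[[k]], , drop = FALSE], ws[[k]])
    }, numeric(3)))
    acc <- acc + as.matrix(stats::dist(coms))
  }
  structure(list(values = acc / n_frames(e), residues = res),
            class = "gag_distance_map")
}

#' Mean and standard deviation of a descriptor series
#'
#' @param x Numeric series (non-empty).
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n).
#' @return A one-row tibble with columns `mean`, `sd`, `n`.
#' @export
summary_stats <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(x) == 0) abort("empty series")
  n <- length(x)
  m <- mean(x)
  s <- if (n == 1) 0 else {
    v <- sum((x - m)^2) / if (sd_type == "sample") (n - 1) else n
    sqrt(v)
  }
  tibble(mean = m, sd = s, n = n)
}

#' Compute the standard descriptor table for an ensemble
#'
#' Per-frame RMSD versus the first frame (after optimal superposition),
#' radius of gyration and end-to-end distance, aligned on frame index.
#'
#' @inheritParams rmsd_timeseries
#' @inheritParams eed_series
#' @return A `gag_descriptors` tibble with columns `frame`, `time_ps`,
#'   `rmsd`, `rg`, `eed`.
#' @export
compute_descriptors <- function(e, sel = NULL, mass_weighted = TRUE,
                                terminal_a = NULL, terminal_b = NULL) {
  stopifnot(is_gag_ensemble(e))
  sel_quo <- enquo(sel)
  idx <- resolve_selection(e$topology, sel_quo)
  w <- if (mass_weighted) e$topology$mass[idx] else rep(1, length(idx))
  ref <- frame_xyz(e, 1)[idx, , drop = FALSE]
  nf <- n_frames(e)
  rmsd <- vapply(seq_len(nf), function(i) {
    if (i == 1) return(0)
    superpose_xyz(frame_xyz(e, i)[idx, , drop = FALSE], ref, w)$rmsd
  }, numeric(1))
  rg <- vapply(seq_len(nf), function(i) {
    rg_of(frame_xyz(e, i)[idx, , drop = FALSE], e$topology$mass[idx])
  }, numeric(1))
  out <- tibble(
    frame = seq_len(nf),
    time_ps = (seq_len(nf) - 1) * e$frame_spacing,
    rmsd = rmsd, rg = rg,
    eed = eed_series(e, terminal_a, terminal_b)
  )
  class(out) <- c("gag_descriptors", class(out))
  out
}

#' Pearson correlations between the RMSD, Rg and EED series
#'
#' @param t A `gag_descriptors` table (or any data frame with columns
#'   `rmsd`, `rg`, `eed`) with at least 3 rows.
#' @return A `gag_correlation`: symmetric 3 x 3 Pearson correlation matrix
#'   with unit diagonal.
#' @export
descriptor_correlations <- function(t) {
  cols <- c("rmsd", "rg", "eed")
  missing <- setdiff(cols, names(t))
  if (length(missing) > 0) {
    abort(paste0("descriptor table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(t)[cols])
  if (nrow(m) < 3) abort("need at least 3 frames for correlations")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant column(s): ",
                 paste(cols[sds == 0], collapse = ", "),
                 "; correlation undefined"))
  }
  cm <- cor(m)
  structure(cm, class = c("gag_correlation", class(cm)))
}
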