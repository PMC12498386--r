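# Ensemble readers/writers (multi-model PDB via bio3d, plain XYZ) and the
# end-to-end analysis pipeline. Coordinates are Angstrom throughout; readers
# for formats that use nm must convert at the boundary.

# default mapping between PDB residue names and residue type labels
DEFAULT_RESIDUE_MAP <- c(
  SGN = "GlcNS(6S)",  # N,6-O-disulfo-glucosamine
  IDS = "IdoA(2S)"    # 2-O-sulfo-iduronic acid
)

residue_type_to_resid <- function(types, residue_map = DEFAULT_RESIDUE_MAP) {
  inv <- setNames(names(residue_map), residue_map)
  out <- unname(inv[types])
  out[is.na(out)] <- substr(types[is.na(out)], 1, 3)
  toupper(out)
}

#' Read a coordinate ensemble
#'
#' Multi-model PDB files are parsed with bio3d; XYZ files with a built-in
#' reader. XYZ carries no residue records, so residues are reconstructed by
#' starting a new residue (type `"UNK"`) whenever an atom name repeats.
#' Topology consistency across frames is enforced and masses are assigned
#' from the element.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param frame_spacing Frame spacing in ps recorded on the ensemble.
#' @param residue_map Named character vector mapping PDB residue names to
#'   residue type labels (default maps SGN and IDS to GlcNS(6S) and
#'   IdoA(2S)).
#' @return A `gag_ensemble`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz"),
                          frame_spacing = 100,
                          residue_map = DEFAULT_RESIDUE_MAP) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "pdb"
  }
  switch(format,
         pdb = read_pdb_ensemble(path, frame_spacing, residue_map),
         xyz = read_xyz_ensemble(path, frame_spacing))
}

read_pdb_ensemble <- function(path, frame_spacing, residue_map) {
  # pre-validate MODEL blocks so truncated files fail loudly, not partially
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grepl("^(ATOM|HETATM)", lines)
  n_models <- sum(grepl("^MODEL", lines))
  n_endmdl <- sum(grepl("^ENDMDL", lines))
  if (n_models > 0 && n_models != n_endmdl) {
    abort(sprintf(
      "truncated multi-model PDB: %d MODEL but %d ENDMDL records in %s",
      n_models, n_endmdl, path))
  }
  if (!any(atom_lines)) abort(paste0("no ATOM/HETATM records in ", path))
  if (n_models > 1) {
    counts <- table(cumsum(grepl("^MODEL", lines))[atom_lines])
    if (length(unique(as.integer(counts))) != 1) {
      abort(sprintf(
        "inconsistent atom counts across models in %s (model %s)",
        path, names(counts)[which(as.integer(counts) != counts[[1]])[1]]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  elesy <- atom$elesy
  guess <- toupper(substr(gsub("[0-9']", "", atom$elety), 1, 1))
  element <- ifelse(!is.na(elesy) & nzchar(trimws(elesy)),
                    trimws(elesy), guess)
  rtype <- unname(residue_map[atom$resid])
  rtype[is.na(rtype)] <- atom$resid[is.na(rtype)]
  topo <- tibble(
    atom_name = trimws(atom$elety),
    element = element,
    mass = element_mass(element),
    residue_index = as.integer(as.integer(factor(
      paste(atom$chain, atom$resno), levels = unique(paste(atom$chain, atom$resno))
    ))),
    residue_type = rtype
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  arr <- array(0, dim = c(nrow(topo), 3, nf))
  for (i in seq_len(nf)) {
    arr[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  }
  new_gag_ensemble(topo, arr, frame_spacing)
}

read_xyz_ensemble <- function(path, frame_spacing) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      abort(sprintf("XYZ parse error at line %d of %s: expected atom count",
                    i, path))
    }
    if (i + 1 + nat > length(lines)) {
      abort(sprintf("truncated XYZ file %s: frame starting at line %d needs %d atoms",
                    path, i, nat))
    }
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4)) {
      abort(sprintf("XYZ parse error in %s near line %d", path, i + 2))
    }
    name <- vapply(parts, `[[`, character(1), 1)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (!all(is.finite(xyz))) {
      abort(sprintf("XYZ parse error in %s near line %d: bad coordinates",
                    path, i + 2))
    }
    element <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
    # XYZ carries no residue records: start a new residue whenever an atom
    # name repeats within the current one
    res <- integer(length(name))
    cur <- 1L
    seen <- character(0)
    for (k in seq_along(name)) {
      if (name[k] %in% seen) {
        cur <- cur + 1L
        seen <- character(0)
      }
      seen <- c(seen, name[k])
      res[k] <- cur
    }
    frames[[length(frames) + 1]] <- gag_structure(tibble(
      atom_name = name, element = element, mass = element_mass(element),
      residue_index = res, residue_type = "UNK",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    ))
    i <- i + 2 + nat
  }
  if (length(frames) == 0) abort(paste0("no frames in ", path))
  gag_ensemble(frames, frame_spacing = frame_spacing)
}

#' Write a coordinate ensemble
#'
#' Multi-model PDB (one MODEL/ENDMDL block per frame, coordinates to 0.001
#' Angstrom) or plain XYZ. Pseudo-atom masses are not representable in
#' either format; on re-reading, masses are reassigned from the element.
#'
#' @param e A `gag_ensemble`.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param residue_map Mapping used to translate residue type labels back to
#'   PDB residue names.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path, format = c("auto", "pdb", "xyz"),
                           residue_map = DEFAULT_RESIDUE_MAP) {
  stopifnot(is_gag_ensemble(e))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "pdb"
  }
  if (format == "pdb") write_pdb_ensemble(e, path, residue_map)
  else write_xyz_ensemble(e, path)
  invisible(path)
}

write_pdb_ensemble <- function(e, path, residue_map) {
  topo <- e$topology
  resid <- residue_type_to_resid(topo$residue_type, residue_map)
  name4 <- ifelse(nchar(topo$atom_name) < 4,
                  sprintf(" %-3s", topo$atom_name),
                  substr(topo$atom_name, 1, 4))
  nf <- n_frames(e)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- e$xyz[, , f]
    rec <- sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(topo)), name4, resid, topo$residue_index,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, topo$element)
    writeLines(rec, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_xyz_ensemble <- function(e, path) {
  topo <- e$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(e))) {
    xyz <- e$xyz[, , f]
    writeLines(as.character(nrow(topo)), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                       topo$atom_name, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
}

# ---- pipeline ---------------------------------------------------------------

#' Default pipeline configuration
#'
#' Defaults reproduce the analysis conventions used throughout the package:
#' +/-23 degree pucker windows, 5 degree torsion bins, mass-weighted RMSD,
#' sample (n - 1) standard deviations.
#'
#' @param input Path to an ensemble file, or `NULL` to generate a synthetic
#'   ensemble from `synth`.
#' @param format Input format passed to [read_ensemble()].
#' @param synth List of [ensemble_recipe()] arguments used when `input` is
#'   `NULL` (must include `n_frames`; `seed` defaults to `seed`).
#' @param seed Integer seed for synthetic generation.
#' @param pucker_half_width Classification window half-width (degrees).
#' @param bin_width Torsion heatmap bin width (degrees).
#' @param stride RMSD matrix stride (`NULL` = automatic).
#' @param sd_type `"sample"` or `"population"` standard deviations.
#' @param mass_weighted Mass-weight superpositions?
#' @param min_mode_fraction Threshold for reported torsion modes.
#' @param output_dir Directory the CSV outputs and manifest are written to.
#' @return A `gag_run_config` list.
#' @export
run_config <- function(input = NULL, format = "auto", synth = list(),
                       seed = 1L, pucker_half_width = 23, bin_width = 5,
                       stride = NULL, sd_type = "sample",
                       mass_weighted = TRUE, min_mode_fraction = 0.01,
                       output_dir = "gagdyn-run") {
  cfg <- list(input = input, format = format, synth = synth,
              seed = as.integer(seed), pucker_half_width = pucker_half_width,
              bin_width = bin_width, stride = stride, sd_type = sd_type,
              mass_weighted = mass_weighted,
              min_mode_fraction = min_mode_fraction,
              output_dir = output_dir)
  class(cfg) <- "gag_run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of [run_config()] fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

pipeline_stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
  message(sprintf("[gagdyn] %-12s %6.2f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full conformational-analysis pipeline
#'
#' Loads (or synthesizes) an ensemble, then computes and writes the
#' descriptor table and summary statistics, per-residue pucker populations,
#' glycosidic torsion series, per-class torsion heatmaps and modes, the
#' pairwise RMSD matrix, the mean inter-residue distance map and the
#' descriptor correlation matrix, all as CSV, plus a reproducibility
#' manifest (inputs hashed, configuration echoed, package version).
#'
#' @param cfg A `gag_run_config`, or a path to a YAML configuration.
#' @return Invisibly, a list with the computed objects and the output paths.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "gag_run_config"))
  if (is.null(cfg$input) && is.null(cfg$synth$n_frames)) {
    abort("config must provide either an input file or synth$n_frames >= 1")
  }
  if (!is.null(cfg$synth$n_frames) && cfg$synth$n_frames < 1) {
    abort("synth$n_frames must be >= 1")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(cfg$output_dir, f)

  e <- pipeline_stage("load", {
    if (!is.null(cfg$input)) {
      read_ensemble(cfg$input, cfg$format)
    } else {
      args <- cfg$synth
      if (is.null(args$seed)) args$seed <- cfg$seed
      generate_ensemble(do.call(ensemble_recipe, args))
    }
  })

  refs <- pucker_reference_set(half_width = cfg$pucker_half_width)

  desc <- pipeline_stage("descriptors", {
    d <- compute_descriptors(e, mass_weighted = cfg$mass_weighted)
    readr::write_csv(d, out_path("descriptors.csv"))
    summ <- dplyr::bind_rows(lapply(c("rmsd", "rg", "eed"), function(col) {
      mutate(summary_stats(d[[col]], cfg$sd_type), descriptor = col,
             .before = 1)
    }))
    readr::write_csv(summ, out_path("descriptor_summary.csv"))
    d
  })

  pucker <- pipeline_stage("pucker", {
    pops <- pucker_populations(e, refs = refs)
    readr::write_csv(
      select(pops, "residue_index", "residue_type", "state", "fraction"),
      out_path("pucker_populations.csv"))
    pops
  })

  linkage <- pipeline_stage("linkage", {
    series <- linkage_series(e)
    readr::write_csv(series, out_path("linkage_series.csv"))
    modes_all <- list()
    for (cl in unique(series$linkage_class)) {
      sub <- series[series$linkage_class == cl, ]
      h <- torsion_heatmap(sub, bin_width = cfg$bin_width)
      fname <- gsub("[^A-Za-z0-9]+", "_", cl)
      write_heatmap_csv(h, out_path(paste0("heatmap_", fname, ".csv")))
      m <- find_modes(h, min_fraction = cfg$min_mode_fraction)
      modes_all[[cl]] <- mutate(m, linkage_class = cl, .before = 1)
    }
    modes <- dplyr::bind_rows(modes_all)
    readr::write_csv(modes, out_path("linkage_modes.csv"))
    list(series = series, modes = modes)
  })

  rmat <- pipeline_stage("rmsd-matrix", {
    m <- rmsd_matrix(e, stride = cfg$stride,
                     mass_weighted = cfg$mass_weighted)
    readr::write_csv(tidy(m), out_path("rmsd_matrix.csv"))
    m
  })

  dmap <- pipeline_stage("distance-map", {
    dm <- residue_distance_map(e)
    readr::write_csv(tidy(dm), out_path("residue_distance_map.csv"))
    dm
  })

  corr <- pipeline_stage("correlation", {
    cm <- descriptor_correlations(desc)
    readr::write_csv(tidy(cm), out_path("descriptor_correlations.csv"))
    cm
  })

  manifest <- list(
    package = "gagdyn",
    version = as.character(utils::packageVersion("gagdyn")),
    config = cfg[setdiff(names(cfg), "output_dir")],
    n_frames = n_frames(e),
    n_atoms = nrow(e$topology),
    input_md5 = if (!is.null(cfg$input)) {
      unname(tools::md5sum(cfg$input))
    } else NULL,
    outputs = list.files(cfg$output_dir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(ensemble = e, descriptors = desc, pucker = pucker,
                 linkage = linkage, rmsd_matrix = rmat,
                 distance_map = dmap, correlations = corr,
                 output_dir = cfg$output_dir))
}

write_heatmap_csv <- function(h, path) {
  m <- h$fraction
  df <- as.data.frame(m)
  names(df) <- sprintf("%g", h$psi_centers)
  df <- cbind(phi_center = sprintf("%g", h$phi_centers), df)
  readr::write_csv(df, path)
}
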