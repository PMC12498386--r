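# Rigid water model registry and pairwise energetics. The interaction
# energy between two placed water molecules a and b is
#   E_ab = sum_ij q_i q_j k / r_ij + 4 eps0 [(sig0/r_OO)^12 - (sig0/r_OO)^6]
# with i, j running over the charged interaction sites of a and b, a single
# oxygen-oxygen Lennard-Jones term, and k = 332.0636 kcal A mol^-1 e^-2
# making the Gaussian-units e^2 prefactor explicit.

#' Load the water model registry
#'
#' Reads the packaged site geometries and nonbonded parameters of the
#' TIP3P, TIP4P, TIP5P, SPC/E and OPC rigid water models and constructs the
#' interaction sites in a molecular frame (oxygen at the origin, hydrogens
#' symmetric about the +x bisector, any massless charge site on +x, lone
#' pairs in the xz-plane on the -x side).
#'
#' @param path Optional path to a registry YAML file; default the packaged
#'   registry.
#' @return Named list of `gag_water_model` objects.
#' @export
water_models <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "water_models.yaml", package = "gagdyn")
  }
  reg <- yaml::read_yaml(path)
  out <- lapply(names(reg), function(nm) water_model_from_spec(nm, reg[[nm]]))
  setNames(out, names(reg))
}

water_model_from_spec <- function(name, p) {
  half <- p$hoh_angle_deg / 2 * pi / 180
  sites <- tibble(
    site = c("O", "H1", "H2"),
    x = c(0, p$r_oh * cos(half), p$r_oh * cos(half)),
    y = c(0, p$r_oh * sin(half), -p$r_oh * sin(half)),
    z = 0,
    charge = c(if (!is.null(p$q_o)) p$q_o else 0, p$q_h, p$q_h)
  )
  if (!is.null(p$r_om)) {
    sites <- bind_rows(sites, tibble(site = "M", x = p$r_om, y = 0, z = 0,
                                     charge = p$q_m))
  }
  if (!is.null(p$r_ol)) {
    lhalf <- p$lol_angle_deg / 2 * pi / 180
    sites <- bind_rows(sites, tibble(
      site = c("L1", "L2"),
      x = -p$r_ol * cos(lhalf), y = 0,
      z = c(p$r_ol * sin(lhalf), -p$r_ol * sin(lhalf)),
      charge = p$q_l
    ))
  }
  net <- sum(sites$charge)
  if (abs(net) > 1e-9) {
    abort(sprintf("water model %s has net charge %.4f e", name, net))
  }
  if (p$lj_sigma <= 0 || p$lj_epsilon < 0) {
    abort(sprintf("water model %s has invalid LJ parameters", name))
  }
  structure(
    list(name = name, sites = sites, lj_sigma = p$lj_sigma,
         lj_epsilon = p$lj_epsilon,
         dipole_reference = p$dipole_reference),
    class = "gag_water_model"
  )
}

#' @export
print.gag_water_model <- function(x, ...) {
  cat(sprintf("<gag_water_model> %s: %d sites, sigma0 = %g A, eps0 = %g kcal/mol\n",
              x$name, nrow(x$sites), x$lj_sigma, x$lj_epsilon))
  invisible(x)
}

#' Rigidly place a water molecule in space
#'
#' @param model A `gag_water_model`.
#' @param rotation 3 x 3 rotation matrix (right action on row vectors).
#' @param translation Length-3 translation in Angstrom.
#' @return The model with transformed site coordinates.
#' @export
place_water <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "gag_water_model"))
  xyz <- as.matrix(model$sites[c("x", "y", "z")]) %*% rotation
  xyz <- sweep(xyz, 2, -translation)
  model$sites$x <- xyz[, 1]
  model$sites$y <- xyz[, 2]
  model$sites$z <- xyz[, 3]
  model
}

#' Pairwise water-water interaction energy
#'
#' Coulomb sum over all charged site pairs plus a single oxygen-oxygen
#' Lennard-Jones term using the model's sigma0/eps0. Both molecules must be
#' placed instances of the same model.
#'
#' @param a,b Placed `gag_water_model` objects.
#' @param coulomb_constant Coulomb prefactor in kcal A mol^-1 e^-2.
#' @return Interaction energy in kcal/mol.
#' @export
water_pair_energy <- function(a, b, coulomb_constant = COULOMB_KCAL) {
  stopifnot(inherits(a, "gag_water_model"), inherits(b, "gag_water_model"))
  if (!identical(a$name, b$name)) {
    abort("both molecules must use the same water model")
  }
  xa <- as.matrix(a$sites[c("x", "y", "z")])
  xb <- as.matrix(b$sites[c("x", "y", "z")])
  qa <- a$sites$charge
  qb <- b$sites$charge
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-9)) abort("overlapping interaction sites (r_ij = 0)")
  qq <- outer(qa, qb)
  e_coul <- coulomb_constant * sum(qq / d)
  r_oo <- d[which(a$sites$site == "O"), which(b$sites$site == "O")]
  sr6 <- (a$lj_sigma / r_oo)^6
  e_lj <- 4 * a$lj_epsilon * (sr6^2 - sr6)
  e_coul + e_lj
}

#' Dipole moment of a water model
#'
#' |sum_i q_i r_i| converted from e Angstrom to Debye. Only defined for a
#' neutral site set (otherwise the dipole is origin-dependent).
#'
#' @param model A `gag_water_model`.
#' @return Dipole moment in Debye.
#' @export
model_dipole <- function(model) {
  stopifnot(inherits(model, "gag_water_model"))
  if (abs(sum(model$sites$charge)) > 1e-9) {
    abort("nonzero net charge: dipole is origin-dependent")
  }
  xyz <- as.matrix(model$sites[c("x", "y", "z")])
  mu <- colSums(xyz * model$sites$charge)
  sqrt(sum(mu^2)) * EA_TO_DEBYE
}
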