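test_that("chair rings have six alternating ring torsions of equal magnitude", {
  ring <- build_pyranose_ring(0.57, 0, 0)
  xyz <- coords(ring)
  rownames(xyz) <- ring$atom_name
  seq6 <- c("O5", "C1", "C2", "C3", "C4", "C5")
  tors <- vapply(1:6, function(i) {
    idx <- seq6[(c(i, i + 1, i + 2, i + 3) - 1) %% 6 + 1]
    torsion_angle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
  }, numeric(1))
  # signs strictly alternate; magnitudes agree up to the C-O/C-C bond-length
  # asymmetry of a realistic ring (a few degrees)
  expect_equal(sign(tors), rep(c(1, -1), 3) * sign(tors[1]))
  expect_lt(max(abs(tors)) - min(abs(tors)), 6)
})

test_that("the planar limit gives gamma = delta = 0 and tiny out-of-plane z", {
  ring <- build_pyranose_ring(1e-4, 0, 0)
  gd <- compute_gamma_delta(ring, 1L)
  expect_lt(abs(gd$gamma), 0.05)
  expect_lt(abs(gd$delta), 0.05)
  expect_error(build_pyranose_ring(1.2), "non-physical")
  expect_error(build_pyranose_ring(0), "> 0")
})

test_that("built rings round-trip their Cremer-Pople parameters", {
  set.seed(91)
  cases <- rbind(
    expand.grid(q = c(0.4, 0.57, 0.75), theta = c(0, 45, 90, 135, 180),
                phi2 = c(0, 30, 150, 210, 330)),
    data.frame(q = runif(10, 0.3, 0.8), theta = runif(10, 5, 175),
               phi2 = runif(10, 0, 360))
  )
  for (i in seq_len(nrow(cases))) {
    ring <- build_pyranose_ring(cases$q[i], cases$theta[i], cases$phi2[i])
    cp <- oracle_cp(coords(ring))
    expect_equal(cp$Q, cases$q[i], tolerance = 1e-3)
    expect_equal(cp$theta, cases$theta[i], tolerance = 0.1)
    if (cases$theta[i] > 1 && cases$theta[i] < 179) {
      expect_lt(gagdyn:::circular_distance(cp$phi2, cases$phi2[i]), 0.1)
    }
    # every ring bond within the idealized window
    xyz <- coords(ring)
    bonds <- sqrt(rowSums((xyz[c(2:6, 1), ] - xyz)^2))
    expect_true(all(bonds > 1.42 & bonds < 1.55))
    # out-of-plane displacements reproduce the CP z-pattern
    expect_equal(xyz[, 3],
                 gagdyn:::cp_z_pattern(cases$q[i], cases$theta[i], cases$phi2[i]),
                 tolerance = 1e-3)
  }
})

test_that("derived references obey chair inversion symmetry and are deterministic", {
  r1 <- derive_pucker_references()
  r2 <- derive_pucker_references()
  expect_identical(r1, r2)
  g <- function(st, col) r1[[col]][r1$state == st]
  expect_equal(g("4C1", "gamma_ref"), -g("1C4", "gamma_ref"), tolerance = 1e-6)
  expect_equal(g("4C1", "delta_ref"), -g("1C4", "delta_ref"), tolerance = 1e-6)
  # the frozen constants match the derivation
  expect_equal(r1$gamma_ref, gag_pucker_refs$gamma_ref, tolerance = 1e-5)
  expect_equal(r1$delta_ref, gag_pucker_refs$delta_ref, tolerance = 1e-5)
})

test_that("reference separations: chairs >46 deg from everything; skews split by >1 half-width", {
  r <- derive_pucker_references()
  sep <- function(a, b) {
    c(gagdyn:::circular_distance(r$gamma_ref[r$state == a],
                                 r$gamma_ref[r$state == b]),
      gagdyn:::circular_distance(r$delta_ref[r$state == a],
                                 r$delta_ref[r$state == b]))
  }
  # chairs are far from every other state in at least one coordinate
  for (pair in list(c("4C1", "1C4"), c("4C1", "2SO"), c("4C1", "1S3"),
                    c("1C4", "2SO"), c("1C4", "1S3"))) {
    expect_gt(max(sep(pair[1], pair[2])), 46)
  }
  # the adjacent skew-boats are geometrically closer than two half-widths
  # (their windows overlap in a corner) but farther than one half-width,
  # so reference points classify unambiguously
  expect_gt(max(sep("2SO", "1S3")), 23)
})

test_that("chains round-trip prescribed glycosidic torsions", {
  s <- build_chain(2, phi = -70, psi = 120)
  pp <- compute_phi_psi(s, 2)
  expect_equal(pp$phi, -70, tolerance = 0.5)
  expect_equal(pp$psi, 120, tolerance = 0.5)
  # eclipsed construction: torsion round trip only (eclipsed glycosidic
  # torsions legitimately produce close contacts, so the clash check is off)
  s0 <- build_chain(2, phi = 0, psi = 0, check_clash = FALSE)
  pp0 <- compute_phi_psi(s0, 2)
  expect_equal(pp0$phi, 0, tolerance = 0.5)
  expect_equal(pp0$psi, 0, tolerance = 0.5)
  set.seed(101)
  # linkage n has donor n+1: odd linkages have IdoA donors (60, 60) basin,
  # even linkages GlcNS donors (-70, 120) basin
  phis <- rep(c(60, -70), length.out = 11) + runif(11, -15, 15)
  psis <- rep(c(60, 120), length.out = 11) + runif(11, -15, 15)
  s12 <- build_chain(12, phi = phis, psi = psis)
  for (k in 2:12) {
    pp <- compute_phi_psi(s12, k)
    expect_equal(pp$phi, phis[k - 1], tolerance = 0.5)
    expect_equal(pp$psi, psis[k - 1], tolerance = 0.5)
  }
})

test_that("a dodecamer has 12 residues and 11 detected linkages, 6/5 by class", {
  s <- build_chain(12)
  expect_equal(length(unique(s$residue_index)), 12)
  links <- detect_linkages(s)
  expect_equal(nrow(links), 11)
  tab <- table(links$linkage_class)
  expect_setequal(as.integer(tab), c(6, 5))
  expect_equal(as.integer(tab[["IdoA(2S)-GlcNS(6S)"]]), 6)
})

test_that("rigid motion leaves chain internal torsions unchanged", {
  set.seed(111)
  s <- build_chain(4, phi = c(60, -70, 60), psi = c(60, 120, 60))
  moved <- transform_structure(s, random_rotation(), rnorm(3, sd = 30))
  for (k in 2:4) {
    expect_equal(as.numeric(compute_phi_psi(moved, k)),
                 as.numeric(compute_phi_psi(s, k)), tolerance = 1e-8)
  }
})

test_that("clashing torsions are rejected with advice", {
  # forcing consecutive residues back onto each other produces a clash
  expect_error(
    build_chain(6, phi = 90, psi = -90, pucker_states = "4C1"),
    "clash")
})

test_that("generator determinism and the noise-free single-state limit", {
  r <- ensemble_recipe(
    n_frames = 4, seed = 99, n_residues = 4,
    pucker_probs = list("GlcNS(6S)" = c("4C1" = 1), "IdoA(2S)" = c("2SO" = 1)),
    linkage_torsions = tibble::tibble(
      linkage_class = c("GlcNS(6S)-IdoA(2S)", "IdoA(2S)-GlcNS(6S)"),
      mean_phi = c(-70, 60), mean_psi = c(120, 60),
      sd_phi = 0, sd_psi = 0, weight = 1),
    noise_sd = 0)
  e <- generate_ensemble(r)
  for (f in 2:4) expect_equal(e$xyz[, , f], e$xyz[, , 1])
  e2 <- generate_ensemble(r)
  expect_identical(e$xyz, e2$xyz)
  # different seed, different coordinates once noise is on
  r3 <- ensemble_recipe(n_frames = 2, seed = 100, n_residues = 4,
                        noise_sd = 0.05)
  e3 <- generate_ensemble(r3)
  expect_false(isTRUE(all.equal(e3$xyz[, , 1], e3$xyz[, , 2])))
})

test_that("recipe validation catches bad probabilities and missing classes", {
  expect_error(ensemble_recipe(n_frames = 0, seed = 1), "n_frames")
  expect_error(ensemble_recipe(n_frames = 1, seed = 1, noise_sd = -1),
               "noise_sd")
  expect_error(
    ensemble_recipe(n_frames = 1, seed = 1,
                    pucker_probs = list("GlcNS(6S)" = c("4C1" = 0.5),
                                        "IdoA(2S)" = c("2SO" = 1))),
    "sum to 1")
  expect_error(
    ensemble_recipe(n_frames = 1, seed = 1,
                    linkage_torsions = tibble::tibble(
                      linkage_class = "GlcNS(6S)-IdoA(2S)",
                      mean_phi = -70, mean_psi = 120,
                      sd_phi = 10, sd_psi = 10, weight = 1)),
    "missing class")
})

test_that("generated pucker populations are recovered by the classifier", {
  # 70/30 chair mixture on every residue of a disaccharide, n = 1000
  r <- ensemble_recipe(
    n_frames = 1000, seed = 2024, n_residues = 2,
    pucker_probs = list("GlcNS(6S)" = c("4C1" = 0.7, "1C4" = 0.3),
                        "IdoA(2S)" = c("4C1" = 0.7, "1C4" = 0.3)),
    linkage_torsions = tibble::tibble(
      linkage_class = "IdoA(2S)-GlcNS(6S)",
      mean_phi = -70, mean_psi = 120, sd_phi = 10, sd_psi = 10, weight = 1),
    noise_sd = 0.02)
  e <- generate_ensemble(r)
  pops <- pucker_populations(e)
  for (res in 1:2) {
    f41 <- pops$fraction[pops$residue_index == res & pops$state == "4C1"]
    f14 <- pops$fraction[pops$residue_index == res & pops$state == "1C4"]
    expect_lt(abs(f41 - 0.7), 0.05)
    expect_lt(abs(f14 - 0.3), 0.05)
  }
})
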