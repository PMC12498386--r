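set_coords_noise <- function(s, sd) {
  xyz <- coords(s) + matrix(rnorm(3 * nrow(s), 0, sd), ncol = 3)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

rigid_copies_ensemble <- function(s, n = 5, seed = 23) {
  set.seed(seed)
  frames <- lapply(seq_len(n), function(i) {
    if (i == 1) s else transform_structure(s, random_rotation(), rnorm(3, sd = 10))
  })
  gag_ensemble(frames)
}

test_that("RMSD series is zero for rigid-body-moved copies and duplicated frames", {
  s <- build_chain(4)
  e <- rigid_copies_ensemble(s, 5)
  expect_equal(rmsd_timeseries(e), rep(0, 5), tolerance = 1e-9)
  set.seed(29)
  frames <- list(s, transform_structure(s, random_rotation(), c(1, 2, 3)))
  frames[[3]] <- set_coords_noise(s, 0.3)
  frames[[4]] <- frames[[1]]
  e2 <- gag_ensemble(frames)
  r <- rmsd_timeseries(e2)
  expect_equal(r[1], 0)
  expect_equal(r[2], 0, tolerance = 1e-9)
  expect_gt(r[3], 0)
  expect_equal(r[4], 0, tolerance = 1e-12)
})

test_that("RMSD series matches per-pair brute-force superposition", {
  set.seed(31)
  s <- random_structure(8)
  frames <- list(s, set_coords_noise(s, 0.5), set_coords_noise(s, 1))
  e <- gag_ensemble(frames)
  r <- rmsd_timeseries(e)
  for (i in 2:3) {
    expect_equal(r[i], oracle_superpose_rmsd(coords(frames[[i]]), coords(s),
                                             s$mass, n_starts = 12, seed = i),
                 tolerance = 1e-6)
  }
})

test_that("RMSD matrix: constant ensemble, 2-frame reduction, oracle, row 0", {
  s <- build_chain(3)
  e <- gag_ensemble(rep(list(s), 4))
  m <- rmsd_matrix(e)
  expect_equal(m$values, matrix(0, 4, 4), tolerance = 1e-10)

  set.seed(37)
  s1 <- random_structure(9)
  frames <- list(s1, set_coords_noise(s1, 0.8))
  e2 <- gag_ensemble(frames)
  m2 <- rmsd_matrix(e2)
  fit <- optimal_superposition(frames[[2]], frames[[1]])
  expect_equal(m2$values[1, 2], fit$rmsd, tolerance = 1e-10)
  expect_equal(m2$values, t(m2$values))
  expect_equal(diag(m2$values), c(0, 0))

  frames5 <- c(list(s1), lapply(1:4, function(i) set_coords_noise(s1, 0.5)))
  e5 <- gag_ensemble(frames5)
  m5 <- rmsd_matrix(e5)
  for (i in 1:4) for (j in seq(i + 1, 5)) {
    expect_equal(
      m5$values[i, j],
      oracle_superpose_rmsd(coords(frames5[[j]]), coords(frames5[[i]]),
                            s1$mass, n_starts = 8, seed = i * 10 + j),
      tolerance = 1e-6)
  }
  # first row reproduces the time series at the strided frames
  expect_equal(m5$values[1, ], rmsd_timeseries(e5), tolerance = 1e-9)
  expect_error(rmsd_matrix(e5, stride = 10), "stride")
})

test_that("EED series: coincident COMs, two point residues, direct-sum oracle", {
  two <- gag_structure(tibble::tibble(
    atom_name = c("A", "B"), element = "C", mass = c(2, 7),
    residue_index = c(1L, 2L), residue_type = "UNK",
    x = c(0, 5), y = 0, z = 0
  ))
  e <- gag_ensemble(list(two))
  expect_equal(eed_series(e), 5)
  same <- gag_structure(tibble::tibble(
    atom_name = c("A1", "A2", "B1"), element = "C", mass = c(1, 1, 2),
    residue_index = c(1L, 1L, 2L), residue_type = "UNK",
    x = c(-1, 1, 0), y = 0, z = 0
  ))
  expect_equal(eed_series(gag_ensemble(list(same))), 0)
  set.seed(41)
  e3 <- generate_ensemble(ensemble_recipe(n_frames = 3, seed = 43,
                                          n_residues = 4, noise_sd = 0.05))
  eed <- eed_series(e3)
  for (f in 1:3) {
    fr <- ensemble_frame(e3, f)
    d <- sqrt(sum((center_of_mass(fr, residue_index == 1) -
                     center_of_mass(fr, residue_index == 4))^2))
    expect_equal(eed[f], d, tolerance = 1e-12)
  }
  expect_error(eed_series(e3, 1, 9), "residue 9")
})

test_that("Rg series: constant ensemble, homogeneity under scaling, oracle", {
  s <- build_chain(3)
  e <- gag_ensemble(rep(list(s), 3))
  expect_equal(diff(range(rg_series(e))), 0)
  doubled <- s
  doubled[c("x", "y", "z")] <- 2 * as.data.frame(coords(s))
  expect_equal(radius_of_gyration(doubled), 2 * radius_of_gyration(s),
               tolerance = 1e-12)
  # per-frame values match the direct mass-weighted formula
  e3 <- generate_ensemble(ensemble_recipe(n_frames = 2, seed = 51,
                                          n_residues = 3, noise_sd = 0.02))
  rg <- rg_series(e3)
  for (f in 1:2) {
    expect_equal(rg[f], radius_of_gyration(ensemble_frame(e3, f)),
                 tolerance = 1e-12)
  }
})

test_that("inter-residue distance map: collinear chain and frame averaging", {
  n <- 5
  pts <- gag_structure(tibble::tibble(
    atom_name = paste0("A", 1:n), element = "C", mass = 1,
    residue_index = seq_len(n), residue_type = "UNK",
    x = 3 * (seq_len(n) - 1), y = 0, z = 0
  ))
  dm <- residue_distance_map(gag_ensemble(list(pts)))
  expect_equal(dm$values, 3 * abs(outer(1:n, 1:n, "-")), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant ensemble equals the single-frame map
  dm3 <- residue_distance_map(gag_ensemble(rep(list(pts), 3)))
  expect_equal(dm3$values, dm$values)
  # random ensemble: brute-force per-frame average
  e <- generate_ensemble(ensemble_recipe(n_frames = 3, seed = 53,
                                         n_residues = 3, noise_sd = 0.05))
  dm4 <- residue_distance_map(e)
  acc <- matrix(0, 3, 3)
  for (f in 1:3) {
    fr <- ensemble_frame(e, f)
    coms <- t(sapply(1:3, function(r) center_of_mass(fr, residue_index == r)))
    acc <- acc + as.matrix(dist(coms))
  }
  expect_equal(dm4$values, acc / 3, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("summary statistics follow the configured SD convention", {
  expect_equal(summary_stats(rep(3.5, 10)), tibble::tibble(mean = 3.5, sd = 0, n = 10L),
               ignore_attr = TRUE)
  expect_equal(summary_stats(c(0, 2))$mean, 1)
  expect_equal(summary_stats(c(0, 2))$sd, sqrt(2))
  expect_equal(summary_stats(c(0, 2), "population")$sd, 1)
  set.seed(59)
  x <- rnorm(100)
  st <- summary_stats(x)
  expect_equal(st$mean, sum(x) / 100, tolerance = 1e-12)
  expect_equal(st$sd, sqrt(sum((x - mean(x))^2) / 99), tolerance = 1e-12)
  expect_error(summary_stats(numeric(0)), "empty")
})

test_that("descriptor correlations: identity, negation, covariance oracle", {
  set.seed(61)
  t <- tibble::tibble(rmsd = rnorm(50), rg = rnorm(50), eed = rnorm(50))
  cm <- descriptor_correlations(t)
  expect_equal(diag(unclass(cm)), c(rmsd = 1, rg = 1, eed = 1))
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_true(all(abs(cm) <= 1))
  # against the covariance formula
  cov_or <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(cm["rmsd", "eed"], cov_or(t$rmsd, t$eed), tolerance = 1e-12)
  t2 <- tibble::tibble(rmsd = t$rmsd, rg = -t$rmsd, eed = t$eed)
  expect_equal(descriptor_correlations(t2)["rmsd", "rg"], -1)
  t3 <- tibble::tibble(rmsd = t$rmsd, rg = 1, eed = t$eed)
  expect_error(descriptor_correlations(t3), "constant")
  expect_error(descriptor_correlations(t[1:2, ]), "3 frames")
})

test_that("descriptors are invariant under a global rigid motion of every frame", {
  e <- generate_ensemble(ensemble_recipe(n_frames = 4, seed = 67,
                                         n_residues = 4, noise_sd = 0.05))
  r <- random_rotation(); tr <- c(7, -4, 2)
  moved_frames <- lapply(seq_len(n_frames(e)), function(i) {
    transform_structure(ensemble_frame(e, i), r, tr)
  })
  e2 <- gag_ensemble(moved_frames)
  expect_equal(rmsd_timeseries(e2), rmsd_timeseries(e), tolerance = 1e-9)
  expect_equal(rg_series(e2), rg_series(e), tolerance = 1e-9)
  expect_equal(eed_series(e2), eed_series(e), tolerance = 1e-9)
  expect_equal(residue_distance_map(e2)$values, residue_distance_map(e)$values,
               tolerance = 1e-9)
})

test_that("two-template ensembles show within- vs between-cluster block structure", {
  ra <- ensemble_recipe(
    n_frames = 20, seed = 71, n_residues = 6,
    linkage_torsions = tibble::tibble(
      linkage_class = c("GlcNS(6S)-IdoA(2S)", "IdoA(2S)-GlcNS(6S)"),
      mean_phi = c(-70, 60), mean_psi = c(120, 60), sd_phi = 3, sd_psi = 3,
      weight = 1),
    noise_sd = 0.05)
  rb <- ensemble_recipe(
    n_frames = 20, seed = 73, n_residues = 6,
    linkage_torsions = tibble::tibble(
      linkage_class = c("GlcNS(6S)-IdoA(2S)", "IdoA(2S)-GlcNS(6S)"),
      mean_phi = c(-90, 60), mean_psi = c(-50, 110), sd_phi = 3, sd_psi = 3,
      weight = 1),
    noise_sd = 0.05)
  e <- bind_ensembles(generate_ensemble(ra), generate_ensemble(rb))
  m <- rmsd_matrix(e)$values
  a <- 1:20; b <- 21:40
  within_a <- mean(m[a, a][upper.tri(m[a, a])])
  within_b <- mean(m[b, b][upper.tri(m[b, b])])
  between <- mean(m[a, b])
  expect_lt(within_a, between)
  expect_lt(within_b, between)
})
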