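test_that("torsion angle reproduces planar cis and trans arrangements", {
  # four coplanar points, outer points on the same side: cis, 0 degrees
  expect_equal(torsion_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  # opposite sides: trans, 180 degrees (wrapped onto +180)
  expect_equal(
    torsion_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
})

test_that("torsion angle matches an independent projection oracle", {
  set.seed(101)
  for (i in 1:50) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(
      torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
      oracle_torsion(p[1, ], p[2, ], p[3, ], p[4, ]),
      tolerance = 1e-9
    )
  }
})

test_that("torsion angle is preserved under sign-preserving reversal", {
  set.seed(7)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(
      torsion_angle(p[4, ], p[3, ], p[2, ], p[1, ]),
      torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
      tolerance = 1e-10
    )
  }
})

test_that("degenerate torsion geometry raises rather than returning a value", {
  expect_error(
    torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(2, 1, 0)),
    "coincide")
  expect_error(
    torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "collinear")
  expect_error(
    torsion_angle(c(0, 1, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
    "collinear")
})

test_that("center of mass handles midpoint, identity and random structures", {
  two <- gag_structure(tibble::tibble(
    atom_name = c("A", "B"), element = "C", mass = 1,
    residue_index = 1L, residue_type = "UNK",
    x = c(0, 2), y = 0, z = 0
  ))
  expect_equal(center_of_mass(two), c(1, 0, 0))
  one <- random_structure(1)
  expect_equal(center_of_mass(one), as.numeric(coords(one)))
  set.seed(11)
  for (i in 1:50) {
    s <- random_structure(sample(3:20, 1))
    direct <- unname(colSums(coords(s) * s$mass) / sum(s$mass))
    expect_equal(center_of_mass(s), direct, tolerance = 1e-12)
  }
  expect_error(center_of_mass(two, atom_name == "Z"), "empty")
})

test_that("superposition returns zero RMSD for identical and rigid copies", {
  set.seed(21)
  s <- random_structure(12)
  fit <- optimal_superposition(s, s)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  r <- random_rotation()
  moved <- transform_structure(s, r, c(3, -2, 8))
  fit2 <- optimal_superposition(moved, s)
  expect_lt(fit2$rmsd, 1e-9)
  # the returned transform reproduces the returned rmsd when applied
  ref <- transform_structure(random_structure(12), random_rotation(), 1:3)
  ref$mass <- moved$mass
  fit3 <- optimal_superposition(moved, ref)
  applied <- sweep(coords(moved) %*% fit3$rotation, 2, -fit3$translation)
  expect_equal(gagdyn:::rmsd_of(applied, coords(ref), moved$mass),
               fit3$rmsd, tolerance = 1e-10)
})

test_that("superposition RMSD matches a brute-force rotational minimizer", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(3 * n, sd = 2), n, 3)
    y <- matrix(rnorm(3 * n, sd = 2), n, 3)
    w <- runif(n, 0.5, 20)
    kab <- gagdyn:::superpose_xyz(x, y, w)$rmsd
    expect_equal(kab, oracle_superpose_rmsd(x, y, w, n_starts = 12, seed = i),
                 tolerance = 1e-6)
  }
})

test_that("fitted RMSD never exceeds the unfitted RMSD", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    x <- matrix(rnorm(3 * n), n, 3)
    y <- matrix(rnorm(3 * n), n, 3)
    w <- runif(n, 0.5, 10)
    expect_lte(gagdyn:::superpose_xyz(x, y, w)$rmsd,
               gagdyn:::rmsd_of(x, y, w) + 1e-12)
  }
})

test_that("superposition rejects too-few or collinear selections", {
  line <- gag_structure(tibble::tibble(
    atom_name = paste0("X", 1:4), element = "C", mass = 1,
    residue_index = 1L, residue_type = "UNK",
    x = 1:4, y = 2 * (1:4), z = 0
  ))
  expect_error(optimal_superposition(line, line), "collinear")
  two <- random_structure(2)
  expect_error(optimal_superposition(two, two), "3 atoms")
})

test_that("radius of gyration: symmetric pair, point, rotation invariance", {
  pair <- gag_structure(tibble::tibble(
    atom_name = c("A", "B"), element = "C", mass = 1,
    residue_index = 1L, residue_type = "UNK",
    x = c(-1, 1), y = 0, z = 0
  ))
  expect_equal(radius_of_gyration(pair), 1.0)
  expect_equal(radius_of_gyration(random_structure(1)), 0)
  set.seed(51)
  for (i in 1:50) {
    s <- random_structure(sample(3:20, 1))
    com <- center_of_mass(s)
    direct <- sqrt(sum(s$mass * rowSums(sweep(coords(s), 2, com)^2)) /
                     sum(s$mass))
    expect_equal(radius_of_gyration(s), direct, tolerance = 1e-12)
    moved <- transform_structure(s, random_rotation(), rnorm(3, sd = 10))
    expect_equal(radius_of_gyration(moved), radius_of_gyration(s),
                 tolerance = 1e-12)
  }
})

test_that("geometry operations are invariant under global rigid motion", {
  set.seed(61)
  s <- random_structure(10)
  r <- random_rotation()
  t <- c(5, -3, 11)
  m <- transform_structure(s, r, t)
  idx <- 1:4
  expect_equal(
    torsion_angle(coords(m)[1, ], coords(m)[2, ], coords(m)[3, ], coords(m)[4, ]),
    torsion_angle(coords(s)[1, ], coords(s)[2, ], coords(s)[3, ], coords(s)[4, ]),
    tolerance = 1e-9)
  expect_equal(as.numeric(center_of_mass(m)),
               as.numeric(center_of_mass(s) %*% r + t), tolerance = 1e-9)
})
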