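# Independent brute-force oracles. These deliberately avoid the package's
# own formulas: torsions via projection onto the bond-normal plane,
# superposition via direct numerical minimization over rotations, and
# Cremer-Pople analysis via the original mean-plane definition.

# torsion by projecting the outer points onto the plane perpendicular to
# the central bond and measuring the signed angle between the projections
oracle_torsion <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  x <- sum(u * v)
  y <- sum(b * c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  ))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

euler_rotation <- function(a, b, c) {
  rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# minimum weighted RMSD over rigid transforms by direct minimization over
# Euler angles (the optimal translation aligns the weighted centroids, so
# only the rotation is searched); multi-start Nelder-Mead + BFGS polish
oracle_superpose_rmsd <- function(x, y, w = rep(1, nrow(x)),
                                  n_starts = 24, seed = 42) {
  cx <- colSums(x * w) / sum(w)
  cy <- colSums(y * w) / sum(w)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  obj <- function(p) {
    r <- euler_rotation(p[1], p[2], p[3])
    sum(w * rowSums((xc %*% r - yc)^2)) / sum(w)
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- runif(3, -pi, pi)
    o1 <- optim(p0, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
    o2 <- optim(o1$par, obj, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-15))
    best <- min(best, o1$value, o2$value)
  }
  sqrt(best)
}

# Cremer-Pople (Q, theta, phi2) of six positions ordered O5, C1..C5
oracle_cp <- function(xyz) {
  n <- 6
  ctr <- colMeans(xyz)
  r <- sweep(xyz, 2, ctr)
  j <- 0:5
  rp <- colSums(r * sin(2 * pi * j / n))
  rpp <- colSums(r * cos(2 * pi * j / n))
  nrm <- c(
    rp[2] * rpp[3] - rp[3] * rpp[2],
    rp[3] * rpp[1] - rp[1] * rpp[3],
    rp[1] * rpp[2] - rp[2] * rpp[1]
  )
  nrm <- nrm / sqrt(sum(nrm^2))
  z <- as.numeric(r %*% nrm)
  q2c <- sqrt(2 / n) * sum(z * cos(4 * pi * j / n))
  q2s <- -sqrt(2 / n) * sum(z * sin(4 * pi * j / n))
  q2 <- sqrt(q2c^2 + q2s^2)
  phi2 <- (atan2(q2s, q2c) * 180 / pi) %% 360
  q3 <- sqrt(1 / n) * sum(z * (-1)^j)
  list(Q = sqrt(q2^2 + q3^2),
       theta = atan2(q2, q3) * 180 / pi,
       phi2 = phi2)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(m)
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

random_structure <- function(n = 10, n_residues = 1) {
  gag_structure(tibble::tibble(
    atom_name = paste0("X", seq_len(n)),
    element = sample(c("C", "O", "N", "S"), n, replace = TRUE),
    mass = runif(n, 1, 40),
    residue_index = sort(sample.int(n_residues, n, replace = TRUE)),
    residue_type = "UNK",
    x = rnorm(n, sd = 3), y = rnorm(n, sd = 3), z = rnorm(n, sd = 3)
  ))
}

# a six-atom planar hexagonal "ring" residue for degenerate-pucker cases
planar_ring_structure <- function(r = 1.45) {
  ang <- -(0:5) * pi / 3
  gag_structure(tibble::tibble(
    atom_name = c("O5", "C1", "C2", "C3", "C4", "C5"),
    element = c("O", rep("C", 5)),
    mass = c(15.999, rep(12.011, 5)),
    residue_index = 1L, residue_type = "UNK",
    x = r * cos(ang), y = r * sin(ang), z = 0
  ))
}
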