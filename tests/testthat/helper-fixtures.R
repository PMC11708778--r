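# Shared fixture builders and independent oracles for the test suite.
# All fixtures are constructed in code; none are stored on disk.

# A small state from explicit coordinates (and optional charges / naming).
toy_state <- function(xyz, label = "R", stage = "acylation", charge = NULL,
                      residue_id = NULL, residue_name = NULL,
                      atom_name = NULL, element = "C", region = "QM",
                      frequencies = NULL) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  atoms <- tibble::tibble(
    element = rep(element, length.out = nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  if (!is.null(charge)) atoms$charge <- charge
  if (!is.null(residue_id)) atoms$residue_id <- residue_id
  if (!is.null(residue_name)) atoms$residue_name <- residue_name
  if (!is.null(atom_name)) atoms$atom_name <- atom_name
  atoms$region <- rep(region, length.out = nrow(xyz))
  stationary_state(atoms, label = label, stage = stage,
                   frequencies = frequencies)
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid-body transform (rotation + translation) to a state.
transform_state <- function(state, rot, trans) {
  xyz <- as.matrix(state$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, trans, `+`)
  atoms <- state$atoms
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  stationary_state(atoms, label = state$label, stage = state$stage,
                   frequencies = state$frequencies, kind = state$kind)
}

# Independent Coulomb oracle: explicit double loop, no vectorization.
coulomb_oracle <- function(res, qm, k = 332.0637, eps = 1) {
  e <- 0
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(qm))) {
      r <- sqrt((res$x[i] - qm$x[j])^2 + (res$y[i] - qm$y[j])^2 +
                  (res$z[i] - qm$z[j])^2)
      e <- e + res$charge[i] * qm$charge[j] / r
    }
  }
  k / eps * e
}

# Independent superposition oracle: Euler-angle grid search refined by
# Nelder-Mead, never using the SVD route under test.
grid_rmsd_oracle <- function(A, B, n_grid = 18) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  euler_rot <- function(a, b, c) {
    rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  obj <- function(p) {
    d <- A %*% t(euler_rot(p[1], p[2], p[3])) - B
    sqrt(sum(d^2) / nrow(A))
  }
  angles <- seq(0, 2 * pi, length.out = n_grid + 1)[seq_len(n_grid)]
  betas <- seq(0, pi, length.out = n_grid)
  best <- Inf; best_p <- c(0, 0, 0)
  for (a in angles) for (b in betas) for (c in angles) {
    v <- obj(c(a, b, c))
    if (v < best) { best <- v; best_p <- c(a, b, c) }
  }
  stats::optim(best_p, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))$value
}

# Write a minimal PDB file for reader tests.
write_toy_pdb <- function(path, atoms) {
  lines <- sprintf(
    "ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), atoms$atom_name, atoms$residue_name,
    atoms$residue_id, atoms$x, atoms$y, atoms$z, atoms$element)
  writeLines(c(lines, "END"), path)
  path
}
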