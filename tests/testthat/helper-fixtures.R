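# Shared fixtures and independent oracles for the test suite.

# bare per-residue profile accepted by normalize_b / compare_profiles
new_profile_for_test <- function(resno, value) {
  tibble::tibble(resno = as.integer(resno), value = as.numeric(value))
}

coords_matrix_for_test <- function(conf) {
  as.matrix(conf$atoms[, c("x", "y", "z")])
}

# minimal atom-table builder for hand-made conformers
atom_row <- function(serial, name, resno, x, y, z, element = NULL,
                     resname = "ALA", chain = "A", occ = 1, b = 0) {
  tibble::tibble(
    serial = serial, name = name,
    element = if (is.null(element)) substr(name, 1, 1) else element,
    resname = resname, resno = resno, chain = chain,
    x = x, y = y, z = z, occ = occ, b = b
  )
}

ca_trace <- function(xyz, resname = "GLY", b = 0, chain = "A",
                     label = "trace") {
  n <- nrow(xyz)
  conformer(tibble::tibble(
    serial = seq_len(n), name = "CA", element = "C", resname = resname,
    resno = seq_len(n), chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, b = if (length(b) == 1) rep(b, n) else b
  ), label = label)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# Independent superposition oracle: dense grid over ZYZ Euler angles with
# centroid-matching translation, refined by Nelder-Mead. Never calls kabsch().
brute_force_superpose_rmsd <- function(ref, mov) {
  ref_c <- sweep(ref, 2, colMeans(ref))
  mov_c <- sweep(mov, 2, colMeans(mov))
  obj <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((mov_c %*% t(r) - ref_c)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 25)[-25],
                      b = seq(0, pi, length.out = 13),
                      c = seq(0, 2 * pi, length.out = 25)[-25])
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
  min(fit$value, fit2$value)
}

# two fixed, asymmetric 4-point sets for the oracle comparison
kabsch_fixture <- function() {
  list(
    ref = matrix(c(0, 0, 0,
                   1.8, 0.2, -0.4,
                   0.3, 2.1, 0.5,
                   -0.9, 0.7, 1.6), 4, 3, byrow = TRUE),
    mov = matrix(c(0.2, -0.1, 0.3,
                   2.0, 0.6, 0.1,
                   -0.4, 1.9, 1.0,
                   -1.2, 0.3, 1.2), 4, 3, byrow = TRUE)
  )
}

# handwritten multi-model PDB text
two_model_pdb <- function(path) {
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 12.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00 14.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   GLY A   1       0.000   0.000   1.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   1.000  1.00 12.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   1.000  1.00 14.00           C",
    "ENDMDL",
    "END"), path)
  path
}
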