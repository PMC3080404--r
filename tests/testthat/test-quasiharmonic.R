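meta_one_atom <- function(mass) {
  tibble::tibble(serial = 1, name = "CA", element = "C", resname = "GLY",
                 resno = 1, chain = "A", occ = 1, b = 0, mass = mass)
}

# wrap a bare covariance + metadata so projection operations can run on it
cov_obj <- function(cov, mean_coords, atom_meta) {
  structure(list(covariance = cov, mean_coords = mean_coords,
                 masses = atom_meta$mass, atom_meta = atom_meta,
                 n_frames_used = 2L, stride_ps = 5),
            class = "mw_covariance")
}

test_that("mass-weighted covariance matches closed forms", {
  # static trajectory -> zero matrix
  static <- trajectory(array(2, c(4, 1, 3)), 5, meta_one_atom(12))
  cv <- mass_weighted_covariance(static, stride = 1)
  expect_equal(max(abs(cv$covariance)), 0)
  # one atom of mass 4, x-variance 0.5 -> C_xx = 2.0 amu A^2
  x <- c(rep(-sqrt(0.5), 2), rep(sqrt(0.5), 2))  # population variance 0.5
  coords <- array(0, c(4, 1, 3))
  coords[, 1, 1] <- x
  tr <- trajectory(coords, 5, meta_one_atom(4))
  cv2 <- mass_weighted_covariance(tr, stride = 1)
  expect_equal(cv2$covariance[1, 1], 2.0, tolerance = 1e-12)
  expect_equal(cv2$covariance[2, 2], 0)
})

test_that("the default stride targets a 5 ps sampled interval", {
  coords <- array(rnorm(100 * 1 * 3), c(100, 1, 3))
  tr <- trajectory(coords, frame_interval = 1, meta_one_atom(12))
  cv <- mass_weighted_covariance(tr)
  expect_equal(cv$stride_ps, 5)
  expect_equal(cv$n_frames_used, 20)
  expect_error(mass_weighted_covariance(tr, stride = 100), "fewer than 2")
})

test_that("diagonalize is exact on diagonal input and reconstructs C", {
  md <- diagonalize(diag(c(4, 3, 2)))
  expect_equal(md$values, c(4, 3, 2))
  expect_equal(abs(md$vectors), diag(3), tolerance = 1e-12)
  set.seed(5)
  a <- matrix(rnorm(36), 6, 6)
  c_sym <- crossprod(a)
  md2 <- diagonalize(c_sym)
  expect_lt(max(abs(md2$vectors %*% diag(md2$values) %*% t(md2$vectors) -
                      c_sym)), 1e-8)
  expect_lt(max(abs(crossprod(md2$vectors) - diag(6))), 1e-6)
  expect_equal(sum(md2$values), sum(diag(c_sym)), tolerance = 1e-6)
  # deterministic sign: largest-magnitude component positive
  for (j in 1:6) expect_gt(md2$vectors[which.max(abs(md2$vectors[, j])), j], 0)
  expect_error(diagonalize(matrix(c(1, 2, 0, 1), 2, 2)), "asymmetric")
})

test_that("planted modes are recovered from sampled trajectories", {
  base <- make_helix(10)
  v <- random_orthonormal(30, 2, seed = 5)
  spec <- mode_spec(v, c(9, 1), n_frames = 10000, seed = 5)
  traj <- make_mode_trajectory(base, spec)
  md <- diagonalize(mass_weighted_covariance(traj, stride = 1))
  expect_equal(md$values[1], 9, tolerance = 0.1)
  expect_equal(md$values[2], 1, tolerance = 0.1)
  expect_gt(abs(sum(md$vectors[, 1] * v[, 1])), 0.99)
  # same planted mode estimated from two independent runs
  traj2 <- make_mode_trajectory(base, mode_spec(v, c(9, 1),
                                                n_frames = 10000, seed = 6))
  md2 <- diagonalize(mass_weighted_covariance(traj2, stride = 1))
  expect_gt(mode_overlap(md, 1, md2, 1), 0.9)
})

test_that("variance fractions follow the spectrum arithmetic", {
  fake <- function(vals) structure(list(values = vals), class = "mode_set")
  expect_equal(variance_fraction(fake(c(5, 0, 0)), 1), 1.0)
  expect_equal(variance_fraction(fake(c(4, 3, 2, 1)), 3), 0.9)
  ms <- fake(c(4, 3, 2, 1))
  fr <- vapply(1:4, variance_fraction, numeric(1), modes = ms)
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[4], 1.0)
  expect_error(variance_fraction(fake(c(0, 0)), 1), "zero")
  expect_error(variance_fraction(fake(c(1, 2)), 3), "k must be")
})

test_that("a planted top-3 fraction of 0.44 is recovered at 10^4 frames", {
  base <- make_helix(8)  # 24 dims
  n3 <- 24
  v <- random_orthonormal(n3, n3, seed = 31)
  top3 <- c(2.2, 1.4, 0.8)                   # sums to 4.4
  rest <- rep((10 - 4.4) / (n3 - 3), n3 - 3) # total 10 -> fraction 0.44
  spec <- mode_spec(v, c(top3, rest), n_frames = 10000, seed = 31)
  traj <- make_mode_trajectory(base, spec)
  md <- diagonalize(mass_weighted_covariance(traj, stride = 1))
  expect_equal(variance_fraction(md, 3), 0.44, tolerance = 0.02 / 0.44)
})

test_that("eigenvalue sum equals the covariance trace on every input", {
  base <- make_helix(6)
  for (seed in 1:3) {
    v <- random_orthonormal(18, 3, seed = seed)
    traj <- make_mode_trajectory(base, mode_spec(v, c(5, 2, 1),
                                                 n_frames = 500,
                                                 seed = seed))
    cv <- mass_weighted_covariance(traj, stride = 1)
    md <- diagonalize(cv)
    expect_equal(sum(md$values), sum(diag(cv$covariance)),
                 tolerance = 1e-6)
  }
})

test_that("extreme conformations obey the harmonic 2kT amplitude", {
  # single atom, mass 1, lambda = 1 -> displacement exactly 2 A at 2kT
  meta <- meta_one_atom(1)
  cv <- cov_obj(diag(c(1, 0, 0)), matrix(0, 1, 3), meta)
  md <- diagonalize(cv)
  ext <- extreme_conformations(md, 1, energy_kT = 2)
  expect_equal(ext$plus$atoms$x, 2, tolerance = 1e-9)
  expect_equal(ext$minus$atoms$x, -2, tolerance = 1e-9)
  expect_equal(ext$plus$atoms$y, 0)
  # doubling the mass at fixed lambda scales displacement by 1/sqrt(2)
  cv2 <- cov_obj(diag(c(1, 0, 0)), matrix(0, 1, 3), meta_one_atom(2))
  ext2 <- extreme_conformations(diagonalize(cv2), 1, energy_kT = 2)
  expect_equal(ext2$plus$atoms$x, 2 / sqrt(2), tolerance = 1e-9)
  # the amplitude is temperature-independent and scales with sqrt(energy)
  ext310 <- extreme_conformations(md, 1, energy_kT = 2, temperature = 310)
  ext100 <- extreme_conformations(md, 1, energy_kT = 2, temperature = 100)
  expect_equal(ext310$plus$atoms$x, ext100$plus$atoms$x)
  ext_half <- extreme_conformations(md, 1, energy_kT = 0.5)
  expect_equal(ext_half$plus$atoms$x, 1, tolerance = 1e-9)
  expect_error(extreme_conformations(md, 1, energy_kT = -1), "nonnegative")
})

test_that("zero-eigenvalue extremes coincide with the mean", {
  meta <- meta_one_atom(12)
  cv <- cov_obj(diag(c(0, 0, 0)), matrix(c(1, 2, 3), 1, 3), meta)
  ext <- extreme_conformations(diagonalize(cv), 1)
  expect_equal(unlist(ext$plus$atoms[, c("x", "y", "z")]),
               unlist(ext$minus$atoms[, c("x", "y", "z")]),
               ignore_attr = TRUE)
})

test_that("extremes are symmetric about the mean for sampled mode sets", {
  base <- make_helix(10)
  v <- random_orthonormal(30, 2, seed = 8)
  traj <- make_mode_trajectory(base, mode_spec(v, c(4, 1), n_frames = 2000,
                                               seed = 8))
  md <- diagonalize(mass_weighted_covariance(traj, stride = 1))
  ext <- extreme_conformations(md, 1)
  mid <- (coords_matrix_for_test(ext$plus) +
            coords_matrix_for_test(ext$minus)) / 2
  expect_lt(max(abs(mid - md$mean_coords)), 1e-9)
})

test_that("mode overlap separates identical from orthogonal modes", {
  md <- diagonalize(diag(c(3, 2, 1)))
  expect_equal(mode_overlap(md, 1, md, 1), 1.0)
  expect_equal(mode_overlap(md, 1, md, 2), 0.0)
  md6 <- diagonalize(diag(6))
  expect_error(mode_overlap(md, 1, md6, 1), "dimension")
})

test_that("loop summaries localize planted displacements and signs", {
  n_res <- 12
  base <- make_helix(n_res)
  n3 <- 3 * n_res
  # planted mode: residues 1-4 move +x, residues 9-12 move -x
  v <- rep(0, n3)
  v[3 * (0:3) + 1] <- 1
  v[3 * (8:11) + 1] <- -1
  v <- v / sqrt(sum(v^2))
  cv <- cov_obj(v %*% t(v) * 4, coords_matrix_for_test(base), base$atoms)
  md <- diagonalize(cv)
  ranges <- list(front = c(1, 4), middle = c(5, 8), back = c(9, 12))
  summ <- loop_displacement_summary(md, 1, ranges)
  cosm <- attr(summ, "direction_cosines")
  expect_lt(cosm["front", "back"], 0)  # opposing motion
  mags <- summ$magnitude
  names(mags) <- summ$loop
  expect_lt(mags["middle"], 0.05 * mags["front"])
  # zero mode -> all magnitudes zero
  cv0 <- cov_obj(matrix(0, n3, n3), coords_matrix_for_test(base),
                 base$atoms)
  summ0 <- loop_displacement_summary(diagonalize(cv0), 1, ranges)
  expect_equal(summ0$magnitude, rep(0, 3))
  # a range outside the structure is omitted with a warning
  expect_warning(
    loop_displacement_summary(md, 1, list(front = c(1, 4),
                                          nowhere = c(100, 110))),
    "nowhere")
})
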