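#' Specification for a planted-amplitude conformer ensemble
#'
#' @param n_residues Number of residues in the base structure.
#' @param amplitude_profile Per-residue displacement amplitude, Angstrom
#'   (the expected RMSD-to-mean each residue should show at large N).
#' @param n_conformers Number of conformers (>= 2).
#' @param seed Integer seed; the generator is a pure function of
#'   (inputs, seed).
#' @return A list of class `flex_spec`.
#' @export
flex_spec <- function(n_residues, amplitude_profile, n_conformers, seed) {
  if (length(amplitude_profile) == 1) {
    amplitude_profile <- rep(amplitude_profile, n_residues)
  }
  stopifnot(length(amplitude_profile) == n_residues)
  if (any(amplitude_profile < 0)) stop("amplitudes must be nonnegative")
  if (n_conformers < 2) stop("n_conformers must be >= 2")
  structure(list(n_residues = n_residues,
                 amplitude_profile = amplitude_profile,
                 n_conformers = n_conformers, seed = as.integer(seed)),
            class = "flex_spec")
}

#' Specification for a planted-mode Gaussian trajectory
#'
#' @param eigenvectors 3N x k matrix with orthonormal columns: the planted
#'   modes, in mass-weighted coordinates.
#' @param variances Length-k vector of mode variances, amu Angstrom^2 (the
#'   eigenvalues the quasiharmonic analysis should recover).
#' @param n_frames Number of frames.
#' @param frame_interval Frame spacing, ps (default 5).
#' @param temperature Kelvin (default 310; metadata only).
#' @param seed Integer seed.
#' @return A list of class `mode_spec`.
#' @export
mode_spec <- function(eigenvectors, variances, n_frames,
                      frame_interval = 5, temperature = 310, seed = 1) {
  eigenvectors <- as.matrix(eigenvectors)
  gram <- crossprod(eigenvectors)
  if (max(abs(gram - diag(ncol(eigenvectors)))) > 1e-9) {
    stop("planted eigenvectors must be orthonormal (within 1e-9)")
  }
  if (length(variances) != ncol(eigenvectors)) {
    stop("one variance per planted eigenvector required")
  }
  if (any(variances < 0)) stop("variances must be nonnegative")
  structure(list(eigenvectors = eigenvectors, variances = variances,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 temperature = temperature, seed = as.integer(seed)),
            class = "mode_spec")
}

#' Ideal C-alpha helix trace
#'
#' A toy structure with ideal alpha-helical C-alpha geometry: 1.5 Angstrom
#' rise and 100 degrees rotation per residue on a 2.3 Angstrom radius, which
#' puts consecutive C-alpha atoms ~3.8 Angstrom apart.
#'
#' @param n_residues Number of residues (>= 4).
#' @param chain Chain identifier.
#' @return A [conformer] holding only C-alpha atoms (residues 1..n).
#' @export
make_helix <- function(n_residues, chain = "A") {
  if (n_residues < 4) stop("a helix needs at least 4 residues")
  i <- seq_len(n_residues) - 1
  theta <- i * 100 * pi / 180
  conformer(
    tibble::tibble(
      serial = seq_len(n_residues), name = "CA", element = "C",
      resname = "GLY", resno = seq_len(n_residues), chain = chain,
      x = 2.3 * cos(theta), y = 2.3 * sin(theta), z = 1.5 * i,
      occ = 1, b = 0
    ),
    label = sprintf("helix%d", n_residues)
  )
}

# uniformly random proper rotation (QR of a Gaussian matrix, det fixed to +1)
.random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  d <- diag(qr.R(qrd))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a conformer ensemble with planted per-residue amplitudes
#'
#' Conformer k is the base structure plus an independent Gaussian
#' displacement of each C-alpha with per-coordinate standard deviation
#' `amplitude_i / sqrt(3)` (so the expected RMSD-to-mean converges to
#' `amplitude_i` as the ensemble grows), followed by a random rigid motion
#' that forces the superposition stage to do real work.
#'
#' @param base A C-alpha [conformer] whose residue count matches the spec.
#' @param spec A [flex_spec].
#' @return An `ensemble` (C-alpha selection) of `n_conformers` members.
#' @export
make_flex_ensemble <- function(base, spec) {
  stopifnot(inherits(spec, "flex_spec"))
  ca <- base$atoms[base$atoms$name == "CA", ]
  if (nrow(ca) != spec$n_residues) {
    stop("base residue count (", nrow(ca), ") != spec n_residues (",
         spec$n_residues, ")")
  }
  base_xyz <- as.matrix(ca[, c("x", "y", "z")])
  sigma <- spec$amplitude_profile / sqrt(3)
  # B-factors consistent with the planted mean-square displacement a_i^2
  ca$b <- b_from_msd(spec$amplitude_profile^2)
  confs <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_conformers), function(k) {
      disp <- matrix(stats::rnorm(3 * nrow(ca), sd = rep(sigma, 3)),
                     ncol = 3)
      xyz <- base_xyz + disp
      rot <- .random_rotation()
      trn <- stats::runif(3, -10, 10)
      xyz <- xyz %*% t(rot) + matrix(trn, nrow(xyz), 3, byrow = TRUE)
      at <- ca
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      conformer(at, label = sprintf("synth:%d", k))
    })
  })
  build_ensemble(confs, selection = "CA")
}

#' Sample a trajectory from a planted mass-weighted harmonic model
#'
#' Frame f is `base + M^(-1/2) * V %*% z_f` with independent
#' `z_fi ~ Normal(0, variance_i)`: the mass-weighted covariance of the
#' resulting trajectory is exactly `V diag(variances) V^T` in expectation,
#' so quasiharmonic analysis should recover the planted modes.
#'
#' @param base A [conformer] (3 x atom count must equal the eigenvector
#'   dimension).
#' @param modespec A [mode_spec].
#' @return A [trajectory].
#' @export
make_mode_trajectory <- function(base, modespec) {
  stopifnot(inherits(modespec, "mode_spec"))
  n_atoms <- nrow(base$atoms)
  if (nrow(modespec$eigenvectors) != 3 * n_atoms) {
    stop("eigenvector dimension (", nrow(modespec$eigenvectors),
         ") != 3 x atom count (", 3 * n_atoms, ")")
  }
  base_flat <- as.vector(t(coords_matrix(base)))  # (x1,y1,z1,x2,...)
  inv_sqrt_m <- 1 / rep(sqrt(base$atoms$mass), each = 3)
  k <- length(modespec$variances)
  coords <- withr::with_seed(modespec$seed, {
    z <- matrix(stats::rnorm(modespec$n_frames * k,
                             sd = rep(sqrt(modespec$variances),
                                      each = modespec$n_frames)),
                nrow = modespec$n_frames)
    flat <- z %*% t(modespec$eigenvectors)           # frames x 3N
    flat <- sweep(flat, 2, inv_sqrt_m, `*`)
    flat <- sweep(flat, 2, base_flat, `+`)
    arr <- array(NA_real_, dim = c(modespec$n_frames, n_atoms, 3))
    for (d in 1:3) arr[, , d] <- flat[, seq(d, 3 * n_atoms, by = 3)]
    arr
  })
  trajectory(coords, modespec$frame_interval, base$atoms)
}

#' Random orthonormal mode matrix
#'
#' Utility for planting modes: the Q factor of a Gaussian matrix.
#'
#' @param dim Ambient dimension (3N).
#' @param k Number of columns.
#' @param seed Integer seed.
#' @return A dim x k matrix with orthonormal columns.
#' @export
random_orthonormal <- function(dim, k, seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(dim * k), dim, k)))
    q[, seq_len(k), drop = FALSE]
  })
}
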