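#' Mass-weighted covariance of a superposed trajectory
#'
#' Computes `C = (1/F) sum_f y_f y_f^T` with
#' `y_f = M^(1/2) (x_f - xbar)`, where `M^(1/2)` applies `sqrt(m_i)` to each
#' of atom i's three coordinates. Frames are subsampled so that the sampled
#' interval is `target_interval` ps (default 5 ps), mirroring common
#' quasiharmonic practice.
#'
#' @param traj A [trajectory] with rigid-body motion removed
#'   (see [superpose_trajectory]).
#' @param stride Integer frame stride; overrides `target_interval` if given.
#' @param target_interval Desired sampled interval, ps (default 5).
#' @return A list of class `mw_covariance`: `covariance` (3N x 3N,
#'   amu Angstrom^2), `mean_coords` (atoms x 3), `masses`, `atom_meta`,
#'   `n_frames_used`, `stride_ps`.
#' @export
mass_weighted_covariance <- function(traj, stride = NULL,
                                     target_interval = 5) {
  if (is.null(stride)) {
    stride <- max(1L, as.integer(round(target_interval /
                                         traj$frame_interval)))
  }
  n_frames <- dim(traj$coords)[1]
  idx <- seq.int(1L, n_frames, by = stride)
  if (length(idx) < 2) stop("fewer than 2 sampled frames at stride ", stride)
  n_atoms <- dim(traj$coords)[2]
  # flatten to frames x 3N with coordinates interleaved (x1,y1,z1,x2,...)
  flat <- matrix(NA_real_, nrow = length(idx), ncol = 3 * n_atoms)
  for (k in 1:3) flat[, seq(k, 3 * n_atoms, by = 3)] <- traj$coords[idx, , k]
  mean_flat <- colMeans(flat)
  sw <- rep(sqrt(traj$masses), each = 3)
  y <- sweep(flat, 2, mean_flat) * matrix(sw, nrow = length(idx),
                                          ncol = 3 * n_atoms, byrow = TRUE)
  cov <- crossprod(y) / length(idx)
  structure(
    list(covariance = cov,
         mean_coords = matrix(mean_flat, ncol = 3, byrow = TRUE),
         masses = traj$masses, atom_meta = traj$atom_meta,
         n_frames_used = length(idx),
         stride_ps = stride * traj$frame_interval),
    class = "mw_covariance"
  )
}

#' Diagonalize a mass-weighted covariance into quasiharmonic modes
#'
#' Eigenvalues are sorted descending and small negative values (round-off)
#' are clamped to zero. Each eigenvector's sign is fixed so its
#' largest-magnitude component is positive, making mode output
#' deterministic.
#'
#' @param covariance A `mw_covariance` object, or a bare symmetric matrix.
#' @return An object of class `mode_set`: `values` (amu Angstrom^2),
#'   `vectors` (3N x 3N, orthonormal columns in mass-weighted coordinates),
#'   plus `mean_coords`, `masses`, `atom_meta`, `n_frames_used`, `stride_ps`
#'   when available.
#' @export
diagonalize <- function(covariance) {
  meta <- list(mean_coords = NULL, masses = NULL, atom_meta = NULL,
               n_frames_used = NA_integer_, stride_ps = NA_real_)
  if (inherits(covariance, "mw_covariance")) {
    meta <- covariance[c("mean_coords", "masses", "atom_meta",
                         "n_frames_used", "stride_ps")]
    covariance <- covariance$covariance
  }
  covariance <- as.matrix(covariance)
  asym <- max(abs(covariance - t(covariance)))
  if (asym > 1e-8) {
    stop("covariance matrix is asymmetric beyond 1e-8 (max |C - C^T| = ",
         format(asym), ")")
  }
  eig <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  vals <- eig$values
  if (any(vals < -1e-8)) {
    stop("covariance has a substantially negative eigenvalue: ",
         format(min(vals)))
  }
  vals[vals < 0] <- 0
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    top <- which.max(abs(vecs[, j]))
    if (vecs[top, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(
    c(list(values = vals, vectors = vecs), meta),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  k <- min(3L, length(x$values))
  cat("<mode_set> ", length(x$values), " modes; top eigenvalues: ",
      paste(format(x$values[seq_len(k)], digits = 4), collapse = ", "),
      " amu A^2\n", sep = "")
  invisible(x)
}

#' @rdname diagonalize
#' @param x A `mode_set`.
#' @param ... Unused.
#' @export
tidy.mode_set <- function(x, ...) {
  total <- sum(x$values)
  tibble::tibble(
    mode = seq_along(x$values),
    eigenvalue = x$values,
    variance_fraction = if (total > 0) x$values / total else NA_real_,
    cumulative_fraction = if (total > 0) cumsum(x$values) / total else
      NA_real_
  )
}

#' @rdname diagonalize
#' @export
glance.mode_set <- function(x, ...) {
  tibble::tibble(
    n_modes = length(x$values),
    total_variance = sum(x$values),
    top3_fraction = if (sum(x$values) > 0)
      sum(x$values[seq_len(min(3, length(x$values)))]) / sum(x$values)
    else NA_real_,
    n_frames_used = x$n_frames_used,
    stride_ps = x$stride_ps
  )
}

#' Fraction of total motion captured by the leading modes
#'
#' @param modes A `mode_set`.
#' @param k Number of leading modes.
#' @return `sum(lambda[1:k]) / sum(lambda)`, in `[0, 1]`.
#' @export
variance_fraction <- function(modes, k) {
  vals <- modes$values
  if (k < 1 || k > length(vals)) stop("k must be in 1..", length(vals))
  total <- sum(vals)
  if (total <= 0) stop("all eigenvalues are zero; variance fraction undefined")
  sum(vals[seq_len(k)]) / total
}

# mass-weighted amplitude reached at energy E = energy_kT * kB * T in the
# quasiharmonic oscillator with omega^2 = kB*T/lambda: q = sqrt(2*E*lambda/kBT)
# = sqrt(2 * energy_kT) * sqrt(lambda). Temperature cancels.
.mode_amplitude <- function(lambda, energy_kT) {
  if (energy_kT < 0) stop("energy must be nonnegative (in kT units)")
  sqrt(2 * energy_kT) * sqrt(lambda)
}

#' Extreme conformations along one quasiharmonic mode
#'
#' Projects the mean structure to the two turning points a harmonic
#' oscillator reaches at energy `energy_kT * kB * T` above its ground state
#' along the chosen mode. With the quasiharmonic frequency
#' `omega^2 = kB*T/lambda` the mass-weighted amplitude is
#' `q = sqrt(2 * energy_kT * lambda)`; at the conventional 2kT this is
#' `q = 2*sqrt(lambda)`, independent of temperature. Cartesian extremes are
#' `xbar +/- M^(-1/2) v q`.
#'
#' @param modes A `mode_set` carrying `mean_coords`, `masses`, `atom_meta`.
#' @param mode_index Which mode (1 = largest eigenvalue).
#' @param energy_kT Excitation energy in units of kB*T (default 2).
#' @param temperature Kelvin (default 310); enters only through the
#'   quasiharmonic frequency and cancels in the amplitude.
#' @return A list of two [conformer] objects, `minus` and `plus`, symmetric
#'   about the mean. For a zero eigenvalue both equal the mean.
#' @export
extreme_conformations <- function(modes, mode_index, energy_kT = 2,
                                  temperature = 310) {
  if (is.null(modes$mean_coords) || is.null(modes$masses)) {
    stop("mode_set lacks mean coordinates/masses; ",
         "diagonalize a mw_covariance, not a bare matrix")
  }
  if (mode_index < 1 || mode_index > length(modes$values)) {
    stop("mode_index out of range")
  }
  lambda <- modes$values[mode_index]
  q <- .mode_amplitude(lambda, energy_kT)
  v <- modes$vectors[, mode_index]
  dx_flat <- v * q / rep(sqrt(modes$masses), each = 3)
  dx <- matrix(dx_flat, ncol = 3, byrow = TRUE)
  make_conf <- function(xyz, tag) {
    meta <- modes$atom_meta
    if (is.null(meta)) {
      stop("mode_set lacks atom metadata for conformer output")
    }
    meta$x <- xyz[, 1]; meta$y <- xyz[, 2]; meta$z <- xyz[, 3]
    if (!"occ" %in% names(meta)) meta$occ <- 1
    if (!"b" %in% names(meta)) meta$b <- 0
    conformer(meta, label = sprintf("mode%d_%s", mode_index, tag))
  }
  list(minus = make_conf(modes$mean_coords - dx, "minus"),
       plus = make_conf(modes$mean_coords + dx, "plus"))
}

#' Overlap between two quasiharmonic modes
#'
#' @param modes_a,modes_b `mode_set` objects of equal dimension.
#' @param i,j Mode indices into `modes_a` and `modes_b`.
#' @return Absolute cosine (inner product of unit eigenvectors) in `[0, 1]`.
#' @export
mode_overlap <- function(modes_a, i, modes_b, j) {
  va <- modes_a$vectors[, i]
  vb <- modes_b$vectors[, j]
  if (length(va) != length(vb)) stop("mode dimensions differ")
  abs(sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2))))
}

#' Per-loop displacement summary for one mode's extremes
#'
#' Summarizes how the excursion between the two `energy_kT` extreme
#' conformations distributes over residue ranges (e.g. the petal-like
#' binding-site loops): the mean C-alpha displacement vector and magnitude
#' per range, plus signed direction cosines between the loop vectors, which
#' quantify concerted (+) versus opposing (-) loop motion.
#'
#' @param modes A `mode_set` with atom metadata.
#' @param mode_index Mode to analyse.
#' @param residue_ranges Named list of `c(lo, hi)` residue ranges.
#' @param energy_kT,temperature As in [extreme_conformations].
#' @return A tibble (`loop`, `n_residues`, `dx`, `dy`, `dz`, `magnitude`)
#'   with a `direction_cosines` matrix attribute (signed, loops x loops).
#' @export
loop_displacement_summary <- function(modes, mode_index, residue_ranges,
                                      energy_kT = 2, temperature = 310) {
  ext <- extreme_conformations(modes, mode_index, energy_kT, temperature)
  a_min <- ext$minus$atoms
  a_plus <- ext$plus$atoms
  is_ca <- a_min$name == "CA"
  rows <- list()
  vecs <- list()
  for (nm in names(residue_ranges)) {
    rng <- residue_ranges[[nm]]
    in_rng <- is_ca & a_min$resno >= rng[1] & a_min$resno <= rng[2]
    if (!any(in_rng)) {
      warning("loop '", nm, "' has no mapped C-alpha residues; omitted")
      next
    }
    d <- cbind(a_plus$x - a_min$x, a_plus$y - a_min$y,
               a_plus$z - a_min$z)[in_rng, , drop = FALSE]
    mv <- colMeans(d)
    vecs[[nm]] <- mv
    rows[[nm]] <- tibble::tibble(
      loop = nm, n_residues = sum(in_rng),
      dx = mv[1], dy = mv[2], dz = mv[3],
      magnitude = sqrt(sum(mv^2))
    )
  }
  if (length(rows) == 0) stop("no residue range overlaps the structure")
  out <- dplyr::bind_rows(rows)
  k <- length(vecs)
  cosmat <- matrix(NA_real_, k, k, dimnames = list(names(vecs), names(vecs)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ni <- sqrt(sum(vecs[[i]]^2))
      nj <- sqrt(sum(vecs[[j]]^2))
      cosmat[i, j] <- if (ni > 0 && nj > 0) {
        sum(vecs[[i]] * vecs[[j]]) / (ni * nj)
      } else NA_real_
    }
  }
  attr(out, "direction_cosines") <- cosmat
  out
}
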