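#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the weighted
#' RMSD between `R %*% x_mov + t` and the reference points. Reflections are
#' excluded by the usual sign correction on the smallest singular value.
#'
#' @param ref_coords,mov_coords n x 3 matrices of matched points (Angstrom).
#' @param weights Nonnegative per-point weights; default all 1.
#' @return A list with `rotation` (3 x 3, det = +1), `translation`
#'   (length 3) and `rmsd` (weighted, Angstrom).
#' @export
kabsch <- function(ref_coords, mov_coords, weights = NULL) {
  ref_coords <- as.matrix(ref_coords)
  mov_coords <- as.matrix(mov_coords)
  n <- nrow(ref_coords)
  if (n != nrow(mov_coords)) stop("point counts differ")
  if (n < 3) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative and not all zero")
  }
  w <- weights / sum(weights)
  cen_ref <- colSums(ref_coords * w)
  cen_mov <- colSums(mov_coords * w)
  a <- sweep(ref_coords, 2, cen_ref)
  b <- sweep(mov_coords, 2, cen_mov)
  # collinearity check: a unique rotation needs rank >= 2 point clouds
  for (m in list(a, b)) {
    sv <- svd(m * sqrt(w))$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-30)) {
      stop("degenerate (collinear) point set: rotation is not unique")
    }
  }
  h <- crossprod(b * w, a)  # sum_i w_i b_i a_i^T
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cen_ref - as.vector(rot %*% cen_mov)
  fitted <- mov_coords %*% t(rot) + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((fitted - ref_coords)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

apply_rigid <- function(coords, rotation, translation) {
  coords %*% t(rotation) + matrix(translation, nrow(coords), 3, byrow = TRUE)
}

#' Iterative ensemble superposition to a converged mean structure
#'
#' Starting from the first conformer as reference, alternates between
#' fitting every conformer to the current mean (via [kabsch]) and
#' recomputing the mean, until the mean moves by less than `tol` at every
#' atom or `max_iter` passes have run.
#'
#' @param ensemble An [build_ensemble] result.
#' @param max_iter Maximum fit-to-mean passes (default 100).
#' @param tol Convergence tolerance on the maximum per-atom mean shift,
#'   Angstrom (default 1e-6).
#' @return An object of class `superposition`: per-conformer rotations and
#'   translations, `mean_coords`, `fitted_coords` (conformers x atoms x 3),
#'   `iterations`, `converged`, and the ensemble's `atom_map`.
#' @export
ensemble_superpose <- function(ensemble, max_iter = 100, tol = 1e-6) {
  if (tol <= 0) stop("tol must be positive")
  arr <- ensemble_coords(ensemble)
  n_conf <- dim(arr)[1]
  n_atom <- dim(arr)[2]
  mean_coords <- arr[1, , , drop = TRUE]
  if (is.null(dim(mean_coords))) mean_coords <- matrix(mean_coords, ncol = 3)
  fitted <- arr
  rot <- vector("list", n_conf)
  trn <- vector("list", n_conf)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (i in seq_len(n_conf)) {
      fit <- kabsch(mean_coords, arr[i, , ])
      rot[[i]] <- fit$rotation
      trn[[i]] <- fit$translation
      fitted[i, , ] <- apply_rigid(arr[i, , ], fit$rotation, fit$translation)
    }
    new_mean <- apply(fitted, c(2, 3), mean)
    shift <- sqrt(max(rowSums((new_mean - mean_coords)^2)))
    mean_coords <- new_mean
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("ensemble superposition did not converge in ", max_iter,
            " iterations")
  }
  structure(
    list(rotations = rot, translations = trn, mean_coords = mean_coords,
         fitted_coords = fitted, iterations = iterations,
         converged = converged, atom_map = ensemble$atom_map),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> ", dim(x$fitted_coords)[1], " conformers, ",
      dim(x$fitted_coords)[2], " atoms; ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

new_flex_profile <- function(resno, value, metric) {
  out <- tibble::tibble(resno = as.integer(resno), value = as.numeric(value))
  attr(out, "metric") <- metric
  class(out) <- c("flex_profile", class(out))
  out
}

#' Per-residue RMSD-to-mean profile
#'
#' For each mapped residue, the root-mean-square deviation of its C-alpha
#' position from the ensemble mean over all conformers:
#' `sqrt( (1/N) * sum_k |x_k - xbar|^2 )`. This is the per-residue
#' flexibility profile of the ensemble (equivalently its RMSF).
#'
#' @param result An [ensemble_superpose] result (C-alpha selection).
#' @return A `flex_profile` tibble with columns `resno`, `value` (Angstrom).
#' @export
per_residue_rmsd <- function(result) {
  dev2 <- sweep(result$fitted_coords, c(2, 3), result$mean_coords)^2
  msd_atom <- colMeans(apply(dev2, c(1, 2), sum))  # per-atom mean |dx|^2
  map <- result$atom_map
  agg <- tapply(msd_atom, map$resno, mean)
  new_flex_profile(as.integer(names(agg)), sqrt(as.numeric(agg)),
                   metric = "ca_rmsd_to_mean")
}

#' Remove rigid-body motion from a trajectory
#'
#' Fits every frame onto the (iteratively converged) trajectory mean using
#' the selected atoms, applying each frame's rigid transform to all atoms.
#' This is the standard preprocessing before mean-square-displacement and
#' quasiharmonic analysis.
#'
#' @param traj A [trajectory].
#' @param selection Atom-name filter used for the fit (default `"CA"`;
#'   `NULL` fits on all atoms).
#' @param max_iter,tol As in [ensemble_superpose].
#' @return A [trajectory] with superposed coordinates and an attribute
#'   `mean_coords`.
#' @export
superpose_trajectory <- function(traj, selection = "CA", max_iter = 100,
                                 tol = 1e-6) {
  sel <- if (is.null(selection)) {
    seq_len(dim(traj$coords)[2])
  } else {
    which(traj$atom_meta$name %in% selection)
  }
  if (length(sel) < 3) stop("fewer than 3 atoms match the fit selection")
  coords <- traj$coords
  n_frames <- dim(coords)[1]
  fitted <- coords
  mean_sel <- apply(coords[, sel, , drop = FALSE], c(2, 3), mean)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    for (f in seq_len(n_frames)) {
      fit <- kabsch(mean_sel, coords[f, sel, ])
      fitted[f, , ] <- apply_rigid(coords[f, , ], fit$rotation,
                                   fit$translation)
    }
    new_mean <- apply(fitted[, sel, , drop = FALSE], c(2, 3), mean)
    shift <- sqrt(max(rowSums((new_mean - mean_sel)^2)))
    mean_sel <- new_mean
    if (shift < tol || iterations >= max_iter) break
  }
  out <- traj
  out$coords <- fitted
  attr(out, "mean_coords") <- apply(fitted, c(2, 3), mean)
  out
}

#' Serialize a per-residue profile as TSV
#'
#' @param profile A `flex_profile` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile)[, c("resno", "value")], path)
  invisible(path)
}
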