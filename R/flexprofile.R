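#' Per-atom mean-square displacement about the mean position
#'
#' @param traj A [trajectory] whose frames have already been superposed to
#'   their mean (see [superpose_trajectory]).
#' @return Numeric vector, one value per atom, Angstrom^2:
#'   `u2_i = (1/F) sum_f |x_fi - xbar_i|^2`.
#' @export
msd_about_mean <- function(traj) {
  coords <- traj$coords
  if (dim(coords)[1] < 2) stop("mean-square displacement needs >= 2 frames")
  mean_coords <- apply(coords, c(2, 3), mean)
  dev2 <- sweep(coords, c(2, 3), mean_coords)^2
  colMeans(apply(dev2, c(1, 2), sum))
}

#' Convert mean-square displacement to a B-factor
#'
#' The crystallographic isotropic temperature factor corresponding to a
#' mean-square displacement `u2` is `B = (8/3) * pi^2 * u2`.
#'
#' @param u2 Mean-square displacement(s), Angstrom^2 (>= 0).
#' @return B-factor(s), Angstrom^2.
#' @export
b_from_msd <- function(u2) {
  if (any(u2 < 0)) stop("mean-square displacement must be nonnegative")
  (8 / 3) * pi^2 * u2
}

.mainchain_names <- c("N", "CA", "C", "O")

new_b_profile <- function(resno, value, source, normalized = FALSE) {
  out <- tibble::tibble(resno = as.integer(resno), value = as.numeric(value))
  attr(out, "metric") <- "mainchain_b"
  attr(out, "source") <- source
  attr(out, "normalized") <- normalized
  class(out) <- c("b_profile", "flex_profile", class(out))
  out
}

# per-residue mean over main-chain atoms of one conformer-like atom table
.residue_mainchain_mean <- function(resno, name, value) {
  is_mc <- name %in% .mainchain_names
  if (!any(is_mc)) return(NULL)
  # C-alpha-only fallback when the input carries no N/C/O (e.g. CA traces)
  if (!any(name %in% setdiff(.mainchain_names, "CA"))) is_mc <- name == "CA"
  agg <- tapply(value[is_mc], resno[is_mc], mean)
  tibble::tibble(resno = as.integer(names(agg)), value = as.numeric(agg))
}

#' Main-chain B-factor profile
#'
#' For crystal structures, averages the deposited isotropic B over the
#' main-chain atoms (N, C-alpha, C, O; C-alpha only for C-alpha traces) of
#' each residue, then averages over monomers sharing a residue number. For a
#' superposed trajectory, computes per-atom mean-square displacements and
#' converts them with [b_from_msd] before the same per-residue averaging.
#'
#' @param x A [conformer], a list of conformers, or a superposed
#'   [trajectory].
#' @return A `b_profile` tibble (`resno`, `value` in Angstrom^2), with
#'   attributes `source` ("crystallographic" or "trajectory") and
#'   `normalized = FALSE`.
#' @export
mainchain_b_profile <- function(x) {
  if (inherits(x, "trajectory")) {
    u2 <- msd_about_mean(x)
    per_res <- .residue_mainchain_mean(x$atom_meta$resno, x$atom_meta$name,
                                       b_from_msd(u2))
    if (is.null(per_res)) stop("trajectory has no main-chain atoms")
    return(new_b_profile(per_res$resno, per_res$value, "trajectory"))
  }
  if (inherits(x, "conformer")) x <- list(x)
  per_conf <- lapply(x, function(cf) {
    .residue_mainchain_mean(cf$atoms$resno, cf$atoms$name, cf$atoms$b)
  })
  per_conf <- per_conf[!vapply(per_conf, is.null, logical(1))]
  if (length(per_conf) == 0) stop("no main-chain atoms in any conformer")
  all_res <- dplyr::bind_rows(per_conf)
  agg <- dplyr::summarise(dplyr::group_by(all_res, .data$resno),
                          value = mean(.data$value), .groups = "drop")
  new_b_profile(agg$resno, agg$value, "crystallographic")
}

#' Normalize a B-factor profile to zero mean and unit variance
#'
#' Uses the population (divide-by-n) standard deviation, so the normalized
#' profile has mean 0 and variance exactly 1.
#'
#' @param profile A `b_profile` (or any `flex_profile`) tibble.
#' @return The profile with standardized values and `normalized = TRUE`.
#' @export
normalize_b <- function(profile) {
  v <- profile$value
  if (length(v) < 2) stop("normalization needs at least 2 residues")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) stop("cannot normalize a constant profile (zero variance)")
  out <- profile
  out$value <- (v - mu) / sigma
  attr(out, "normalized") <- TRUE
  out
}

#' Compare two normalized per-residue profiles
#'
#' Aligns the profiles on shared residue numbers (inner join) and reports
#' their Pearson correlation together with a per-residue difference profile.
#'
#' @param p1,p2 Normalized `b_profile` tibbles (see [normalize_b]).
#' @return An object of class `profile_comparison`: a list with `pearson_r`,
#'   `n_shared`, and `diff` (tibble of `resno`, `value1`, `value2`, `delta`).
#' @export
compare_profiles <- function(p1, p2) {
  for (p in list(p1, p2)) {
    if (!isTRUE(attr(p, "normalized"))) {
      stop("profiles must be normalized before comparison (see normalize_b)")
    }
  }
  joined <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(p1)[, c("resno", "value")],
                  value1 = "value"),
    dplyr::rename(tibble::as_tibble(p2)[, c("resno", "value")],
                  value2 = "value"),
    by = "resno"
  )
  if (nrow(joined) < 3) stop("fewer than 3 shared residues between profiles")
  joined$delta <- joined$value1 - joined$value2
  structure(
    list(pearson_r = stats::cor(joined$value1, joined$value2),
         n_shared = nrow(joined), diff = joined),
    class = "profile_comparison"
  )
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("<profile_comparison> Pearson r = ", format(x$pearson_r, digits = 4),
      " over ", x$n_shared, " shared residues\n", sep = "")
  invisible(x)
}

#' @rdname compare_profiles
#' @param x A `profile_comparison` object.
#' @param ... Unused.
#' @export
glance.profile_comparison <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, n_shared = x$n_shared)
}
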