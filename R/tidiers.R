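#' Per-conformer summary of a superposition
#'
#' @param x A `superposition` object.
#' @param ... Unused.
#' @return A tibble with one row per conformer: its RMSD to the converged
#'   mean over the mapped atoms.
#' @export
tidy.superposition <- function(x, ...) {
  dev2 <- sweep(x$fitted_coords, c(2, 3), x$mean_coords)^2
  per_conf <- sqrt(rowMeans(apply(dev2, c(1, 2), sum)))
  tibble::tibble(conformer = seq_along(per_conf), rmsd_to_mean = per_conf)
}

#' @rdname tidy.superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble::tibble(
    n_conformers = dim(x$fitted_coords)[1],
    n_atoms = dim(x$fitted_coords)[2],
    iterations = x$iterations,
    converged = x$converged,
    mean_rmsd = mean(tidy(x)$rmsd_to_mean)
  )
}

#' @export
tidy.flex_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$metric <- attr(x, "metric") %||% "value"
  out
}
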