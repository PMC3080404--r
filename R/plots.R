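#' Plot a per-residue flexibility profile
#'
#' @param object A `flex_profile` (or `b_profile`) tibble.
#' @param ... Unused.
#' @return A ggplot: residue number against the profile value.
#' @export
autoplot.flex_profile <- function(object, ...) {
  metric <- attr(object, "metric") %||% "value"
  ylab <- switch(metric,
                 ca_rmsd_to_mean = "C-alpha RMSD to mean (Å)",
                 mainchain_b = if (isTRUE(attr(object, "normalized")))
                   "normalized main-chain B" else
                     "main-chain B (Å²)",
                 metric)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$resno, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue number", y = ylab) +
    ggplot2::theme_minimal()
}

#' Overlay two per-residue profiles
#'
#' The usual experimental-vs-theoretical B-factor comparison figure: two
#' normalized profiles on the same residue axis.
#'
#' @param p1,p2 `flex_profile` tibbles.
#' @param labels Length-2 character vector naming the two series.
#' @return A ggplot.
#' @export
plot_profile_overlay <- function(p1, p2,
                                 labels = c("experimental", "theoretical")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(p1)[, c("resno", "value")],
                  series = labels[1]),
    dplyr::mutate(tibble::as_tibble(p2)[, c("resno", "value")],
                  series = labels[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$value,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue number", y = "normalized B") +
    ggplot2::theme_minimal()
}

#' Scree plot of a quasiharmonic mode set
#'
#' @param object A `mode_set`.
#' @param n_modes How many leading modes to show (default 20).
#' @param ... Unused.
#' @return A ggplot of per-mode variance fractions.
#' @export
autoplot.mode_set <- function(object, n_modes = 20, ...) {
  df <- utils::head(tidy(object), n_modes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode,
                                   y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mode", y = "fraction of total motion") +
    ggplot2::theme_minimal()
}
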