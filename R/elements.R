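#' @keywords internal
#' @importFrom rlang .data
#' @importFrom utils head modifyList
#' @importFrom stats rnorm runif cor dist
"_PACKAGE"

# Boltzmann constant in units convenient for quasiharmonic amplitudes:
# kcal/mol/K is never needed because the 2kT amplitude q = sqrt(2 E lambda / kT)
# is dimensionless in (E / kT); only the ratio enters. Kept for documentation.
.kB_note <- NULL

# Element -> atomic mass (amu), standard atomic weights.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  MN = 54.938, CU = 63.546, "NA" = 22.990, K = 39.098, CL = 35.45
)

# Element -> van der Waals radius (A), Chothia-style set used for ASA.
# Carbon is treated uniformly at 1.80 A; N 1.65, O 1.40, S 1.85.
.vdw_radii <- c(
  C = 1.80, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
  H = 1.00, SE = 1.90, FE = 1.47, ZN = 1.39, MG = 1.73
)

#' Look up atomic masses for element symbols
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in amu.
#' @details Unknown elements are a hard error: silently defaulting a mass
#'   would bias every mass-weighted covariance downstream.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("no mass known for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Look up van der Waals radii for element symbols
#'
#' @param element Character vector of element symbols.
#' @param radii_set Either the string `"chothia"` (built-in table) or a named
#'   numeric vector of element -> radius overriding/extending it.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, radii_set = "chothia") {
  tab <- .vdw_radii
  if (is.numeric(radii_set)) {
    tab[toupper(names(radii_set))] <- radii_set
  } else if (!identical(radii_set, "chothia")) {
    stop("unknown radii_set: ", radii_set)
  }
  key <- toupper(trimws(element))
  r <- tab[key]
  if (anyNA(r)) {
    bad <- unique(key[is.na(r)])
    stop("no van der Waals radius known for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

# Derive an element symbol from a PDB atom name when the element column is
# blank (common in minimal hand-written files). Protein heavy-atom convention:
# first alphabetic character, except two-letter elements present in proteins.
.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  vapply(nm, function(x) {
    if (x %in% c("SE", "FE", "ZN", "MG", "MN", "CU")) return(x)
    ltr <- gsub("[^A-Z]", "", x)
    if (nchar(ltr) == 0) stop("cannot derive element from atom name '", x, "'")
    substr(ltr, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}
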