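#' ASA calculation parameters
#'
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4, a water
#'   molecule).
#' @param n_points Sphere sample count per atom (default 960).
#' @param radii_set `"chothia"` or a named numeric vector of element ->
#'   van der Waals radius overrides.
#' @return A list of class `asa_params`.
#' @export
asa_params <- function(probe_radius = 1.4, n_points = 960,
                       radii_set = "chothia") {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_points < 100) stop("n_points must be at least 100")
  structure(list(probe_radius = probe_radius, n_points = n_points,
                 radii_set = radii_set),
            class = "asa_params")
}

#' Quasi-uniform points on the unit sphere
#'
#' Deterministic golden-spiral construction: point i (0-based) sits at
#' `z = 1 - 2(i + 0.5)/n` and azimuth `i * pi * (3 - sqrt(5))`.
#'
#' @param n Number of points (>= 1).
#' @return An n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (n < 1) stop("n must be >= 1")
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Each atom's van der Waals sphere is expanded by the probe radius; its ASA
#' is `4*pi*R^2` times the fraction of quasi-uniform surface points not
#' buried inside any neighbour's expanded sphere. Results are independent of
#' atom order.
#'
#' @param conformer A [conformer].
#' @param params An [asa_params] object.
#' @return Numeric vector of per-atom ASA, Angstrom^2.
#' @export
atom_asa <- function(conformer, params = asa_params()) {
  atoms <- conformer$atoms
  xyz <- coords_matrix(conformer)
  radii <- tryCatch(
    vdw_radius(atoms$element, params$radii_set),
    error = function(e) stop("atom_asa: ", conditionMessage(e), call. = FALSE)
  )
  r_exp <- radii + params$probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(params$n_points)
  # candidate neighbours: centre distance below the sum of expanded radii
  d2 <- as.matrix(stats::dist(xyz))^2
  asa <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (r_exp[i] + r_exp)^2
    nb <- which(d2[i, ] < cutoff2)
    nb <- nb[nb != i]
    p <- pts * r_exp[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(accessible)) break
      dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      accessible <- accessible & (dd >= r_exp[j]^2)
    }
    asa[i] <- 4 * pi * r_exp[i]^2 * mean(accessible)
  }
  asa
}

# ---- ideal-geometry peptide construction (reference state) ----

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# NeRF atom placement: new atom bonded to c, with angle(new, c, b) = angle
# and dihedral(new, c, b, a) = torsion (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Side-chain Z-matrix rows per residue: name, ref atoms (a, b, c with the
# new atom bonded to c), bond (A), angle (deg), torsion (deg). CB is placed
# separately. Extended (chi = 180) conformation; ring/branch geometry is
# idealized -- adequate for a 2-decimal fractional-ASA reference state.
.sidechain_zmat <- list(
  ALA = NULL,
  SER = list(c("OG", "N", "CA", "CB", 1.417, 110.8, 180)),
  CYS = list(c("SG", "N", "CA", "CB", 1.808, 114.4, 180)),
  THR = list(c("OG1", "N", "CA", "CB", 1.433, 109.6, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
  VAL = list(c("CG1", "N", "CA", "CB", 1.521, 110.5, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, 60)),
  LEU = list(c("CG", "N", "CA", "CB", 1.530, 116.3, 180),
             c("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
             c("CD2", "CA", "CB", "CG", 1.521, 110.7, 60)),
  ILE = list(c("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
             c("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = list(c("CG", "N", "CA", "CB", 1.520, 114.1, 180),
             c("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
             c("CE", "CB", "CG", "SD", 1.791, 100.9, 180)),
  PRO = list(c("CG", "N", "CA", "CB", 1.495, 104.5, 30),
             c("CD", "CA", "CB", "CG", 1.507, 105.5, -35)),
  PHE = list(c("CG", "N", "CA", "CB", 1.502, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.390, 120.8, 90),
             c("CD2", "CA", "CB", "CG", 1.390, 120.8, -90),
             c("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.390, 120.0, 0)),
  TYR = list(c("CG", "N", "CA", "CB", 1.502, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.390, 120.8, 90),
             c("CD2", "CA", "CB", "CG", 1.390, 120.8, -90),
             c("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.390, 120.0, 0),
             c("OH", "CD1", "CE1", "CZ", 1.380, 120.0, 180)),
  TRP = list(c("CG", "N", "CA", "CB", 1.500, 113.6, 180),
             c("CD1", "CA", "CB", "CG", 1.370, 127.0, 90),
             c("CD2", "CA", "CB", "CG", 1.430, 126.6, -90),
             c("NE1", "CB", "CG", "CD1", 1.380, 110.2, 180),
             c("CE2", "CB", "CG", "CD2", 1.410, 107.2, 180),
             c("CE3", "CB", "CG", "CD2", 1.400, 133.9, 0),
             c("CZ2", "CG", "CD2", "CE2", 1.400, 122.4, 180),
             c("CZ3", "CG", "CD2", "CE3", 1.390, 118.8, 180),
             c("CH2", "CD2", "CE2", "CZ2", 1.370, 117.5, 0)),
  ASP = list(c("CG", "N", "CA", "CB", 1.516, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.249, 118.4, 90),
             c("OD2", "CA", "CB", "CG", 1.249, 118.4, -90)),
  ASN = list(c("CG", "N", "CA", "CB", 1.516, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.231, 120.8, 90),
             c("ND2", "CA", "CB", "CG", 1.328, 116.4, -90)),
  GLU = list(c("CG", "N", "CA", "CB", 1.520, 114.0, 180),
             c("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.249, 118.4, 90),
             c("OE2", "CB", "CG", "CD", 1.249, 118.4, -90)),
  GLN = list(c("CG", "N", "CA", "CB", 1.520, 114.0, 180),
             c("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.231, 120.8, 90),
             c("NE2", "CB", "CG", "CD", 1.328, 116.4, -90)),
  LYS = list(c("CG", "N", "CA", "CB", 1.520, 114.0, 180),
             c("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
             c("CE", "CB", "CG", "CD", 1.520, 111.3, 180),
             c("NZ", "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = list(c("CG", "N", "CA", "CB", 1.520, 114.0, 180),
             c("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
             c("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
             c("CZ", "CG", "CD", "NE", 1.329, 124.2, 180),
             c("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  HIS = list(c("CG", "N", "CA", "CB", 1.500, 113.8, 180),
             c("ND1", "CA", "CB", "CG", 1.378, 122.7, 90),
             c("CD2", "CA", "CB", "CG", 1.354, 131.0, -90),
             c("CE1", "CB", "CG", "ND1", 1.320, 109.0, 180),
             c("NE2", "CB", "CG", "CD2", 1.374, 107.0, 180)),
  GLY = NULL
)

#' Build an extended peptide with ideal geometry
#'
#' Constructs a fully extended (phi = psi = omega = 180 deg) peptide from
#' three-letter residue codes, with standard backbone bond lengths/angles
#' and extended side chains. The main use is the Gly-X-Gly reference state
#' for fractional side-chain accessibility.
#'
#' @param resnames Character vector of 3-letter codes, e.g.
#'   `c("GLY", "ASP", "GLY")`.
#' @param chain Chain identifier.
#' @return A [conformer].
#' @export
build_extended_peptide <- function(resnames, chain = "A") {
  resnames <- toupper(resnames)
  unknown <- setdiff(resnames, names(.sidechain_zmat))
  if (length(unknown) > 0) {
    stop("unknown residue type(s): ", paste(unknown, collapse = ", "))
  }
  rows <- list()
  serial <- 0L
  add <- function(name, resname, resno, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      serial = serial, name = name,
      element = .element_from_name(name), resname = resname,
      resno = resno, chain = chain,
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0
    )
  }
  pos <- list()  # per-residue named coordinate lists
  prev <- NULL
  for (i in seq_along(resnames)) {
    rn <- resnames[i]
    cur <- list()
    if (i == 1) {
      cur$N <- c(0, 0, 0)
      cur$CA <- c(1.458, 0, 0)
      # place first C in the xy-plane at the ideal N-CA-C angle
      cur$C <- place_atom(c(0, 1, 0), cur$N, cur$CA, 1.525, 111.0, 0)
    } else {
      cur$N <- place_atom(prev$N, prev$CA, prev$C, 1.329, 116.6, 180)
      cur$CA <- place_atom(prev$CA, prev$C, cur$N, 1.458, 121.7, 180)
      cur$C <- place_atom(prev$C, cur$N, cur$CA, 1.525, 111.0, 180)
    }
    # carbonyl O: dihedral N-CA-C-O = psi + 180; psi = 180 throughout
    cur$O <- place_atom(cur$N, cur$CA, cur$C, 1.231, 120.8, 0)
    if (rn != "GLY") {
      cur$CB <- place_atom(cur$C, cur$N, cur$CA, 1.530, 110.5, 122.6)
      for (row in .sidechain_zmat[[rn]] %||% list()) {
        nm <- row[1]
        cur[[nm]] <- place_atom(cur[[row[2]]], cur[[row[3]]], cur[[row[4]]],
                                as.numeric(row[5]), as.numeric(row[6]),
                                as.numeric(row[7]))
      }
    }
    for (nm in names(cur)) add(nm, rn, i, cur[[nm]])
    pos[[i]] <- cur
    prev <- cur
  }
  conformer(dplyr::bind_rows(rows),
            label = paste(resnames, collapse = "-"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Side-chain atom names of a residue
#'
#' Every atom that is not backbone (N, CA, C, O, OXT). Glycine's "side
#' chain" is its C-alpha (NACCESS convention), so glycine rows remain
#' computable.
#'
#' @param atom_names Character vector of atom names in the residue.
#' @param resname 3-letter residue code.
#' @return Character vector of side-chain atom names.
#' @export
sidechain_atom_names <- function(atom_names, resname) {
  if (toupper(resname) == "GLY") return(intersect("CA", atom_names))
  setdiff(atom_names, c("N", "CA", "C", "O", "OXT"))
}

.ref_cache <- new.env(parent = emptyenv())

# total side-chain ASA of residue X in the extended Gly-X-Gly tripeptide,
# computed with the same parameters as the query structure (memoised)
reference_sidechain_asa <- function(resname, params) {
  resname <- toupper(resname)
  key <- paste(resname, params$probe_radius, params$n_points,
               paste(deparse(params$radii_set), collapse = ""), sep = "|")
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  tri <- build_extended_peptide(c("GLY", resname, "GLY"))
  asa <- atom_asa(tri, params)
  a <- tri$atoms
  sc <- sidechain_atom_names(a$name[a$resno == 2], resname)
  val <- sum(asa[a$resno == 2 & a$name %in% sc])
  .ref_cache[[key]] <- val
  val
}

.sidechain_fraction_from_asa <- function(conf, asa, residue_number, params) {
  a <- conf$atoms
  in_res <- a$resno == residue_number
  if (!any(in_res)) {
    stop("residue ", residue_number, " not present in '", conf$label, "'")
  }
  resname <- a$resname[in_res][1]
  sc <- sidechain_atom_names(a$name[in_res], resname)
  if (length(sc) == 0) {
    stop("residue ", residue_number, " (", resname,
         ") has no side-chain atoms")
  }
  ref <- reference_sidechain_asa(resname, params)
  sum(asa[in_res & a$name %in% sc]) / ref
}

#' Fractional side-chain solvent accessibility of one residue
#'
#' The residue's summed side-chain ASA in the structure divided by the same
#' residue's side-chain ASA in an extended Gly-X-Gly reference tripeptide
#' computed with identical parameters. Values slightly above 1 are possible
#' (the reference is a conformation, not a supremum).
#'
#' @param conformer A [conformer].
#' @param residue_number Author residue number.
#' @param params An [asa_params].
#' @return A fraction (unitless, usually in `[0, 1]`).
#' @export
sidechain_fraction <- function(conformer, residue_number,
                               params = asa_params()) {
  asa <- atom_asa(conformer, params)
  .sidechain_fraction_from_asa(conformer, asa, residue_number, params)
}

#' Parse a residue-list string
#'
#' Accepts the form `"161:GLY,164:ASP"` and returns a tibble.
#'
#' @param txt Residue list string.
#' @return A tibble with columns `resno`, `code`.
#' @export
parse_residue_list <- function(txt) {
  parts <- strsplit(trimws(unlist(strsplit(txt, ","))), ":")
  tibble::tibble(
    resno = as.integer(vapply(parts, `[`, character(1), 1)),
    code = toupper(vapply(parts, `[`, character(1), 2))
  )
}

#' Fractional side-chain ASA of named residues averaged over conformers
#'
#' Computes [sidechain_fraction] for each listed residue in every conformer
#' containing it and averages over those conformers (e.g. all subunits of
#' one or more asymmetric units). A listed residue whose 3-letter code does
#' not match the structure is a hard error (it guards against numbering
#' mix-ups between homologues).
#'
#' @param conformers A [conformer] or list of conformers.
#' @param residue_list A tibble with `resno` and `code` columns, or a string
#'   accepted by [parse_residue_list].
#' @param params An [asa_params].
#' @return A tibble: `resno`, `code`, `n_subunits`, `fraction_mean` (raw),
#'   `fraction_2dp` (rounded to 2 decimals as conventionally reported).
#' @export
conserved_residue_report <- function(conformers, residue_list,
                                     params = asa_params()) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (is.character(residue_list)) {
    residue_list <- parse_residue_list(residue_list)
  }
  asa_list <- lapply(conformers, atom_asa, params = params)
  rows <- purrr::pmap(residue_list, function(resno, code, ...) {
    vals <- c()
    for (i in seq_along(conformers)) {
      conf <- conformers[[i]]
      in_res <- conf$atoms$resno == resno
      if (!any(in_res)) next
      found <- conf$atoms$resname[in_res][1]
      if (found != toupper(code)) {
        stop("residue ", resno, " is ", found, " in '", conf$label,
             "', expected ", toupper(code))
      }
      vals <- c(vals, .sidechain_fraction_from_asa(conf, asa_list[[i]],
                                                   resno, params))
    }
    if (length(vals) == 0) {
      warning("residue ", resno, " absent from every conformer")
      return(tibble::tibble(resno = resno, code = toupper(code),
                            n_subunits = 0L, fraction_mean = NA_real_,
                            fraction_2dp = NA_real_))
    }
    tibble::tibble(resno = resno, code = toupper(code),
                   n_subunits = length(vals),
                   fraction_mean = mean(vals),
                   fraction_2dp = round(mean(vals), 2))
  })
  dplyr::bind_rows(rows)
}
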