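#' Construct a conformer
#'
#' A conformer is one chain's worth of atoms: an ordered atom table plus a
#' label. It is the unit all ensemble and ASA operations work on.
#'
#' @param atoms A data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z`, `occ`, `b`. A `mass` column
#'   is added from the element table if absent.
#' @param label Character label, e.g. `"3CYP:D"`.
#' @return An object of class `conformer`: a list with `label` and an
#'   `atoms` tibble.
#' @export
conformer <- function(atoms, label = "conformer") {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("serial", "name", "element", "resname", "resno", "chain",
              "x", "y", "z", "occ", "b")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  blank <- is.na(atoms$element) | trimws(atoms$element) == ""
  if (any(blank)) atoms$element[blank] <- .element_from_name(atoms$name[blank])
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- element_mass(atoms$element)
  } else if (anyNA(atoms$mass)) {
    na <- is.na(atoms$mass)
    atoms$mass[na] <- element_mass(atoms$element[na])
  }
  if (any(atoms$mass <= 0)) stop("non-positive atomic mass in atom table")
  if (is.unsorted(atoms$resno)) {
    stop("residue numbers must be non-decreasing within a conformer")
  }
  if (anyDuplicated(paste(atoms$resno, atoms$name))) {
    stop("duplicate (residue_number, atom_name) pair in conformer '", label, "'")
  }
  structure(list(label = label, atoms = atoms), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", x$label, ": ", nrow(x$atoms), " atoms, residues ",
      min(x$atoms$resno), "-", max(x$atoms$resno), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.conformer <- function(x, ...) {
  dplyr::mutate(x$atoms, label = x$label, .before = 1)
}

coords_matrix <- function(conf) {
  as.matrix(conf$atoms[, c("x", "y", "z")])
}

set_coords <- function(conf, xyz) {
  conf$atoms$x <- xyz[, 1]
  conf$atoms$y <- xyz[, 2]
  conf$atoms$z <- xyz[, 3]
  conf
}

# Validate ATOM/HETATM lines before handing the file to the parser, so a
# malformed record is reported with its line number.
.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("unparseable ATOM record at line ", i, ": too short")
    }
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    num <- suppressWarnings(as.numeric(flds))
    if (anyNA(num)) {
      stop("unparseable ATOM record at line ", i,
           ": non-numeric coordinate field")
    }
  }
  invisible(TRUE)
}

# Resolve alternate locations: keep the highest-occupancy record per
# (chain, resno, name); ties broken by order of appearance in the file.
.resolve_altloc <- function(atom) {
  atom$.row <- seq_len(nrow(atom))
  atom <- dplyr::group_by(atom, .data$chain, .data$resno, .data$elety)
  atom <- dplyr::slice(
    atom, which.max(.data$o - .data$.row * 1e-9)  # max occ, first on ties
  )
  atom <- dplyr::ungroup(atom)
  atom <- dplyr::arrange(atom, .data$.row)
  atom$.row <- NULL
  atom
}

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL", "MSE")

#' Read a PDB file into a list of conformers
#'
#' Parses ATOM records (via bio3d), drops waters and hetero groups and
#' hydrogens, resolves alternate locations to the highest-occupancy copy
#' (ties broken by file order), and splits the content into one conformer
#' per (model, chain).
#'
#' @param path Path to a PDB-format text file.
#' @param model_policy `"first_model"` (default) or `"all_models"`.
#' @return A list of [conformer] objects, labelled `"<stem>:<chain>"` (with
#'   `":m<k>"` inserted for models beyond the first).
#' @export
read_pdb <- function(path, model_policy = c("first_model", "all_models")) {
  model_policy <- match.arg(model_policy)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE,
                         hex = TRUE)
  atom <- tibble::as_tibble(pdb$atom)
  keep <- atom$type == "ATOM" & atom$resid %in% .standard_aa
  if (!any(keep)) stop("no protein ATOM records found in ", path)
  n_models <- nrow(pdb$xyz)
  models <- if (model_policy == "first_model") 1L else seq_len(n_models)
  stem <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)

  out <- list()
  for (m in models) {
    at <- atom
    at[, c("x", "y", "z")] <-
      matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    at <- at[keep, ]
    at <- at[is.na(at$elesy) | toupper(at$elesy) != "H", ]
    at <- at[!grepl("^[0-9]*H", trimws(at$elety)), ]
    at <- .resolve_altloc(at)
    for (ch in unique(at$chain)) {
      sub <- at[at$chain == ch, ]
      lab <- paste0(stem, if (m > 1L) paste0(":m", m) else "", ":", ch)
      elem <- ifelse(is.na(sub$elesy) | trimws(sub$elesy) == "",
                     NA_character_, toupper(trimws(sub$elesy)))
      elem[!is.na(elem) & elem == "SE"] <- "SE"
      out[[lab]] <- conformer(
        tibble::tibble(
          serial = sub$eleno,
          name = trimws(sub$elety),
          element = elem,
          resname = sub$resid,
          resno = sub$resno,
          chain = sub$chain,
          x = sub$x, y = sub$y, z = sub$z,
          occ = ifelse(is.na(sub$o), 1, sub$o),
          b = ifelse(is.na(sub$b), 0, sub$b)
        ),
        label = lab
      )
    }
  }
  out
}

#' Write conformers to a PDB file
#'
#' Emits fixed-width ATOM records; multiple conformers become MODEL blocks.
#' Coordinates are written to 3 decimals, so `read_pdb(write_pdb(x))` is the
#' identity on names, residue numbers and coordinates at that precision.
#'
#' @param conformers A [conformer] or list of conformers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conformers, path) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  for (conf in conformers) {
    xyz <- coords_matrix(conf)
    if (any(!is.finite(xyz))) stop("non-finite coordinate in '", conf$label, "'")
    if (any(abs(xyz) >= 10000)) {
      stop("coordinate magnitude >= 10000 A overflows the PDB format")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(conformers) > 1
  for (k in seq_along(conformers)) {
    conf <- conformers[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    a <- conf$atoms
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000, nm, a$resname, substr(a$chain, 1, 1), a$resno,
      a$x, a$y, a$z, a$occ, a$b, a$element
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.normalize_ranges <- function(ranges) {
  if (is.null(ranges) || length(ranges) == 0) return(integer(0))
  if (is.numeric(ranges)) return(as.integer(ranges))
  unlist(lapply(ranges, function(r) {
    if (length(r) == 1) as.integer(r) else seq.int(r[1], r[2])
  }))
}

#' Build an ensemble with a common atom correspondence
#'
#' The atom map is the intersection of (residue_number, atom_name) pairs
#' present in every conformer, restricted to `selection` and excluding the
#' given residue ranges, ordered by residue number then name. Disordered
#' stretches absent from some monomers thus drop out automatically; ranges
#' known to be disordered can be excluded explicitly.
#'
#' @param conformers List of [conformer] objects (>= 2).
#' @param selection Atom-name filter; default `"CA"` (C-alpha only). `NULL`
#'   keeps every shared atom.
#' @param excluded_ranges Residues to exclude: an integer vector, or a list
#'   of `c(lo, hi)` ranges.
#' @return An object of class `ensemble`: conformers plus the `atom_map`
#'   tibble (`resno`, `name`).
#' @export
build_ensemble <- function(conformers, selection = "CA",
                           excluded_ranges = NULL) {
  if (length(conformers) < 2) stop("an ensemble needs at least 2 conformers")
  excl <- .normalize_ranges(excluded_ranges)
  keysets <- lapply(conformers, function(cf) {
    a <- cf$atoms
    if (!is.null(selection)) a <- a[a$name %in% selection, ]
    a <- a[!(a$resno %in% excl), ]
    paste(a$resno, a$name)
  })
  common <- Reduce(intersect, keysets)
  if (length(common) == 0) {
    sizes <- vapply(keysets, length, integer(1))
    culprit <- conformers[[which.min(sizes)]]$label
    stop("empty atom intersection across conformers (first lacking coverage: '",
         culprit, "')")
  }
  parts <- strsplit(common, " ", fixed = TRUE)
  atom_map <- tibble::tibble(
    resno = as.integer(vapply(parts, `[`, character(1), 1)),
    name = vapply(parts, `[`, character(1), 2)
  )
  atom_map <- dplyr::arrange(atom_map, .data$resno, .data$name)
  structure(
    list(conformers = conformers, atom_map = atom_map,
         excluded_ranges = excl),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", length(x$conformers), " conformers, ",
      nrow(x$atom_map), " mapped atoms\n", sep = "")
  invisible(x)
}

#' Extract mapped coordinates of an ensemble
#'
#' @param ensemble An [build_ensemble] result.
#' @return A conformers x atoms x 3 array of coordinates (Angstrom).
#' @export
ensemble_coords <- function(ensemble) {
  map_key <- paste(ensemble$atom_map$resno, ensemble$atom_map$name)
  n <- length(ensemble$conformers)
  arr <- array(NA_real_, dim = c(n, length(map_key), 3))
  for (i in seq_len(n)) {
    a <- ensemble$conformers[[i]]$atoms
    idx <- match(map_key, paste(a$resno, a$name))
    arr[i, , ] <- as.matrix(a[idx, c("x", "y", "z")])
  }
  arr
}

#' Construct a trajectory
#'
#' @param coords A frames x atoms x 3 array (Angstrom).
#' @param frame_interval Time between stored frames, ps.
#' @param atom_meta Atom table as in [conformer] (element/mass columns used).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, frame_interval, atom_meta) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be a frames x atoms x 3 array")
  }
  if (dim(coords)[1] < 2) stop("a trajectory needs at least 2 frames")
  if (frame_interval <= 0) stop("frame_interval must be positive (ps)")
  atom_meta <- tibble::as_tibble(atom_meta)
  if (nrow(atom_meta) != dim(coords)[2]) {
    stop("atom_meta rows must match the trajectory atom count")
  }
  if (!"mass" %in% names(atom_meta)) {
    atom_meta$mass <- element_mass(atom_meta$element)
  }
  structure(
    list(coords = coords, frame_interval = frame_interval,
         masses = atom_meta$mass, atom_meta = atom_meta),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<trajectory> ", d[1], " frames x ", d[2], " atoms, ",
      x$frame_interval, " ps/frame\n", sep = "")
  invisible(x)
}

#' Read a plain-text XYZ-frame trajectory
#'
#' The format is repeated standard XYZ blocks: an atom-count line, a comment
#' line, then one `<element> x y z` line per atom. The atom count must be
#' constant across frames.
#'
#' @param path Path to the text file.
#' @param frame_interval Time between frames, ps.
#' @param atom_meta Optional atom table; if omitted, a minimal one is built
#'   from the element symbols in the file.
#' @return A [trajectory].
#' @export
read_xyz_trajectory <- function(path, frame_interval, atom_meta = NULL) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames <- list()
  elements <- NULL
  n_atoms <- NA_integer_
  f <- 0L
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "") {  # blank separator/trailing line
      pos <- pos + 1L
      next
    }
    f <- f + 1L
    cnt <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(cnt)) stop("frame ", f, ": expected an atom-count line")
    if (is.na(n_atoms)) n_atoms <- cnt
    if (cnt != n_atoms) {
      stop("frame ", f, ": atom count ", cnt, " differs from first frame (",
           n_atoms, ")")
    }
    block_end <- pos + 1L + cnt
    if (block_end > length(lines)) {
      stop("frame ", f, " is truncated: expected ", cnt, " atom lines")
    }
    atom_lines <- lines[(pos + 2L):block_end]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4)
    if (length(bad) > 0) {
      stop("frame ", f, " is truncated or malformed at atom ", bad[1])
    }
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("frame ", f, ": non-numeric coordinate")
    if (is.null(elements)) {
      elements <- toupper(vapply(toks, `[`, character(1), 1))
    }
    frames[[f]] <- xyz
    pos <- block_end + 1L
  }
  if (f < 2L) stop("a trajectory needs at least 2 frames, found ", f)
  coords <- array(NA_real_, dim = c(f, n_atoms, 3))
  for (i in seq_len(f)) coords[i, , ] <- frames[[i]]
  if (is.null(atom_meta)) {
    atom_meta <- tibble::tibble(
      serial = seq_len(n_atoms), name = elements, element = elements,
      resname = "UNK", resno = seq_len(n_atoms), chain = "A",
      occ = 1, b = 0
    )
  }
  trajectory(coords, frame_interval, atom_meta)
}

#' Write a trajectory as XYZ-frame text
#'
#' @param traj A [trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  el <- traj$atom_meta$element
  for (fnum in seq_len(d[1])) {
    writeLines(c(as.character(d[2]), sprintf("frame %d", fnum)), con)
    xyz <- traj$coords[fnum, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
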