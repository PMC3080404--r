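single_atom <- function(element = "C") {
  conformer(atom_row(1, element, 1, 0, 0, 0, element = element))
}

two_atoms <- function(d, element = "C") {
  conformer(dplyr::bind_rows(
    atom_row(1, "C1", 1, 0, 0, 0, element = element),
    atom_row(2, "C2", 1, d, 0, 0, element = element)
  ))
}

test_that("sphere points are unit vectors with balanced coverage", {
  expect_equal(sqrt(sum(sphere_points(1)^2)), 1, tolerance = 1e-12)
  p <- sphere_points(960)
  expect_equal(rowSums(p^2), rep(1, 960), tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(p)^2)), 0.05)
  # near-uniform spacing: nearest-neighbour distances have low spread
  nn <- apply(as.matrix(dist(p)) + diag(1e9, 960), 1, min)
  expect_lt(sd(nn) / mean(nn), 0.2)
})

test_that("an isolated atom has its full expanded-sphere area", {
  p <- asa_params(radii_set = c(C = 1.7))
  got <- atom_asa(single_atom(), p)
  expect_equal(got, 4 * pi * 3.1^2, tolerance = 0.02)
})

test_that("a fully enclosed atom has zero accessible area", {
  shell <- sphere_points(60) * 2.0
  atoms <- dplyr::bind_rows(
    atom_row(1, "C0", 1, 0, 0, 0, element = "C"),
    atom_row(1 + seq_len(60), "CS", 2, shell[, 1], shell[, 2], shell[, 3],
             element = "C")
  )
  caged <- conformer(dplyr::mutate(atoms, serial = dplyr::row_number(),
                                   name = paste0(name, dplyr::row_number())))
  asa <- atom_asa(caged, asa_params())
  expect_equal(asa[1], 0)
})

test_that("two-sphere ASA matches the spherical-cap closed form", {
  p <- asa_params(radii_set = c(C = 1.7))
  r_exp <- 1.7 + 1.4
  for (d in c(0.5, 1.1, 2.0, 3.4, 4.8, 5.9, 6.2)) {
    h <- max(0, r_exp - d / 2)
    analytic <- 4 * pi * r_exp^2 - 2 * pi * r_exp * h
    got <- atom_asa(two_atoms(d), p)
    expect_equal(got[1], analytic, tolerance = 0.02)
    expect_equal(got[2], analytic, tolerance = 0.02)
  }
})

test_that("ASA is invariant to rigid motion and independent of atom order", {
  tri <- build_extended_peptide(c("GLY", "LEU", "GLY"))
  ref <- atom_asa(tri, asa_params())
  rot <- euler_rotation(0.4, 1.1, 2.2)
  moved <- tri
  xyz <- coords_matrix_for_test(tri) %*% t(rot) +
    matrix(c(3, -7, 11), nrow(tri$atoms), 3, byrow = TRUE)
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3]
  moved_asa <- atom_asa(moved, asa_params())
  expect_equal(sum(moved_asa), sum(ref), tolerance = 0.005)
  expect_lt(max(abs(moved_asa - ref)), 1.5)  # per-atom sampling noise, A^2
  rev_conf <- tri
  rev_conf$atoms <- tri$atoms[rev(seq_len(nrow(tri$atoms))), ]
  expect_equal(rev(atom_asa(rev_conf, asa_params())), ref,
               tolerance = 1e-12)
})

test_that("adding a neighbour never increases any atom's ASA", {
  p <- asa_params(n_points = 480)
  tri <- build_extended_peptide(c("GLY", "SER", "GLY"))
  before <- atom_asa(tri, p)
  extra <- atom_row(99, "CX", 4, 2.5, 1.0, 0.5, element = "C")
  grown <- conformer(dplyr::bind_rows(tri$atoms, extra))
  after <- atom_asa(grown, p)[seq_along(before)]
  expect_true(all(after <= before + 1e-9))
})

test_that("doubling the sphere sampling changes total ASA by < 1%", {
  tri <- build_extended_peptide(c("GLY", "ARG", "GLY"))
  t1 <- sum(atom_asa(tri, asa_params(n_points = 480)))
  t2 <- sum(atom_asa(tri, asa_params(n_points = 960)))
  expect_lt(abs(t2 - t1) / t1, 0.01)
})

test_that("the reference tripeptide has fractional accessibility 1", {
  for (rn in c("GLY", "ASP", "LEU", "ARG")) {
    tri <- build_extended_peptide(c("GLY", rn, "GLY"))
    expect_equal(sidechain_fraction(tri, 2), 1.0, tolerance = 0.02)
  }
})

test_that("a buried side chain reports fraction ~0 and errors are typed", {
  # bury a serine side chain under a dense carbon shell
  tri <- build_extended_peptide(c("GLY", "SER", "GLY"))
  og <- tri$atoms[tri$atoms$name == "OG" & tri$atoms$resno == 2, ]
  cb <- tri$atoms[tri$atoms$name == "CB" & tri$atoms$resno == 2, ]
  centre <- c(mean(c(og$x, cb$x)), mean(c(og$y, cb$y)),
              mean(c(og$z, cb$z)))
  shell <- sphere_points(80) * 3.2
  cage <- tibble::tibble(
    serial = 100 + seq_len(80), name = paste0("CG", seq_len(80)),
    element = "C", resname = "ALA", resno = 4L, chain = "A",
    x = centre[1] + shell[, 1], y = centre[2] + shell[, 2],
    z = centre[3] + shell[, 3], occ = 1, b = 0
  )
  buried <- conformer(dplyr::bind_rows(tri$atoms, cage))
  expect_lt(sidechain_fraction(buried, 2), 0.02)
  expect_error(build_extended_peptide(c("GLY", "XXX", "GLY")), "XXX")
  expect_error(sidechain_fraction(tri, 9), "not present")
})

test_that("conserved-residue reports average fractions over conformers", {
  tri <- build_extended_peptide(c("GLY", "ASP", "GLY"))
  single <- conserved_residue_report(tri, "2:ASP")
  expect_equal(single$fraction_mean, sidechain_fraction(tri, 2),
               tolerance = 1e-12)
  expect_equal(single$n_subunits, 1L)
  # hand-check the two-conformer average with planted fractions 1 and ~0
  shell <- sphere_points(120) * 3.0
  cg <- tri$atoms[tri$atoms$name == "CG" & tri$atoms$resno == 2, ]
  cage <- tibble::tibble(
    serial = 200 + seq_len(120), name = paste0("CX", seq_len(120)),
    element = "C", resname = "ALA", resno = 4L, chain = "A",
    x = cg$x + shell[, 1], y = cg$y + shell[, 2], z = cg$z + shell[, 3],
    occ = 1, b = 0
  )
  buried <- conformer(dplyr::bind_rows(tri$atoms, cage), label = "buried")
  rep2 <- conserved_residue_report(list(tri, buried), "2:ASP")
  f_open <- sidechain_fraction(tri, 2)
  f_buried <- sidechain_fraction(buried, 2)
  expect_equal(rep2$fraction_mean, (f_open + f_buried) / 2,
               tolerance = 1e-12)
  expect_equal(rep2$n_subunits, 2L)
  # residue-code mismatch is a hard error
  expect_error(conserved_residue_report(tri, "2:LEU"), "expected LEU")
  # a residue absent from one conformer averages over those containing it
  short <- build_extended_peptide(c("GLY", "ASP"))
  rep3 <- suppressWarnings(
    conserved_residue_report(list(tri, short), "3:GLY"))
  expect_equal(rep3$n_subunits, 1L)
})

test_that("residue-list strings parse to (number, code) pairs", {
  rl <- parse_residue_list("161:GLY, 164:ASP,226:arg")
  expect_equal(rl$resno, c(161L, 164L, 226L))
  expect_equal(rl$code, c("GLY", "ASP", "ARG"))
})
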