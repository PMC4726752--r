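test_that("PDB round trip preserves identifiers and coordinates to 1e-3 A", {
  ens <- make_tunnel_ensemble(2, constriction_radius = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, path)
  back <- read_structure(path)
  expect_equal(n_frames(back), 2)
  expect_identical(topology_key(back), topology_key(ens))
  expect_identical(back$res_name, ens$res_name)
  expect_identical(back$element, ens$element)
  expect_lt(max(abs(back$x - ens$x)), 1e-3 + 1e-12)
  expect_lt(max(abs(back$y - ens$y)), 1e-3 + 1e-12)
  expect_lt(max(abs(back$z - ens$z)), 1e-3 + 1e-12)

  # double round trip is exact (coordinates already at format precision)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(back, path2)
  again <- read_structure(path2)
  expect_equal(again$x, back$x, tolerance = 1e-12)
})

test_that("b-factor column survives a round trip at format precision", {
  fr <- toy_protein_frame("ACDEF")
  fr$b_factor <- c(0.12, 0.98, 0.55, 0.31, 0.77)[fr$res_seq]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fr, path)
  expect_equal(read_structure(path)$b_factor, fr$b_factor,
               tolerance = 1e-9)
})

test_that("parser cross-checks against bio3d on the same file", {
  fr <- toy_protein_frame("ACDEFGHIK")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fr, path)
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  expect_equal(unname(matrix(ref$xyz, ncol = 3, byrow = TRUE)),
               unname(cbind(fr$x, fr$y, fr$z)), tolerance = 1e-6)
  expect_identical(ref$atom$resid, fr$res_name)
  expect_identical(as.integer(ref$atom$resno), fr$res_seq)
})

test_that("inconsistent topology across models is a topology error", {
  fr <- toy_protein_frame("ACD")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fr, path)
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  broken <- c("MODEL     1", atom_lines, "ENDMDL",
              "MODEL     2", atom_lines[-1], "ENDMDL", "END")
  writeLines(broken, path)
  expect_error(read_structure(path), "topology error")
})

test_that("malformed numeric columns raise a parse error naming the line", {
  fr <- toy_protein_frame("AC")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fr, path)
  lines <- readLines(path)
  substr(lines[3], 31, 38) <- "  xx.yyy"
  writeLines(lines, path)
  expect_error(read_structure(path), "line 3")
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AGLY A   2       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       8.000   0.000   0.000  0.50  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  ens <- read_structure(path)
  expect_equal(nrow(ens), 2)
  expect_equal(ens$x, c(9, 1))  # B wins on occupancy; A wins the tie
})

test_that("selections follow the atom-class and clause semantics", {
  fr <- toy_protein_frame("ACDEFGHIKL")
  expect_equal(nrow(select_atoms(fr, "calpha")), 10)
  expect_equal(select_atoms(fr, "chain:A resid:2 mainchain")$name,
               c("N", "CA", "C", "O"))
  expect_equal(nrow(select_atoms(fr, "resid:3-5 name:CA")), 3)
  expect_warning(out <- select_atoms(fr, "chain:Z"), "matched no atoms")
  expect_equal(nrow(out), 0)
  # heavy excludes hydrogens
  h <- fr[1, ]
  h$name <- "H1"; h$element <- "H"
  withH <- as_ensemble(dplyr::bind_rows(fr, h))
  expect_equal(nrow(select_atoms(withH, "heavy")), nrow(fr))
})

test_that("measure_distance is Euclidean, symmetric, zero on identity", {
  atoms <- as_ensemble(tibble::tibble(
    name = c("P1", "P2"), element = "C", res_name = "XXX",
    chain = "A", res_seq = 1:2,
    x = c(0, 3), y = c(0, 4), z = c(0, 0)))
  expect_equal(measure_distance(atoms, "A:1:P1", "A:2:P2")$distance, 5)
  expect_equal(measure_distance(atoms, "A:2:P2", "A:1:P1")$distance, 5)
  expect_equal(measure_distance(atoms, "A:1:P1", "A:1:P1")$distance, 0)
  expect_error(measure_distance(atoms, "A:9:P1", "A:1:P1"), "A:9:P1")
})

test_that("superposition is exact under rigid motion and underdetermined below 3 atoms", {
  fr <- toy_protein_frame("ACDEFG")
  expect_equal(superpose(fr, fr)$rmsd, 0, tolerance = 1e-12)
  moved <- rigid_move(fr, seed = 4)
  fit <- superpose(moved, fr)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # rigid pre-transformation cannot change the rmsd
  jit <- toy_protein_frame("ACDEFG", jitter = 0.3, seed = 8)
  r1 <- superpose(jit, fr)$rmsd
  r2 <- superpose(rigid_move(jit, seed = 5), fr)$rmsd
  expect_lt(abs(r1 - r2), 1e-6)
  expect_error(superpose(fr[fr$name == "CA" & fr$res_seq <= 2, ], fr,
                         expr = "calpha"), "underdetermined")
})

test_that("superposition agrees with bio3d's fit on the same atom pairs", {
  fr <- toy_protein_frame("ACDEFGHIKL")
  jit <- rigid_move(toy_protein_frame("ACDEFGHIKL", jitter = 0.5,
                                      seed = 21), seed = 22)
  ours <- superpose(jit, fr)$rmsd
  xyz_fix <- as.numeric(t(cbind(fr$x, fr$y, fr$z)))
  xyz_mob <- as.numeric(t(cbind(jit$x, jit$y, jit$z)))
  theirs <- bio3d::rmsd(xyz_fix, xyz_mob, fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-4)
})

test_that("rmsd_series matches a hand-computed radial expansion oracle", {
  base <- make_reference_site(4 * (1 - diag(4)), n_decoys = 0, seed = 2)
  centroid <- colMeans(cbind(base$x, base$y, base$z))
  eps <- c(0, 0.1, 0.25)
  frames <- lapply(seq_along(eps), function(k) {
    fr <- base
    fr$frame <- k - 1L
    fr$x <- centroid[1] + (1 + eps[k]) * (base$x - centroid[1])
    fr$y <- centroid[2] + (1 + eps[k]) * (base$y - centroid[2])
    fr$z <- centroid[3] + (1 + eps[k]) * (base$z - centroid[3])
    fr
  })
  ens <- as_ensemble(dplyr::bind_rows(frames))
  got <- rmsd_series(ens, frames[[1]], expr = "heavy")
  radial_rms <- sqrt(mean(rowSums(sweep(cbind(base$x, base$y, base$z), 2,
                                        centroid)^2)))
  # symmetric dilation about the centroid: optimal fit is the identity,
  # so rmsd is exactly eps * radial rms
  expect_equal(got$rmsd, eps * radial_rms, tolerance = 1e-9)
  # identical frames -> all zeros
  same <- as_ensemble(dplyr::bind_rows(lapply(0:2, function(k) {
    fr <- base; fr$frame <- k; fr
  })))
  expect_equal(rmsd_series(same, base, expr = "heavy")$rmsd, rep(0, 3),
               tolerance = 1e-12)
})

test_that("vdW radii come from the shipped Bondi table, unknowns error", {
  expect_equal(vdw_radius("C"), 1.70)
  expect_equal(vdw_radius("N"), 1.55)
  expect_equal(vdw_radius(c("O", "S")), c(1.52, 1.80))
  expect_error(vdw_radius("Xx"), "Xx")
})
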