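test_that("aligned FASTA reading validates widths and alphabet", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "AC-DE", ">s2", "ACGDE", ">s3", "acgde"), path)
  expect_message(msa <- read_msa(path), "uppercased")
  expect_equal(nrow(msa), 3)
  expect_equal(attr(msa, "L"), 5)
  expect_equal(msa$seq[3], "ACGDE")
  writeLines(c(">s1", "ACDE", ">bad", "ACD"), path)
  expect_error(read_msa(path), "bad")
  # round trip
  msa2 <- make_msa(5, c(1, 0.5, 0), seed = 1)
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_msa(msa2, p2)
  expect_equal(read_msa(p2)$seq, msa2$seq)
})

test_that("column conservation follows the normalized-entropy closed form", {
  msa <- chokepoint:::new_msa(tibble::tibble(
    id = paste0("s", 1:4),
    seq = c("AAAR", "AGAN", "AGGD", "AGGC")))
  prof <- column_conservation(msa)
  expect_equal(prof$score[1], 1.0)                       # monomorphic
  expect_equal(prof$score[2], 1 - (-0.25 * log(0.25) -
                                     0.75 * log(0.75)) / log(20))
  expect_equal(prof$score[3], 1 - log(2) / log(20), tolerance = 1e-9)
  # 20 distinct residues -> maximal entropy, score 0
  all20 <- chokepoint:::new_msa(tibble::tibble(
    id = paste0("t", 1:20),
    seq = c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")))
  expect_equal(column_conservation(all20)$score, 0, tolerance = 1e-12)
})

test_that("gap handling: exclusion from frequencies, flags, all-gap NA", {
  msa <- chokepoint:::new_msa(tibble::tibble(
    id = paste0("s", 1:4),
    seq = c("A--", "A--", "AG-", "-G-")))
  prof <- column_conservation(msa)
  expect_equal(prof$score[1], 1.0)        # gaps excluded: all-A column
  expect_equal(prof$gap_fraction, c(0.25, 0.5, 1))
  expect_true(prof$flagged[3])
  expect_true(is.na(prof$score[3]))
})

test_that("conservation is invariant under row permutation", {
  msa <- make_msa(30, seq(0, 1, length.out = 12), seed = 9)
  shuffled <- chokepoint:::new_msa(msa[rev(seq_len(nrow(msa))), ])
  expect_equal(column_conservation(msa)$score,
               column_conservation(shuffled)$score)
})

test_that("pairwise alignment reproduces small hand-enumerated cases", {
  # identical sequences: identity map
  m <- align_pair("ACDEFG", "ACDEFG")
  expect_equal(m$pos_a, 1:6)
  expect_equal(m$pos_b, 1:6)
  # 'ACD' vs 'AD' under match +1 / mismatch -1 / linear gap -1:
  # optimum skips C, mapping {1->1, 3->2}
  m2 <- align_pair("ACD", "AD", substitution = "simple",
                   gap_open = 0, gap_extend = 1)
  expect_equal(m2$pos_a, c(1, 3))
  expect_equal(m2$pos_b, c(1, 2))
  expect_equal(attr(m2, "score"), 1)
  expect_error(align_pair("AC1", "AD"), "alphabet")
})

test_that("alignment score equals the exhaustive-enumeration optimum", {
  letters4 <- c("A", "C", "D", "E")
  withr::with_seed(101, {
    for (trial in 1:40) {
      la <- sample(1:7, 1); lb <- sample(1:7, 1)
      a <- paste(sample(letters4, la, TRUE), collapse = "")
      b <- paste(sample(letters4, lb, TRUE), collapse = "")
      sub <- matrix(sample(-3:3, 16, TRUE), 4, 4,
                    dimnames = list(letters4, letters4))
      sub <- (sub + t(sub)) / 2
      go <- sample(c(0, 2, 5), 1)
      ge <- sample(c(0.5, 1, 2), 1)
      got <- attr(align_pair(a, b, substitution = sub,
                             gap_open = go, gap_extend = ge), "score")
      want <- enumerate_align_score(a, b, sub, go, ge)
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("score(%s, %s, open=%g, ext=%g)",
                                   a, b, go, ge))
    }
  })
})

test_that("residue mapping transfers positions and is injective over matches", {
  m <- align_pair("ACDEFGH", "ACEFGH")
  expect_equal(map_residue(m, 1), 1)
  expect_equal(map_residue(m, 5), 4)
  expect_true(is.na(map_residue(m, 3)) || all(diff(m$pos_b) > 0))
  expect_true(all(diff(m$pos_a) > 0) && all(diff(m$pos_b) > 0))
  expect_error(map_residue(m, 0), "range")
  expect_error(map_residue(m, 99), "range")
  # a deletion in sequence B leaves the deleted position unmapped and
  # shifts downstream numbering, the homolog-mutation mapping pattern
  ins <- align_pair("MKLVAATTG", "MKLATTG", substitution = "simple",
                    gap_open = 2, gap_extend = 1)
  expect_equal(map_residue(ins, 9), 7)
})

test_that("profile projection writes scores into B-factors with sentinels", {
  fr <- toy_protein_frame("ACDEF")
  msa <- chokepoint:::new_msa(tibble::tibble(
    id = c("target", "h1", "h2"),
    seq = c("ACDEF", "ACDEG", "ACDE-")))
  prof <- column_conservation(msa)
  ann <- project_profile(prof, msa, "target", fr, chain = "A")
  per_res <- ann$b_factor[ann$name == "CA"]
  expect_equal(per_res, prof$score, tolerance = 1e-12)
  expect_equal(length(attr(ann, "unmapped")), 0)
  # an extra structure residue is sentinel-flagged and reported
  fr6 <- toy_protein_frame("ACDEFG")
  ann6 <- project_profile(prof, msa, "target", fr6, chain = "A")
  expect_equal(ann6$b_factor[ann6$res_seq == 6][1], -1)
  expect_equal(attr(ann6, "unmapped"), "6 ")
  # scores survive a structure round trip at format precision
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ann, path)
  expect_equal(read_structure(path)$b_factor, ann$b_factor,
               tolerance = 5e-3)
  # identity mismatch between structure and alignment sequence warns
  msa_bad <- chokepoint:::new_msa(tibble::tibble(
    id = "target", seq = "AWDEF"))
  expect_warning(project_profile(column_conservation(msa_bad), msa_bad,
                                 "target", fr, chain = "A"),
                 "mismatch")
})

test_that("synthetic homolog superposition via sequence pairing recovers zero rmsd", {
  a <- toy_protein_frame("ACDEFGHIKL")
  # homolog missing residues 4 and 7, then rigidly moved
  keep <- !a$res_seq %in% c(4, 7)
  b <- a[keep, ]
  b$res_seq <- match(b$res_seq, sort(unique(b$res_seq)))
  b <- rigid_move(as_ensemble(b), seed = 31)
  m <- align_pair("ACDEFGHIKL", "ACDFGIKL")
  fit <- superpose(b, a, expr = "mainchain",
                   pairing = structure(
                     tibble::tibble(pos_a = m$pos_b, pos_b = m$pos_a),
                     class = class(m)))
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$n_atoms, 32)  # 8 paired residues x 4 main-chain atoms
})
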