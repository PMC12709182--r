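test_that("PDB parsing builds an ordered RNA structure", {
  s <- read_pdb_structure(two_residue_pdb())
  expect_s3_class(s, "rna_structure")
  expect_equal(s$L, 2L)
  expect_equal(s$residues$resid, c("G", "C"))
  expect_equal(s$residues$index, 1:2)
  expect_false(any(s$atoms$hydrogen))
})

test_that("protein-only input raises an empty-structure error", {
  prot <- paste(c(pdb_atom(1, " CA", "ALA", "A", 1, 0, 0, 0),
                  pdb_atom(2, " CA", "GLY", "A", 2, 3.8, 0, 0),
                  "END"), collapse = "\n")
  expect_error(read_pdb_structure(prot), "no RNA residues")
})

test_that("altloc atoms resolve to the highest-occupancy copy", {
  txt <- paste(c(
    pdb_atom(1, " N9", "G", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom(2, " N9", "G", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_atom(3, " C1'", "G", "A", 1, 1, 1, 1),
    pdb_atom(4, " N1", "U", "A", 2, 5, 0, 0),
    "END"), collapse = "\n")
  s <- read_pdb_structure(txt)
  n9 <- s$atoms[s$atoms$elety == "N9", ]
  expect_equal(nrow(n9), 1L) # single coordinate kept
  expect_equal(unlist(n9[, c("x", "y", "z")], use.names = FALSE), c(9, 9, 9))
})

test_that("hydrogens are retained but flagged", {
  txt <- paste(c(pdb_atom(1, " N9", "A", "A", 1, 0, 0, 0),
                 pdb_atom(2, " H8", "A", "A", 1, 0.5, 0.5, 0, element = "H"),
                 pdb_atom(3, " N1", "U", "A", 2, 6, 0, 0),
                 "END"), collapse = "\n")
  s <- read_pdb_structure(txt)
  expect_equal(sum(s$atoms$hydrogen), 1L)
  expect_equal(nrow(s$atoms), 3L)
})

test_that("multi-chain residues are renumbered 1..L keeping originals", {
  txt <- paste(c(pdb_atom(1, " N9", "G", "A", 7, 0, 0, 0),
                 pdb_atom(2, " N1", "C", "A", 8, 5, 0, 0),
                 pdb_atom(3, " N9", "A", "B", 1, 20, 0, 0),
                 "END"), collapse = "\n")
  s <- read_pdb_structure(txt)
  expect_equal(s$residues$index, 1:3)
  expect_equal(s$residues$resno, c(7L, 8L, 1L))
  expect_equal(s$residues$chain, c("A", "A", "B"))
  sB <- read_pdb_structure(txt, chain = "B")
  expect_equal(sB$L, 1L)
})

test_that("reference atoms follow the purine/pyrimidine rule", {
  expect_equal(reference_atom("A"), "N9")
  expect_equal(reference_atom("G"), "N9")
  expect_equal(reference_atom("U"), "N1")
  expect_equal(reference_atom("C"), "N1")
  expect_equal(reference_atom("PSU"), "N1") # pseudouridine maps to U
  expect_error(reference_atom("XYZ"), "unknown residue")
  withr::with_options(list(rnatopo.modified_residues = c(XYZ = "A")),
                      expect_equal(reference_atom("XYZ"), "N9"))
})

test_that("nitrogen-mode extraction matches hand enumeration on a collinear chain", {
  s <- read_pdb_structure(collinear_pdb(6, spacing = 1.8))
  cm <- extract_contact_map(s, contact_definition("nitrogen"))
  # distances: (1,5)=7.2, (1,6)=9.0, (2,6)=7.2; all others with sep>=4 exceed 9.5
  expect_equal(cm$contacts, rbind(c(i = 1L, j = 5L), c(1L, 6L), c(2L, 6L)),
               ignore_attr = "dimnames")
  expect_equal(cm$contacts[, 2] - cm$contacts[, 1] >= 4, c(TRUE, TRUE, TRUE))
})

test_that("threshold comparison is inclusive in nitrogen mode", {
  txt <- paste(c(pdb_atom(1, " N9", "G", "A", 1, 0, 0, 0),
                 pdb_atom(2, " N1", "C", "A", 2, 2, 0, 0),
                 pdb_atom(3, " N1", "U", "A", 3, 4, 0, 0),
                 pdb_atom(4, " N9", "A", "A", 4, 6, 0, 0),
                 pdb_atom(5, " N1", "C", "A", 5, 9.5, 0, 0),
                 "END"), collapse = "\n")
  s <- read_pdb_structure(txt)
  cm <- extract_contact_map(s, contact_definition("nitrogen"))
  expect_true(any(cm$contacts[, 1] == 1 & cm$contacts[, 2] == 5)) # exactly 9.5
})

test_that("single-residue structures give an empty map", {
  txt <- paste(c(pdb_atom(1, " N9", "G", "A", 1, 0, 0, 0), "END"),
               collapse = "\n")
  cm <- extract_contact_map(read_pdb_structure(txt))
  expect_equal(nrow(cm$contacts), 0L)
})

test_that("missing reference atoms raise an error naming the residue", {
  txt <- paste(c(pdb_atom(1, " C1'", "G", "A", 1, 0, 0, 0),
                 pdb_atom(2, " N1", "C", "A", 2, 5, 0, 0),
                 "END"), collapse = "\n")
  s <- read_pdb_structure(txt)
  expect_error(extract_contact_map(s), "missing reference atom N9")
})

test_that("with equal thresholds the heavy-mode set contains the nitrogen-mode set", {
  s <- generate_toy_structure(n_helices = 2, helix_len = 5, seed = 31)
  nm <- extract_contact_map(s, contact_definition("nitrogen", threshold = 9.5))
  hm <- extract_contact_map(s, contact_definition("heavy", threshold = 9.5,
                                                  inclusive = TRUE))
  expect_true(all(paste(nm$contacts[, 1], nm$contacts[, 2]) %in%
                    paste(hm$contacts[, 1], hm$contacts[, 2])))
})

test_that("extraction is invariant under rigid-body motion", {
  s <- generate_toy_structure(n_helices = 1, helix_len = 6, seed = 13)
  base <- extract_contact_map(s)
  set.seed(99)
  for (k in 1:5) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2)) # random unit quaternion -> rotation matrix
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1]),
      2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1]),
      2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE)
    t0 <- stats::rnorm(3, sd = 30)
    xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
    s2 <- s
    s2$atoms$x <- xyz[, 1] + t0[1]
    s2$atoms$y <- xyz[, 2] + t0[2]
    s2$atoms$z <- xyz[, 3] + t0[3]
    expect_equal(extract_contact_map(s2)$contacts, base$contacts)
  }
})

test_that("contact tables round-trip and normalize", {
  cm <- read_contact_table("1 10\n2 12\n", L = 20)
  expect_equal(nrow(cm$contacts), 2L)
  dup <- read_contact_table("10 1\n1 10\n", L = 20)
  expect_equal(dup$contacts, rbind(c(i = 1L, j = 10L)), ignore_attr = "dimnames")
  expect_error(read_contact_table("1 1\n", L = 20), "i == j")
  expect_error(read_contact_table("1 25\n", L = 20), "out of \\[1, 20\\]")
  # write then read is the identity, including the definition header
  s <- generate_toy_structure(n_helices = 1, helix_len = 5, seed = 3)
  orig <- extract_contact_map(s)
  back <- read_contact_table(write_contact_table(orig))
  expect_equal(back$contacts, orig$contacts)
  expect_equal(back$L, orig$L)
  expect_equal(back$definition$mode, "nitrogen")
  expect_equal(back$definition$threshold, 9.5)
})

test_that("scores in contact tables survive parsing", {
  cm <- read_contact_table("1 10 0.9\n2 12 0.4\n", L = 20)
  expect_equal(attr(cm$contacts, "scores"), c(0.9, 0.4))
})

test_that("PDB writer and reader round-trip toy structures", {
  s <- generate_toy_structure(n_helices = 1, helix_len = 4, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, f)
  s2 <- read_pdb_structure(f)
  expect_equal(s2$L, s$L)
  expect_equal(s2$residues$resid, s$residues$resid)
  expect_equal(extract_contact_map(s2)$contacts, extract_contact_map(s)$contacts)
})
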