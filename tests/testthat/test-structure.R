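test_that("PDB parsing is faithful and resolves models and altlocs", {
  p <- write_temp_pdb(list(
    atomrec("N", "ALA", 1, 1.234, 2.345, 3.456, "N"),
    atomrec("CA", "ALA", 1, 4.001, 5.002, 6.003, "C"),
    atomrec("C", "ALA", 1, 7.100, 8.200, 9.300, "C")))
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$x, c(1.234, 4.001, 7.100), tolerance = 1e-3)
  expect_equal(s$atoms$elem, c("N", "C", "C"))
  expect_false(any(s$atoms$het))

  # multi-model: model 2 coordinates differ by the per-model shift
  p2 <- write_temp_pdb(list(
    atomrec("CA", "GLY", 1, 0, 0, 0, "C", shift_per_model = c(1, 0, 0)),
    atomrec("CA", "GLY", 2, 3, 0, 0, "C", shift_per_model = c(1, 0, 0)),
    atomrec("CA", "GLY", 3, 0, 3, 0, "C", shift_per_model = c(1, 0, 0))),
    models = 3)
  s1 <- read_structure(p2, model = 1)
  s2 <- read_structure(p2, model = 2)
  expect_equal(s2$atoms$x, s1$atoms$x + 1)
  expect_error(read_structure(p2, model = 9), "model")

  # altloc: highest occupancy wins
  p3 <- write_temp_pdb(list(
    atomrec("CA", "SER", 1, 0, 0, 0, "C", alt = "A", occ = 0.4),
    atomrec("CA", "SER", 1, 9, 9, 9, "C", alt = "B", occ = 0.6),
    atomrec("CB", "SER", 1, 1, 1, 1, "C"),
    atomrec("N", "SER", 1, 2, 2, 2, "N")))
  s3 <- read_structure(p3)
  ca <- s3$atoms[s3$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9)
})

test_that("ligand proximity uses min heavy-atom distance, inclusive", {
  mk <- function(res_x) write_temp_pdb(list(
    atomrec("C1", "LIG", 90, 0, 0, 0, "C", het = TRUE),
    atomrec("CA", "ALA", 1, res_x, 0, 0, "C"),
    atomrec("CA", "GLY", 2, 20, 0, 0, "C"),
    atomrec("H", "ALA", 1, 2, 0, 0, "H")))   # hydrogen must not count
  near <- ligand_proximal_residues(read_structure(mk(4.9)), "LIG", 5.0)
  expect_true(1 %in% near$resno)
  expect_false(2 %in% near$resno)
  far <- ligand_proximal_residues(read_structure(mk(5.1)), "LIG", 5.0)
  expect_false(1 %in% far$resno)

  expect_error(ligand_proximal_residues(read_structure(mk(4)), "XYZ"),
               "LIG")
})

test_that("proximity is monotone in the cutoff on a random structure", {
  set.seed(21)
  atoms <- list(atomrec("C1", "LIG", 99, 0, 0, 0, "C", het = TRUE))
  for (i in 1:30) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2)) * runif(1, 2, 12)
    atoms[[i + 1]] <- atomrec("CA", "ALA", i, v[1], v[2], v[3], "C")
  }
  s <- read_structure(write_temp_pdb(atoms))
  r4 <- ligand_proximal_residues(s, "LIG", 4)$resno
  r5 <- ligand_proximal_residues(s, "LIG", 5)$resno
  r6 <- ligand_proximal_residues(s, "LIG", 6)$resno
  expect_true(all(r4 %in% r5))
  expect_true(all(r5 %in% r6))
  expect_gt(length(r6), length(r4))
})

test_that("position mapping translates numbering and reports unmapped", {
  p <- write_temp_pdb(list(
    atomrec("CA", "LEU", 257, 0, 0, 0, "C"),
    atomrec("CA", "PHE", 285, 5, 0, 0, "C")))
  s <- read_structure(p)
  mp <- map_positions_to_structure(c(267, 295, 300), s, offset = -10)
  expect_equal(mp$selection$resno, c(257, 285))
  expect_equal(mp$selection$reference_resno, c(267, 295))
  expect_equal(mp$unmapped, 300)

  mp0 <- map_positions_to_structure(c(257, 285), s, offset = 0)
  expect_equal(mp0$selection$resno, c(257, 285))
})

test_that("residue group distances: com, ca and min_heavy modes", {
  p <- write_temp_pdb(list(
    atomrec("CA", "ALA", 1, 0, 0, 0, "C"),
    atomrec("CA", "GLY", 2, 3, 4, 0, "C"),
    atomrec("CA", "VAL", 3, 0, 0, 0, "C"),
    atomrec("CB", "VAL", 3, 2, 0, 0, "C"),
    atomrec("CA", "SER", 4, 5, 0, 0, "C")))
  s <- read_structure(p)
  a <- residue_selection("A", 1)
  b <- residue_selection("A", 2)
  for (m in c("com", "ca", "min_heavy")) {
    expect_equal(residue_group_distance(s, a, b, m), 5.0)
  }
  # com of equal-mass atoms at x = 0, 2 vs a single atom at x = 5
  expect_equal(residue_group_distance(s, residue_selection("A", 3),
                                      residue_selection("A", 4), "com"),
               4.0)
  expect_equal(residue_group_distance(s, a, a, "com"), 0.0)

  # min_heavy <= ca and <= com for whole-residue selections
  expect_lte(residue_group_distance(s, residue_selection("A", 3),
                                    residue_selection("A", 4),
                                    "min_heavy"),
             residue_group_distance(s, residue_selection("A", 3),
                                    residue_selection("A", 4), "ca"))
  # ca mode on a residue without CA errors
  p2 <- write_temp_pdb(list(
    atomrec("C1", "LIG", 9, 0, 0, 0, "C", het = TRUE),
    atomrec("CA", "ALA", 1, 1, 0, 0, "C")))
  s2 <- read_structure(p2)
  expect_error(residue_group_distance(s2, residue_selection("A", 9),
                                      residue_selection("A", 1), "ca"),
               "zero atoms")
})

test_that("static distances are invariant under rigid transforms", {
  set.seed(31)
  atoms <- list(atomrec("C1", "LIG", 50, 0.5, 0.2, -0.1, "C", het = TRUE))
  for (i in 1:8) {
    v <- rnorm(3, sd = 4)
    atoms[[i + 1]] <- atomrec("CA", "ALA", i, v[1], v[2], v[3], "C")
  }
  s <- read_structure(write_temp_pdb(atoms))
  a <- residue_selection("A", 2)
  b <- residue_selection("A", 7)
  d0 <- residue_group_distance(s, a, b, "com")
  prox0 <- ligand_proximal_residues(s, "LIG", 6)$resno
  s_t <- s
  xyz <- apply_random_rigid(as.matrix(s$atoms[, c("x", "y", "z")]), 5)
  s_t$atoms$x <- xyz[, 1]; s_t$atoms$y <- xyz[, 2]; s_t$atoms$z <- xyz[, 3]
  expect_equal(residue_group_distance(s_t, a, b, "com"), d0,
               tolerance = 1e-9)
  expect_equal(ligand_proximal_residues(s_t, "LIG", 6)$resno, prox0)
})

test_that("the bundled synthetic domain reproduces the documented map", {
  p <- system.file("extdata", "gafa_synthetic.pdb", package = "coevdyn")
  s <- read_structure(p)
  expect_gt(nrow(s$atoms), 100)
  expect_true("PCG" %in% s$atoms$resid[s$atoms$het])
  # the four binding-site positions in human numbering, offset -10
  mp <- map_positions_to_structure(c(230, 266, 283, 285), s, offset = -10)
  expect_equal(length(mp$unmapped), 0)
  prox <- ligand_proximal_residues(s, "PCG", 5.0)
  expect_true(all(mp$selection$resno %in% prox$resno))
  # the distant coevolving pair sits ~5.3 A apart and outside the site
  expect_false(257 %in% prox$resno)
  expect_false(285 %in% prox$resno)
  d <- residue_group_distance(s, residue_selection("A", 257),
                              residue_selection("A", 285), "ca")
  expect_equal(d, 5.3, tolerance = 0.01)
})
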