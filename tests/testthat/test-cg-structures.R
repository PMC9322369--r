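# PDB reading, coarse-graining, mutation and residue matching.

test_that("read_pdb_model parses records and applies the dialect rules", {
  p <- write_fixture_pdb(two_residue_lines())
  m <- read_pdb_model(p)
  expect_s3_class(m, "aa_model")
  expect_equal(nrow(m$atoms), 8)
  expect_equal(length(unique(paste(m$atoms$chain, m$atoms$resno))), 2)

  # altloc: only A (or blank) retained
  alt <- c(two_residue_lines(),
           pdb_atom_line(9, "CB", "ALA", "A", 1, 9, 9, 9, altloc = "B",
                         element = "C"))
  m2 <- read_pdb_model(write_fixture_pdb(alt))
  cb <- m2$atoms[m2$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 2.0)

  # no CA atoms anywhere -> invalid structure
  noca <- write_fixture_pdb(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"))
  expect_error(read_pdb_model(noca), "CA")
  expect_error(read_pdb_model(tempfile()), "cannot read")
})

test_that("coarse_grain places the united side particle at the heavy-atom
          centroid", {
  p <- write_fixture_pdb(two_residue_lines())
  cg <- coarse_grain(read_pdb_model(p))
  expect_s3_class(cg, "cg_structure")
  expect_equal(nrow(cg$residues), 2)
  # ALA: single CB -> side particle at CB
  expect_equal(unlist(cg$residues[1, c("sc_x", "sc_y", "sc_z")],
                      use.names = FALSE), c(2.0, -0.8, -1.2))
  # GLY: no side particle
  expect_true(is.na(cg$residues$sc_x[2]))
  expect_equal(cg$residues$klass, c("nonpolar", "nonpolar"))

  # LYS with five collinear side-chain heavy atoms -> centroid
  lys <- c(pdb_atom_line(1, "N", "LYS", "A", 1, -10, 0, 0, element = "N"),
           pdb_atom_line(2, "CA", "LYS", "A", 1, -9, 1, 0, element = "C"),
           pdb_atom_line(3, "C", "LYS", "A", 1, -8, 0, 0, element = "C"),
           pdb_atom_line(4, "O", "LYS", "A", 1, -8, -1.2, 0, element = "O"),
           pdb_atom_line(5, "CB", "LYS", "A", 1, 0, 0, 0, element = "C"),
           pdb_atom_line(6, "CG", "LYS", "A", 1, 2, 0, 0, element = "C"),
           pdb_atom_line(7, "CD", "LYS", "A", 1, 4, 0, 0, element = "C"),
           pdb_atom_line(8, "CE", "LYS", "A", 1, 6, 0, 0, element = "C"),
           pdb_atom_line(9, "NZ", "LYS", "A", 1, 8, 0, 0, element = "N"))
  cgl <- coarse_grain(read_pdb_model(write_fixture_pdb(lys)))
  expect_equal(unlist(cgl$residues[1, c("sc_x", "sc_y", "sc_z")],
                      use.names = FALSE), c(4, 0, 0))
  expect_equal(cgl$residues$klass, "ionizable")
  expect_equal(cgl$residues$sign, 1L)
  expect_equal(cgl$residues$pka_water, 10.5)

  # missing backbone atom on a non-terminal residue is a structural error
  broken <- two_residue_lines()[-1]   # drop N of residue 1
  expect_error(coarse_grain(read_pdb_model(write_fixture_pdb(broken))),
               "missing backbone")
})

test_that("residue count is preserved by coarse-graining", {
  for (seed in 1:5) {
    cg <- rand_structure(seed)
    p <- tempfile(fileext = ".pdb")
    write_cg_pdb(cg, p)
    back <- coarse_grain(read_pdb_model(p))
    expect_equal(nrow(back$residues), nrow(cg$residues))
  }
})

test_that("mutate_residue updates the table fields and keeps coordinates", {
  cg <- make_helix(helix_spec("LAKLALSLA"))
  key <- list("A", 3L, "")
  mut <- mutate_residue(cg, key, "SER")   # LYS -> SER, a K588S-style change
  i <- 3
  expect_equal(mut$residues$name[i], "SER")
  expect_equal(mut$residues$sign[i], 0L)
  expect_equal(mut$residues$klass[i], "polar")
  expect_true(is.na(mut$residues$pka_water[i]))
  expect_equal(mut$residues$sc_x[i], cg$residues$sc_x[i])
  # all other residues untouched
  expect_equal(mut$residues[-i, ], cg$residues[-i, ])

  # nonpolar -> nonpolar keeps the class
  mut2 <- mutate_residue(cg, list("A", 4L, ""), "ALA")  # LEU -> ALA
  expect_equal(mut2$residues$klass[4], "nonpolar")
  expect_equal(mut2$residues$name[4], "ALA")

  expect_error(mutate_residue(cg, list("A", 99L, ""), "ALA"), "no residue")
  expect_error(mutate_residue(cg, key, "XYZ"), "unknown residue type")
})

test_that("mutation followed by the inverse mutation restores the
          structure", {
  cg <- make_helix(helix_spec("LAKLDLSLA"))
  for (m in list(c(3L, "SER", "LYS"), c(5L, "ALA", "ASP"),
                 c(7L, "HIS", "SER"))) {
    key <- list("A", as.integer(m[1]), "")
    round <- mutate_residue(mutate_residue(cg, key, m[2]), key, m[3])
    expect_equal(round$residues, cg$residues)
  }
})

test_that("match_residues pairs identical keys and names", {
  cg <- make_helix(helix_spec("LAKLDLSLAM"))
  m <- match_residues(cg, cg)
  expect_equal(nrow(m$pairs), 10)
  expect_equal(m$pairs[, 1], m$pairs[, 2])
  expect_length(m$unmatched_a, 0)

  # b missing its last residue
  b <- memcg:::.new_cg(cg$residues[-10, ], label = "b")
  mb <- match_residues(cg, b)
  expect_equal(nrow(mb$pairs), 9)
  expect_equal(mb$unmatched_a, 10L)
  expect_length(mb$unmatched_b, 0)

  # name mismatch without a declared mutation map -> unmatched
  c_ <- mutate_residue(cg, list("A", 3L, ""), "SER")
  mc_ <- match_residues(cg, c_)
  expect_equal(nrow(mc_$pairs), 9)
  expect_equal(mc_$unmatched_a, 3L)
  expect_equal(mc_$unmatched_b, 3L)
  # with the mutation declared, the pair is kept
  md <- match_residues(cg, c_, mutations = c("A|3|" = "SER"))
  expect_equal(nrow(md$pairs), 10)
})

test_that("write_cg_pdb round-trips coordinates to 1e-3 A", {
  cg <- make_helix(helix_spec("LAKLDGSLA"))
  p <- tempfile(fileext = ".pdb")
  write_cg_pdb(cg, p)
  back <- coarse_grain(read_pdb_model(p))
  for (cc in c("ca_x", "ca_y", "ca_z", "n_x", "o_z", "sc_x", "sc_y")) {
    expect_equal(back$residues[[cc]], cg$residues[[cc]], tolerance = 1e-3)
  }
  # GLY rows carry no SC1 record
  lines <- readLines(p)
  expect_false(any(grepl("SC1 GLY", lines)))
  expect_true(any(grepl("SC1 ALA", lines)))
  # empty structure cannot be written
  empty <- memcg:::.new_cg(cg$residues[0, ])
  expect_error(write_cg_pdb(empty, tempfile()), "empty")
})
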