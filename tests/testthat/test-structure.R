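test_that("minimal one-atom PDB parses into the full hierarchy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 15.00           C",
    "END"), f)
  s <- readStructure(f)
  expect_s4_class(s, "PDBStructure")
  expect_identical(chainIds(s), "A")
  expect_identical(nrow(s@atoms), 1L)
  expect_equal(unname(unlist(s@atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(s@atoms$b, 15)
})

test_that("altloc conflicts resolve to the highest occupancy", {
  s <- readStructure(altlocPdbFile())
  ca <- s@atoms[s@atoms$atom == "CA" & s@atoms$resno == 1, ]
  expect_identical(nrow(ca), 1L)
  expect_identical(ca$altloc, "A")
  expect_equal(ca$occupancy, 0.6)
})

test_that("altloc resolution never increases the atom count and ties keep file order", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50 11.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.50 12.00           C",
    "END"), f)
  s <- readStructure(f)
  expect_identical(nrow(s@atoms), 1L)
  expect_identical(s@atoms$altloc, "A")   # tie -> first in file
})

test_that("write/read round-trip preserves the model to PDB precision", {
  s <- makeChain(25, "random-walk", seed = 11, bfactor = 33.3)
  s@cell <- c(124.5, 124.5, 77.5, 90, 90, 90)
  s@spacegroup <- "P41"
  s@auPerCell <- 4L
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  cr <- grep("^CRYST1", readLines(f), value = TRUE)
  expect_length(cr, 1)
  expect_match(cr, "124.500 +124.500 +77.500 +90.00 +90.00 +90.00 P 41")
  s2 <- readStructure(f)
  expect_identical(nrow(s2@atoms), nrow(s@atoms))
  expect_identical(s2@atoms$resno, s@atoms$resno)
  expect_equal(s2@atoms$b, s@atoms$b)
  expect_equal(s2@atoms$occupancy, s@atoms$occupancy)
  for (col in c("x", "y", "z"))
    expect_lt(max(abs(s2@atoms[[col]] - s@atoms[[col]])), 1e-3)
  expect_equal(s2@cell, s@cell)
  expect_identical(s2@spacegroup, "P41")
  expect_identical(s2@auPerCell, 4L)
})

test_that("empty structure writes header/END only and coordinate overflow errors", {
  s <- new("PDBStructure", id = "empty",
           atoms = makeChain(1)@atoms[0, ])
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  expect_identical(readLines(f), "END")

  big <- makeChain(5)
  big@atoms$x[1] <- 1e5
  expect_error(writeStructure(big, tempfile(fileext = ".pdb")), "overflow")
})

test_that("unreadable input and unknown chains give informative errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", f)
  expect_error(readStructure(f), "parse|atom")
  expect_error(readStructure(tempfile(fileext = ".pdb")), "not found")
  s <- makeChain(5)
  expect_error(selectAtoms(s, atomSelection("Z")), "unknown chain")
})

test_that("mmCIF input parses atoms and cell metadata", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell.length_a   124.500",
    "_cell.length_b   124.500",
    "_cell.length_c   77.500",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 41'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 1.000 2.000 3.000 1.00 15.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.000 5.000 6.000 1.00 16.00 ? 2 GLY A CA 1",
    "#"), f)
  s <- readStructure(f)
  expect_identical(nrow(s@atoms), 2L)
  expect_equal(s@cell, c(124.5, 124.5, 77.5, 90, 90, 90))
  expect_identical(s@spacegroup, "P41")
  expect_identical(s@auPerCell, 4L)
})

test_that("range selections implement the published residue arithmetic", {
  # chain numbered 1-281, model 2-272 selected -> 271 residues
  s <- makeChain(281, "extended")
  sel <- selectAtoms(s, atomSelection("A", include = c(2, 272)))
  expect_identical(attr(sel, "nResidues"), 271L)

  # all of 1-272 except residue 1, 140-145 and 251-272 -> 243 residues
  sel2 <- selectAtoms(s, atomSelection(
    "A", include = c(1, 272),
    exclude = list(1, c(140, 145), c(251, 272))))
  expect_identical(attr(sel2, "nResidues"), 243L)
  expect_identical(nrow(sel2), 243L)

  # whole-chain CA selection on a 10-residue chain -> 10 atoms
  s10 <- makeChain(10)
  expect_identical(nrow(selectAtoms(s10, atomSelection("A"))), 10L)
})

test_that("selection algebra matches direct set arithmetic on gap-free chains", {
  set.seed(42)
  s <- makeChain(200, "extended")
  for (i in 1:10) {
    inc <- sort(sample(200, 2))
    exc <- sort(sample(200, 2))
    got <- attr(selectAtoms(s, atomSelection("A", include = inc,
                                             exclude = exc)), "nResidues")
    want <- length(setdiff(seq(inc[1], inc[2]), seq(exc[1], exc[2])))
    expect_identical(got, as.integer(want))
  }
})

test_that("waters are flagged and excluded from selections by default", {
  s <- makeChain(5)
  wat <- s@atoms[1, ]
  wat$resname <- "HOH"; wat$resno <- 100L; wat$atom <- "O"; wat$het <- TRUE
  s@atoms <- rbind(s@atoms, wat)
  sel <- selectAtoms(s, atomSelection("A", atomNames = "*"))
  expect_false(any(sel$resname == "HOH"))
  selW <- selectAtoms(s, atomSelection("A", atomNames = "*"),
                      includeWaters = TRUE)
  expect_true(any(selW$resname == "HOH"))
})

test_that("class validity catches bad occupancy, B-factors, cells and ranges", {
  s <- makeChain(3)
  bad <- s@atoms; bad$occupancy[1] <- 1.5
  expect_error(new("PDBStructure", id = "x", atoms = bad), "occupancy")
  bad <- s@atoms; bad$b[1] <- -2
  expect_error(new("PDBStructure", id = "x", atoms = bad), "B-factors")
  expect_error(new("PDBStructure", id = "x", atoms = s@atoms,
                   cell = c(10, 10, 10, 90, 90, 190)), "angles")
  expect_error(atomSelection("A", include = c(10, 2)), "start")
})
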