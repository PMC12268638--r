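test_that("a minimal Calpha-only PDB parses with cell and space group", {
  f <- write_toy_pdb(tempfile(fileext = ".pdb"))
  s <- readStructure(f)
  expect_s4_class(s, "Structure")
  expect_equal(nAtoms(s), 3L)
  expect_equal(unique(atoms(s)$chain), "A")
  expect_equal(atoms(s)$resno, 1:3)
  expect_equal(unitCell(s), c(78, 80, 70, 90, 90, 90))
  expect_equal(spaceGroup(s), "P 21 21 21")
})

test_that("altloc collapse keeps highest occupancy, ties alphabetical", {
  f <- write_toy_pdb(tempfile(fileext = ".pdb"), lines = c(
    "ATOM      4  CA ATHR A   4      10.000   2.000   3.000  0.60 10.00           C",
    "ATOM      5  CA BTHR A   4      10.100   2.000   3.000  0.40 10.00           C",
    "ATOM      6  CA CVAL A   5      13.000   2.000   3.000  0.50 10.00           C",
    "ATOM      7  CA BVAL A   5      13.100   2.000   3.000  0.50 10.00           C"))
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 5L)
  expect_equal(a$alt[a$resno == 4], "A")          # higher occupancy wins
  expect_equal(a$alt[a$resno == 5], "B")          # tie -> first label
  expect_equal(a$x[a$resno == 4], 10.0)
  # collapse is idempotent: writing and re-reading changes nothing
  f2 <- tempfile(fileext = ".pdb")
  writeStructure(s, f2)
  expect_equal(atoms(readStructure(f2))$x, a$x)
})

test_that("PDB round-trip preserves atoms, names, coords and cell", {
  tl <- makeTwoLobe(twoLobeParams(thetaOpen = 25, noiseSd = 0.2, seed = 4))
  s <- initialize(tl$structure, unitCell = c(50, 60, 70, 90, 90, 90),
                  spaceGroup = "P 1")
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_equal(nAtoms(s2), nAtoms(s))
  expect_equal(atoms(s2)$elety, atoms(s)$elety)
  expect_equal(atoms(s2)$resno, atoms(s)$resno)
  expect_equal(as.matrix(atoms(s2)[, c("x", "y", "z")]),
               as.matrix(atoms(s)[, c("x", "y", "z")]),
               tolerance = 5e-4, ignore_attr = TRUE)
  expect_equal(unitCell(s2), unitCell(s))
  # residue numbers beyond PDB fixed columns refuse to format
  big <- toy_chain(c(1, 2, 10000))
  expect_error(writeStructure(big, tempfile(fileext = ".pdb")),
               "fixed-column")
  expect_error(writeStructure(newStructure(atoms(s)[0, ]),
                              tempfile(fileext = ".pdb")))
})

test_that("mmCIF atom_site records parse with cell metadata", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy",
    "_cell.length_a 78.000", "_cell.length_b 80.000",
    "_cell.length_c 70.000", "_cell.angle_alpha 90.00",
    "_cell.angle_beta 90.00", "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M \"P 21 21 21\"",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 2.000 2.000 3.000 1.00 10.00 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 5.000 2.000 3.000 1.00 10.00 2 GLY A CA 1",
    "ATOM 3 C CA . SER A 1 3 ? 8.000 2.000 3.000 1.00 10.00 3 SER A CA 1"),
    f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 3L)
  expect_equal(atoms(s)$resno, 1:3)
  expect_equal(unitCell(s), c(78, 80, 70, 90, 90, 90))
  expect_equal(spaceGroup(s), "P 21 21 21")
})

test_that("unreadable and empty files produce informative errors", {
  expect_error(readStructure(tempfile()), "not found")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(readStructure(f), "parse|empty")
})

test_that("selectAtoms honours ranges, disorder and wildcard chains", {
  s <- toy_chain(1:100)
  sel <- atomSelection("A", list(c(10, 12)))
  expect_equal(nrow(selectAtoms(s, sel)), 3L)
  s2 <- toy_chain(setdiff(1:100, 11))          # residue 11 disordered
  expect_equal(nrow(selectAtoms(s2, sel)), 2L)
  expect_equal(selectAtoms(s2, sel)$resno, c(10, 12))
  # wildcard chain: both chains, in chain order
  two <- newStructure(rbind(atoms(toy_chain(1:5, "B")),
                            atoms(toy_chain(1:5, "A"))))
  got <- selectAtoms(two, atomSelection("*", list(c(1, 5))))
  expect_equal(got$chain, rep(c("A", "B"), each = 5))
  # full range selects every Calpha exactly once
  full <- selectAtoms(s, atomSelection("A", NULL))
  expect_equal(nrow(full), 100L)
  expect_false(anyDuplicated(full$resno) > 0)
  expect_lte(nrow(full), nAtoms(s))
})

test_that("selection parsing and interval normalisation", {
  sel <- parseSelection("A:180-270,271-450")
  expect_equal(sel@chain, "A")
  # adjacent intervals merge
  expect_equal(unname(sel@ranges), matrix(c(180L, 450L), 1))
  sel2 <- parseSelection("*:5")
  expect_equal(unname(sel2@ranges), matrix(c(5L, 5L), 1))
  expect_error(atomSelection("A", list(c(10, 5))), "lower")
  expect_error(parseSelection("A:x-y"))
})

test_that("chainSequence maps positions to author numbering", {
  s <- newStructure(data.frame(chain = "A", resno = 1:3,
                               resid = c("ALA", "GLY", "SER"),
                               elety = "CA", elesy = "C",
                               x = c(0, 4, 8), y = 0, z = 0))
  cs <- chainSequence(s, "A")
  expect_equal(cs$sequence, "AGS")
  expect_equal(cs$resno, 1:3)
  # modified residue becomes X; waters and ions are not polymer
  s2 <- newStructure(data.frame(chain = "A", resno = c(1, 2, 3, 101),
                                resid = c("ALA", "SEP", "GLY", "HOH"),
                                elety = c("CA", "CA", "CA", "O"),
                                elesy = c("C", "C", "C", "O"),
                                x = c(0, 4, 8, 20), y = 0, z = 0))
  expect_equal(chainSequence(s2, "A")$sequence, "AXG")
  expect_error(chainSequence(s, "Z"), "chain")
})

test_that("insertion codes are carried through matching keys", {
  lines <- c(
    "ATOM      4  CA  THR A   3A      9.000   2.000   3.000  1.00 10.00           C")
  f <- write_toy_pdb(tempfile(fileext = ".pdb"), lines)
  s <- readStructure(f)
  a <- atoms(s)
  expect_true("A" %in% a$insert)
  expect_equal(sum(a$resno == 3), 2L)   # 3 and 3A are distinct residues
  f2 <- tempfile(fileext = ".pdb")
  writeStructure(s, f2)
  expect_equal(atoms(readStructure(f2))$insert, a$insert)
})
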