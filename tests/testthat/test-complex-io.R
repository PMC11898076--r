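# Structure reading, writing and binding-site extraction.

test_that("SDF ligand reading preserves atoms, bonds and charges", {
  dir <- withr::local_tempdir()
  ben <- buildBenzene()
  p <- file.path(dir, "benzene.sdf")
  writeLigandSDF(ben, p)
  mol <- readLigand(p)
  expect_equal(sum(atoms(mol)$element == "C"), 6)
  expect_equal(sum(atoms(mol)$element == "H"), 6)
  ring_bonds <- bonds(mol)[atoms(mol)$element[bonds(mol)$i] == "C" &
                             atoms(mol)$element[bonds(mol)$j] == "C", ]
  expect_equal(nrow(ring_bonds), 6)
  expect_length(gradeFP:::aromaticRings(mol), 1)

  # formal charges survive the M CHG block
  pq <- file.path(dir, "ma.sdf")
  writeLigandSDF(buildMethylammonium(), pq)
  ma <- readLigand(pq)
  expect_equal(atoms(ma)$formal_charge[1], 1L)
  expect_equal(sum(atoms(ma)$formal_charge), 1L)
})

test_that("degenerate SDF inputs are rejected with a parse error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.sdf")
  writeLines(c("empty", "  none", "",
               "  0  0  0  0  0  0  0  0  0  0999 V2000",
               "M  END", "$$$$"), p)
  expect_error(readLigand(p), "no atoms")
  p2 <- file.path(dir, "flat.sdf")
  writeLines(c("flat", "  prog              2D", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0",
               "    1.5000    0.0000    0.0000 C   0  0",
               "  1  2  1  0", "M  END", "$$$$"), p2)
  expect_error(readLigand(p2), "2-D")
  expect_error(readLigand(file.path(dir, "nothere.sdf")), "does not exist")
})

test_that("MOL2 write/read round-trips coordinates at format precision", {
  dir <- withr::local_tempdir()
  lig <- ligand(makeHbondFixture())
  p <- file.path(dir, "l.mol2")
  writeLigandMOL2(lig, p)
  m1 <- readLigand(p, format = "MOL2")
  expect_equal(nrow(atoms(m1)), nrow(atoms(lig)))
  expect_equal(as.matrix(atoms(m1)[, c("x", "y", "z")]),
               as.matrix(atoms(lig)[, c("x", "y", "z")]),
               tolerance = 1e-4, ignore_attr = TRUE)
  # second pass is bit-stable: the written representation is a fixed point
  p2 <- file.path(dir, "l2.mol2")
  writeLigandMOL2(m1, p2)
  m2 <- readLigand(p2, format = "MOL2")
  expect_identical(as.matrix(atoms(m2)[, c("x", "y", "z")]),
                   as.matrix(atoms(m1)[, c("x", "y", "z")]))
})

test_that("PDB receptor reading resolves altLocs and deduces elements", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "alt.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB AALA A   1       2.000   1.400   0.000  0.60  0.00           C",
    "ATOM      4  CB BALA A   1       2.100   1.300   0.100  0.40  0.00           C",
    "ATOM      5  C   ALA A   1       2.000  -1.400   0.000  1.00  0.00           C",
    "ATOM      6  O   ALA A   1       3.200  -1.500   0.000  1.00  0.00",
    "END"), p)
  rec <- readReceptor(p)
  a <- atoms(rec)
  expect_equal(sum(a$atom_name == "CB"), 1)       # one altLoc kept
  expect_equal(a$x[a$atom_name == "CB"], 2.0)     # the higher-occupancy one
  expect_equal(a$element[a$atom_name == "O"], "O")  # from the atom name
  expect_equal(sum(a$element != "H"), 5)
  expect_equal(length(unique(a$residue_id)), 1)
})

test_that("receptor PDB round-trip preserves coordinates to 0.001 A", {
  dir <- withr::local_tempdir()
  rec <- receptor(makeHbondFixture())
  p <- file.path(dir, "rec.pdb")
  writeReceptorPDB(rec, p)
  r2 <- readReceptor(p)
  expect_equal(nrow(atoms(r2)), nrow(atoms(rec)))
  expect_lt(max(abs(as.matrix(atoms(r2)[, c("x", "y", "z")]) -
                      as.matrix(atoms(rec)[, c("x", "y", "z")]))), 1e-3)
  expect_identical(atoms(r2)$element, atoms(rec)$element)
})

test_that("mmCIF receptor path parses a minimal atom_site loop", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "mini.cif")
  writeLines(c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "#"), p)
  rec <- readReceptor(p, format = "mmCIF")
  expect_equal(nrow(atoms(rec)), 2)
  expect_equal(atoms(rec)$element, c("N", "C"))
})

test_that("binding-site extraction selects whole residues within cutoff", {
  # two single-residue fragments: one near the ligand, one far
  near <- gradeFP:::buildSerineFragment()
  far <- gradeFP:::buildSerineFragment()
  fa <- atoms(far)
  fa$x <- fa$x + 20
  fa$residue_id <- "A:SER:2"
  combined <- methods::new("MolecularStructure",
                           atoms = rbind(atoms(near), fa),
                           bonds = bonds(near), name = "two-residues")
  lig <- buildMethanol(o_pos = c(4, 0, 0), acceptor = c(0, 0, 0))
  cplx <- proteinLigandComplex(combined, lig)
  env <- extractBindingSite(cplx, cutoff = 7)
  expect_setequal(env@sourceResidues, "A:SER:1")
  expect_equal(nrow(atoms(env)), nrow(atoms(near)))

  # 50 A separation: empty environment, not an error
  lig_far <- buildMethanol(o_pos = c(80, 0, 0), acceptor = c(77, 0, 0))
  env0 <- extractBindingSite(proteinLigandComplex(combined, lig_far), 7)
  expect_equal(nrow(atoms(env0)), 0)

  # superset-monotone in the cutoff
  env6 <- extractBindingSite(cplx, 6)
  env9 <- extractBindingSite(cplx, 9)
  expect_true(all(env6@atoms$receptor_index %in% env9@atoms$receptor_index))
})

test_that("binding-site selection is invariant under atom-record order", {
  cplx <- makeHbondFixture()
  rec <- receptor(cplx)
  env1 <- extractBindingSite(cplx, 7)
  perm <- rev(seq_len(nrow(atoms(rec))))
  rec2 <- methods::new("MolecularStructure",
                       atoms = atoms(rec)[perm, ],
                       bonds = data.frame(i = integer(), j = integer(),
                                          order = numeric()),
                       name = rec@name)
  rownames(rec2@atoms) <- NULL
  env2 <- extractBindingSite(proteinLigandComplex(rec2, ligand(cplx)), 7)
  key <- function(e) {
    a <- atoms(e)
    sort(sprintf("%s|%.4f|%.4f|%.4f", a$element, a$x, a$y, a$z))
  }
  expect_identical(key(env1), key(env2))
})

test_that("polar hydrogens are exactly the H atoms bonded to N, O or S", {
  lig <- buildMethanol()
  ph <- isPolarHydrogen(lig)
  a <- atoms(lig)
  adj <- gradeFP:::adjacencyList(lig)
  manual <- vapply(seq_len(nrow(a)), function(i) {
    a$element[i] == "H" && any(a$element[adj[[i]]] %in% c("N", "O", "S"))
  }, logical(1))
  expect_identical(ph, manual)
  expect_equal(sum(ph), 1)   # only the hydroxyl hydrogen
  ma <- buildMethylammonium()
  expect_equal(sum(isPolarHydrogen(ma)), 3)
})

test_that("rule-based protonation adds hydroxyl/amine hydrogens only", {
  # serine fragment with hydrogens stripped
  rec <- gradeFP:::buildSerineFragment()
  a <- atoms(rec)
  keep <- a$element != "H"
  bare <- methods::new("MolecularStructure", atoms = a[keep, ],
                       bonds = data.frame(i = integer(), j = integer(),
                                          order = numeric()),
                       name = "bare")
  rownames(bare@atoms) <- NULL
  bare <- perceiveBonds(bare)
  prot <- addPolarHydrogens(bare)
  added <- atoms(prot)$element == "H"
  expect_gt(sum(added), 0)
  expect_true(all(isPolarHydrogen(prot)[added]))
  # structures with complete hydrogens pass through unchanged
  expect_identical(nrow(atoms(addPolarHydrogens(rec))), nrow(atoms(rec)))
})
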