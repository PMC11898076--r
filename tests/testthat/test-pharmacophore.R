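# Feature perception, Sybyl subtyping, hydrophobic placement and the
# pose-independent ligand block.

## small inline builders for typing checks
build_acetamide <- function() {
  # CH3-C(=O)-NH2
  coords <- rbind(c(0, 0, 0),       # CH3 C
                  c(1.51, 0, 0),    # carbonyl C
                  c(2.12, 1.06, 0), # O
                  c(2.18, -1.18, 0),# N
                  c(-0.36, 1.02, 0), c(-0.36, -0.51, 0.88),
                  c(-0.36, -0.51, -0.88),
                  c(3.19, -1.18, 0), c(1.74, -2.06, 0))
  molecularStructure(c("C", "C", "O", "N", "H", "H", "H", "H", "H"), coords,
                     data.frame(i = c(1, 2, 2, 1, 1, 1, 4, 4),
                                j = c(2, 3, 4, 5, 6, 7, 8, 9),
                                order = c(1, 2, 1, 1, 1, 1, 1, 1)),
                     name = "acetamide")
}

build_ethanol <- function() {
  coords <- rbind(c(0, 0, 0), c(1.52, 0, 0), c(2.00, 1.33, 0),
                  c(2.96, 1.33, 0),
                  c(-0.36, 1.02, 0), c(-0.36, -0.51, 0.88),
                  c(-0.36, -0.51, -0.88), c(1.88, -0.52, 0.88),
                  c(1.88, -0.52, -0.88))
  molecularStructure(c("C", "C", "O", "H", "H", "H", "H", "H", "H"), coords,
                     data.frame(i = c(1, 2, 3, 1, 1, 1, 2, 2),
                                j = c(2, 3, 4, 5, 6, 7, 8, 9), order = 1),
                     name = "ethanol")
}

build_bromopyridine <- function() {
  # pyridine ring (N at position 1), Br para to N
  ang <- (0:5) * pi / 3
  ring <- t(vapply(ang, function(a) 1.39 * c(cos(a), sin(a), 0), numeric(3)))
  el <- c("N", rep("C", 5))
  hs <- t(vapply(ang[c(2, 3, 5, 6)], function(a) {
    2.47 * c(cos(a), sin(a), 0)
  }, numeric(3)))
  br <- 1.39 * c(cos(pi), sin(pi), 0) * (1.90 + 1.39) / 1.39
  coords <- rbind(ring, hs, br)
  el <- c(el, rep("H", 4), "Br")
  bonds <- data.frame(i = c(1:6, 2, 3, 5, 6, 4),
                      j = c(2:6, 1, 7, 8, 9, 10, 11),
                      order = c(2, 1, 2, 1, 2, 1, rep(1, 5)))
  molecularStructure(el, coords, bonds, name = "4-bromopyridine")
}

test_that("Sybyl subtyping follows the vocabulary rules", {
  st_am <- assignSybylTypes(build_acetamide())
  expect_equal(st_am[4], "N.am")
  expect_equal(st_am[3], "O.2")
  st_eth <- assignSybylTypes(build_ethanol())
  expect_equal(st_eth[3], "O.3")
  st_ac <- assignSybylTypes(buildAcetate())
  expect_equal(unname(st_ac[3:4]), c("O.co2", "O.co2"))  # equivalent oxygens
  st_py <- assignSybylTypes(build_bromopyridine())
  expect_equal(st_py[1], "N.ar")
  st_ma <- assignSybylTypes(buildMethylammonium())
  expect_equal(st_ma[1], "N.4")
  # every N/O/S atom gets exactly one subtype; others are OTHER
  for (mol in list(build_acetamide(), buildAcetate(), buildMethanol())) {
    st <- assignSybylTypes(mol)
    nos <- atoms(mol)$element %in% c("N", "O", "S")
    expect_true(all(st[!nos] == "OTHER"))
    expect_true(all(st[nos] %in% c(gradeFP:::.SYBYL_VOCAB, "OTHER")))
  }
})

test_that("HBD features are emitted once per donor hydrogen", {
  f <- perceiveFeatures(buildMethylamine())
  expect_equal(sum(f$type == "HBD"), 2)   # -NH2 contributes two donors
  f3 <- perceiveFeatures(buildMethylammonium())
  expect_equal(sum(f3$type == "HBD"), 3)  # -NH3+ three
  f1 <- perceiveFeatures(buildMethanol())
  expect_equal(sum(f1$type == "HBD"), 1)  # -OH one
})

test_that("feature perception covers AR, HBA, XBD with geometry", {
  f <- perceiveFeatures(buildBenzene())
  ar <- f[f$type == "AR", ]
  expect_equal(nrow(ar), 1)
  expect_equal(c(ar$x, ar$y, ar$z), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sqrt(ar$dirx^2 + ar$diry^2 + ar$dirz^2), 1, tolerance = 1e-9)

  fb <- perceiveFeatures(build_bromopyridine())
  expect_equal(sum(fb$type == "XBD"), 1)
  hba <- fb[fb$type == "HBA", ]
  expect_equal(nrow(hba), 1)
  expect_equal(hba$subtype, "N.ar")
  # XBA mirrors the HBA atom set
  expect_equal(sum(fb$type == "XBA"), nrow(hba))

  # ionizable groups
  expect_equal(sum(perceiveFeatures(buildAcetate())$type == "NI"), 1)
  expect_equal(sum(perceiveFeatures(buildMethylammonium())$type == "PI"), 1)
})

test_that("hydrophobic features obey the increment threshold", {
  # methanol: both heavy atoms fall below 0.15
  expect_equal(nrow(placeHydrophobicFeatures(buildMethanol())), 0)
  # any emitted feature carries weight >= 0.15, on the atom position
  pr <- buildPropane()
  h <- placeHydrophobicFeatures(pr)
  expect_true(all(h$weight >= 0.15))
  inc <- atomLogPIncrements(pr)
  heavy <- which(atoms(pr)$element != "H")
  expect_equal(nrow(h), sum(inc[heavy] >= 0.15))   # brute-force recount
  expect_equal(h$weight, inc[h$parent])
  # threshold is configurable
  h_hi <- placeHydrophobicFeatures(pr, threshold = 0.4)
  expect_equal(nrow(h_hi), sum(inc[heavy] >= 0.4))
})

test_that("ligand properties match definitions on reference molecules", {
  p <- ligandProfile(buildBenzene())
  expect_equal(p$heavy_atom_count, 6)
  expect_equal(p$rotatable_bond_count, 0)
  expect_equal(p$tpsa, 0)
  p2 <- ligandProfile(build_ethanol())
  # both ethanol single bonds touch a terminal heavy atom
  expect_equal(p2$rotatable_bond_count, 0)
  expect_equal(p2$tpsa, 20.23)
  # amide C-N is not rotatable
  p3 <- ligandProfile(build_acetamide())
  expect_equal(p3$rotatable_bond_count, 0)
  # total hydrophobic weight equals the sum over emitted H features
  for (mol in list(buildPropane(), buildBenzene(), buildBromobenzene())) {
    pp <- ligandProfile(mol)
    hf <- pp$features[pp$features$type == "H", ]
    expect_equal(pp$total_hydrophobic_weight, sum(hf$weight),
                 tolerance = 1e-9)
  }
})

test_that("pose-independent vectors have the published lengths and order", {
  p <- ligandProfile(buildMethylamine())
  v13 <- poseIndependentVector(p, "GRADE")
  v31 <- poseIndependentVector(p, "XGRADE")
  expect_length(v13, 13)
  expect_length(v31, 31)
  expect_equal(names(v13)[1:8],
               paste(c("PI", "NI", "AR", "H", "HBD", "HBA", "XBD", "XBA"),
                     "feature count"))
  expect_equal(names(v13)[9:13],
               c("heavy atom count", "rotatable bond count",
                 "total hydrophobic feature weight", "XlogP", "TPSA"))
})

test_that("X-GRADE subtype counts partition the generic GRADE counts", {
  mols <- list(buildMethylamine(), buildMethanol(), buildAcetate(),
               build_acetamide(), build_bromopyridine(),
               buildMethylammonium(), ligand(makeHbondFixture()))
  for (mol in mols) {
    p <- ligandProfile(mol)
    g <- poseIndependentVector(p, "GRADE")
    x <- poseIndependentVector(p, "XGRADE")
    # generic (OTHER) + subtype blocks == GRADE totals (0-based 4, 8:15)
    expect_equal(unname(x[5] + sum(x[9:16])), unname(g[5]))
    expect_equal(unname(x[6] + sum(x[17:26])), unname(g[6]))
  }
})

test_that("the ligand block ignores pose and receptor entirely", {
  cplx <- makeHbondFixture()
  p0 <- poseIndependentVector(ligandProfile(ligand(cplx)), "GRADE")
  set.seed(42)
  for (k in 1:3) {
    rot <- random_rotation_matrix()
    tr <- rnorm(3, 0, 10)
    moved <- rigid_transform_complex(cplx, rot, tr)
    p1 <- poseIndependentVector(ligandProfile(ligand(moved)), "GRADE")
    expect_equal(p1, p0, tolerance = 1e-9)
  }
})
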