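# Distance/angle kernels, pair scores, aggregation and coverage.

test_that("distance kernel: plateau, support bounds and ramp midpoints", {
  p <- defaultInteractionParams()[["HBD:HBA"]]   # 2.5 / 2.8 / 3.2 / 3.8
  expect_equal(distanceScore(3.0, p), 1)
  expect_equal(distanceScore((2.8 + 3.2) / 2, p), 1)
  expect_equal(distanceScore(4.8, p), 0)
  expect_equal(distanceScore(2.4, p), 0)
  expect_equal(distanceScore(2.65, p), 0.5)   # lower ramp midpoint
  expect_equal(distanceScore(3.5, p), 0.5)    # upper ramp midpoint
  r <- seq(0, 5, by = 0.01)
  v <- distanceScore(r, p)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v[r <= 2.8]) >= 0))    # monotone ramps
  expect_true(all(diff(v[r >= 3.2]) <= 0))
})

test_that("angle kernel: ideal geometry scores 1, beyond tolerance 0", {
  expect_equal(gradeFP:::angleKernel(0, 50), 1)
  expect_equal(gradeFP:::angleKernel(55, 50), 0)
  expect_equal(gradeFP:::angleKernel(25, 50), 0.5)
  # hydrophobic pairs carry no angle term
  hh <- defaultInteractionParams()[["H:H"]]
  f1 <- random_features(1); f2 <- random_features(1)
  expect_equal(angleScore(f1[1, ], f2[1, ], hh), 1)
})

test_that("pair score composes C * DS * AS", {
  hh <- defaultInteractionParams()[["H:H"]]
  mk <- function(x, w) {
    f <- random_features(1); f$x <- x; f$y <- 0; f$z <- 0; f$weight <- w
    f
  }
  # hydrophobic pair at plateau distance: FIS = product of weights
  ps <- pairScore(mk(0, 0.3)[1, ], mk(4.0, 0.5)[1, ], hh)
  expect_equal(ps$fis, 0.15)
  expect_equal(ps$c, 0.15)
  expect_equal(ps$ds, 1)
  # out of range: DS = 0 regardless of weights
  ps0 <- pairScore(mk(0, 0.9)[1, ], mk(9.0, 0.9)[1, ], hh)
  expect_equal(ps0$fis, 0)
  # ideal geometry, weightless type: FIS = 1
  hb <- defaultInteractionParams()[["HBD:HBA"]]
  lf <- mk(0, 1); lf$type <- "HBD"
  lf$auxx <- -0.96; lf$auxy <- 0; lf$auxz <- 0   # H pointing at acceptor
  ef <- mk(-2.9, 1); ef$type <- "HBA"
  ps1 <- pairScore(lf[1, ], ef[1, ], hb)
  expect_equal(ps1$fis, 1)
})

test_that("aggregation equals the brute-force double loop", {
  hh <- defaultInteractionParams()[["H:H"]]
  set.seed(11)
  for (k in 1:25) {
    lf <- random_features(sample(1:6, 1))
    ef <- random_features(sample(1:6, 1))
    o <- oracle_pair_sums(lf, ef, hh)
    expect_equal(aggregateSum(lf, ef, hh), o$sum, tolerance = 1e-12)
    expect_equal(aggregateMaxSum(lf, ef, hh), o$max_sum, tolerance = 1e-12)
    expect_lte(aggregateMaxSum(lf, ef, hh), aggregateSum(lf, ef, hh) + 1e-12)
  }
  # empty sides
  e0 <- lf[0, ]
  expect_equal(aggregateSum(e0, ef, hh), 0)
  expect_equal(aggregateMaxSum(lf, e0, hh), 0)
  # singleton environment: max-sum equals sum
  ef1 <- random_features(1)
  expect_equal(aggregateMaxSum(lf, ef1, hh), aggregateSum(lf, ef1, hh))
})

test_that("coverage terms match the single-pair closed form and oracle", {
  hb <- defaultInteractionParams()[["HBD:HBA"]]
  # single bare atom at plateau distance from one env HBA
  at <- matrix(c(3.0, 0, 0), 1, 3)
  ef <- random_features(1, "HBA"); ef$x <- 0; ef$y <- 0; ef$z <- 0
  expect_equal(coverageSum(at, ef, hb), 1)
  at2 <- matrix(c(3.55, 0, 0), 1, 3)
  expect_equal(coverageSum(at2, ef, hb),
               1 - gradeFP:::smoothstep((3.55 - 3.2) / 0.6),
               tolerance = 1e-12)
  # beyond support: zero
  expect_equal(coverageSum(matrix(c(9, 0, 0), 1, 3), ef, hb), 0)
  # oracle equivalence on random configurations
  set.seed(12)
  for (k in 1:25) {
    atoms_m <- matrix(runif(3 * sample(1:6, 1), -4, 4), ncol = 3)
    envf <- random_features(sample(1:5, 1), "HBA")
    o <- oracle_coverage(atoms_m, envf, hb)
    expect_equal(coverageSum(atoms_m, envf, hb), o$sum, tolerance = 1e-12)
    expect_equal(coverageMaxSum(atoms_m, envf, hb), o$max_sum,
                 tolerance = 1e-12)
  }
  # empty environment
  expect_equal(coverageMaxSum(at, ef[0, ], hb), 0)
})

test_that("non-complementary atom selection follows the coverage contract", {
  lig <- buildMethanol()
  f <- perceiveFeatures(lig)
  # O carries an HBD: excluded against env HBA; C remains
  nc_hba <- gradeFP:::nonComplementaryAtoms(lig, f, "HBA")
  expect_equal(nrow(nc_hba), 1)
  # against env HBD the O (an HBA parent) is excluded instead
  nc_hbd <- gradeFP:::nonComplementaryAtoms(lig, f, "HBD")
  expect_equal(nrow(nc_hbd), 1)
  # a pure hydrocarbon blocks everything
  pr <- buildPropane()
  fpr <- perceiveFeatures(pr)
  expect_equal(nrow(gradeFP:::nonComplementaryAtoms(pr, fpr, "HBA")), 3)
})

test_that("scores are invariant under joint rigid transformation", {
  cplx <- makeHbondFixture(3.0, 170)
  cfg <- peoe_config()
  v0 <- descriptorValues(assembleDescriptor(cplx, "GRADE", cfg))
  set.seed(99)
  for (k in 1:10) {
    rot <- random_rotation_matrix()
    tr <- rnorm(3, 0, 20)
    v1 <- descriptorValues(assembleDescriptor(
      rigid_transform_complex(cplx, rot, tr), "GRADE", cfg))
    expect_equal(v1, v0, tolerance = 1e-9)
  }
})

test_that("DS/AS bounds and FIS ordering hold across the panel", {
  panel <- makePanel(5)
  P <- defaultInteractionParams()
  for (cplx in panel) {
    ligF <- perceiveFeatures(ligand(cplx))
    env <- extractBindingSite(cplx, 7)
    envS <- gradeFP:::environmentStructure(receptor(cplx), env)
    envF <- perceiveFeatures(envS)
    for (pair in names(P)) {
      ty <- strsplit(pair, ":")[[1]]
      lf <- ligF[ligF$type == ty[1], ]
      ef <- envF[envF$type == ty[2], ]
      if (!nrow(lf) || !nrow(ef)) next
      for (i in seq_len(nrow(lf))) {
        for (j in seq_len(nrow(ef))) {
          ps <- pairScore(lf[i, ], ef[j, ], P[[pair]])
          expect_gte(ps$ds, 0); expect_lte(ps$ds, 1)
          expect_gte(ps$as_, 0); expect_lte(ps$as_, 1)
          expect_gte(ps$fis, -1e-15)
          expect_lte(ps$fis, ps$c + 1e-12)
        }
      }
    }
  }
})
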