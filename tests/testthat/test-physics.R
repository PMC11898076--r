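# Partial charges, electrostatics and the Morse van-der-Waals split.

build_methane <- function() {
  c0 <- c(0, 0, 0)
  hs <- rbind(c(0.63, 0.63, 0.63), c(-0.63, -0.63, 0.63),
              c(-0.63, 0.63, -0.63), c(0.63, -0.63, -0.63))
  molecularStructure(c("C", rep("H", 4)), rbind(c0, hs),
                     data.frame(i = 1, j = 2:5, order = 1),
                     name = "methane")
}

test_that("PEOE charges conserve total charge and molecular symmetry", {
  q <- peoeCharges(build_methane())
  expect_equal(sum(q), 0, tolerance = 1e-6)
  expect_lt(q[1], 0)                       # carbon slightly negative vs H
  expect_equal(sd(q[2:5]), 0, tolerance = 1e-9)

  qa <- peoeCharges(buildAcetate())
  expect_equal(sum(qa), -1, tolerance = 1e-6)

  qb <- peoeCharges(buildBenzene())
  expect_equal(sum(qb), 0, tolerance = 1e-6)
  # symmetry-equivalent ring carbons carry equal charges
  expect_lt(diff(range(qb[1:6])), 1e-9)

  qm <- peoeCharges(buildMethylammonium())
  expect_equal(sum(qm), 1, tolerance = 1e-6)
})

test_that("charge assignment reports its scheme and falls back cleanly", {
  res <- assignPartialCharges(build_methane(), scheme = "peoe")
  expect_equal(res$scheme, "peoe")
  res2 <- assignPartialCharges(build_methane(), scheme = "mmff94")
  expect_true(res2$scheme %in% c("mmff94", "peoe"))
  expect_equal(sum(res2$charges), 0, tolerance = 1e-5)
})

test_that("electrostatic term: closed forms, oracle, bilinearity, symmetry", {
  # single pair: q1*q2/r^x
  lc <- matrix(c(0, 0, 0), 1, 3); ec <- matrix(c(2, 0, 0), 1, 3)
  expect_equal(electrostaticTerm(lc, ec, 0.5, -0.5, 1), -0.125)
  expect_equal(electrostaticTerm(lc, ec, 0.5, -0.5, 2), -0.0625)
  expect_equal(electrostaticTerm(lc, ec, 0, 0.7, 1), 0)
  set.seed(21)
  for (k in 1:20) {
    lc <- matrix(runif(9, -3, 3), 3, 3)
    ec <- matrix(runif(6, 4, 8), 2, 3)
    lq <- rnorm(3); eq <- rnorm(2)
    for (x in 1:2) {
      got <- electrostaticTerm(lc, ec, lq, eq, x)
      expect_equal(got, oracle_electrostatic(lc, ec, lq, eq, x),
                   tolerance = 1e-12)
      # symmetric under exchanging the two atom sets
      expect_equal(got, electrostaticTerm(ec, lc, eq, lq, x),
                   tolerance = 1e-12)
      # doubling every charge quadruples the term
      expect_equal(electrostaticTerm(lc, ec, 2 * lq, 2 * eq, x), 4 * got,
                   tolerance = 1e-12)
    }
  }
  # coincident atoms are an error naming the pair
  expect_error(electrostaticTerm(lc, lc, lq, lq, 1), "coincident")
})

test_that("UFF pair parameters combine geometrically with polar-H scaling", {
  tab <- defaultUFFTable()
  # the published organogenic values
  expect_equal(tab$D_kcal_mol[tab$element == "C"], 0.105)
  expect_equal(tab$x_angstrom[tab$element == "C"], 3.851)
  expect_equal(tab$x_angstrom[tab$element == "H"], 2.886)
  # identical types: geometric mean collapses to the element values
  p <- uffPairParams("C", "C")
  expect_equal(unname(p), c(0.105, 3.851))
  # mixed pair equals the root products of the table entries
  pn <- uffPairParams("C", "N")
  expect_equal(unname(pn["D"]), sqrt(0.105 * tab$D_kcal_mol[tab$element == "N"]))
  expect_equal(unname(pn["x"]), sqrt(3.851 * tab$x_angstrom[tab$element == "N"]))
  # polar hydrogen: x halved before combining
  ph <- uffPairParams("H", "H", polarI = TRUE, polarJ = TRUE)
  expect_equal(unname(ph["x"]), 0.5 * 2.886)
  ph1 <- uffPairParams("H", "O", polarI = TRUE)
  expect_equal(unname(ph1["x"]), sqrt(0.5 * 2.886 * 3.5))
  expect_error(uffPairParams("Xx", "C"), "Xx")
  # every naturally occurring element is covered with positive parameters
  expect_gte(nrow(tab), 103)
  expect_true(all(tab$D_kcal_mol > 0 & tab$x_angstrom > 0))
})

test_that("Morse split: minimum, decay, and brute-force equivalence", {
  tab <- defaultUFFTable()
  two_atoms <- function(r, el = "C") {
    molecularStructure(el, matrix(c(0, 0, 0), 1, 3), name = "probe")
  }
  env_at <- function(r, el = "C") {
    data.frame(element = el, x = r, y = 0, z = 0)
  }
  D <- tab$D_kcal_mol[tab$element == "C"]
  x <- tab$x_angstrom[tab$element == "C"]
  # at r = x the total Morse energy is exactly -D
  v <- morseVdw(two_atoms(), env_at(x), ligPolarH = FALSE,
                envPolarH = FALSE, alpha = 1.1)
  expect_equal(unname(sum(v)), -D, tolerance = 1e-12)
  expect_gte(v["repulsion"], 0); expect_lte(v["attraction"], 0)
  # at 100 A both terms vanish below 1e-10 * D
  vfar <- morseVdw(two_atoms(), env_at(100), FALSE, FALSE, alpha = 1.1)
  expect_lt(max(abs(vfar)), 1e-10 * D)
  # dense sampling: repulsion decreasing, attraction increasing beyond x,
  # total minimal at r = x
  rs <- seq(x - 1, x + 4, by = 0.02)
  vals <- t(vapply(rs, function(r) {
    morseVdw(two_atoms(), env_at(r), FALSE, FALSE, alpha = 1.1)
  }, numeric(2)))
  expect_true(all(diff(vals[, 2]) < 0))
  expect_true(all(diff(vals[, 1]) > 0))
  tot <- rowSums(vals)
  expect_equal(rs[which.min(tot)], x, tolerance = 0.03)
  expect_equal(min(tot), -D, tolerance = 1e-4)
  # random configurations against the naive double loop
  set.seed(31)
  for (k in 1:20) {
    els_l <- sample(c("C", "N", "O", "H"), 4, replace = TRUE)
    els_e <- sample(c("C", "O", "S"), 3, replace = TRUE)
    lig <- molecularStructure(els_l, matrix(runif(12, -3, 3), 4, 3),
                              name = "rand")
    env <- data.frame(element = els_e, x = runif(3, 4, 7),
                      y = runif(3, -2, 2), z = runif(3, -2, 2))
    got <- morseVdw(lig, env, rep(FALSE, 4), rep(FALSE, 3), alpha = 1.1)
    li <- match(els_l, tab$element); ei <- match(els_e, tab$element)
    want <- oracle_morse(as.matrix(lig@atoms[, c("x", "y", "z")]),
                         as.matrix(env[, c("x", "y", "z")]),
                         tab$D_kcal_mol[li], tab$D_kcal_mol[ei],
                         tab$x_angstrom[li], tab$x_angstrom[ei], 1.1)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("physics block is invariant under joint rigid transformation", {
  cplx <- makeHbondFixture()
  cfg <- peoe_config()
  env <- extractBindingSite(cplx, 7)
  es <- gradeFP:::environmentStructure(receptor(cplx), env)
  p0 <- physicsBlock(ligand(cplx), es, cfg)
  set.seed(17)
  for (k in 1:5) {
    moved <- rigid_transform_complex(cplx, random_rotation_matrix(),
                                     rnorm(3, 0, 15))
    env2 <- extractBindingSite(moved, 7)
    es2 <- gradeFP:::environmentStructure(receptor(moved), env2)
    p1 <- physicsBlock(ligand(moved), es2, cfg)
    expect_equal(p1, p0, tolerance = 1e-9)
  }
})
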