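# Synthetic protein-ligand fixtures with known interaction geometry.
# Chemically valid capped fragments are laid out by hand so that exactly
# the declared interaction is exercised at a requested geometry, and
# everything else stays outside kernel support. Fixtures are written as
# standard PDB (receptor) + SDF (ligand) pairs and round-trip through the
# package readers.

## three tetrahedral unit directions around -u (109.47 deg from u)
tetraDirs <- function(u, phase = 0) {
  u <- unitVec(u)
  p1 <- if (abs(u[1]) < 0.9) unitVec(pracmaCross(u, c(1, 0, 0)))
        else unitVec(pracmaCross(u, c(0, 1, 0)))
  p2 <- pracmaCross(u, p1)
  th <- 109.47 * pi / 180
  lapply(0:2, function(k) {
    phi <- phase + k * 2 * pi / 3
    cos(th) * u + sin(th) * (cos(phi) * p1 + sin(phi) * p2)
  })
}

rotZ <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

## ---- ligand builders (canonical frames) ----

#' Benzene with explicit hydrogens (ring in the xy-plane, centroid at
#' \code{center})
#' @param center 3-vector centroid position
#' @param normal unit ring normal (default +z)
#' @return MolecularStructure
#' @export
buildBenzene <- function(center = c(0, 0, 0), normal = c(0, 0, 1)) {
  normal <- unitVec(normal)
  # orthonormal frame with normal as z
  p1 <- if (abs(normal[1]) < 0.9) unitVec(pracmaCross(normal, c(1, 0, 0)))
        else unitVec(pracmaCross(normal, c(0, 1, 0)))
  p2 <- pracmaCross(normal, p1)
  ang <- (0:5) * pi / 3
  ring <- t(vapply(ang, function(a) {
    center + 1.39 * (cos(a) * p1 + sin(a) * p2)
  }, numeric(3)))
  hpos <- t(vapply(ang, function(a) {
    center + 2.47 * (cos(a) * p1 + sin(a) * p2)
  }, numeric(3)))
  coords <- rbind(ring, hpos)
  el <- c(rep("C", 6), rep("H", 6))
  bonds <- data.frame(
    i = c(1:6, 1:6),
    j = c(2:6, 1, 7:12),
    order = c(rep(c(2, 1), 3), rep(1, 6)))
  molecularStructure(el, coords, bonds, name = "benzene")
}

#' Methanol: hydroxyl donor aimed at an acceptor position
#'
#' The oxygen sits at \code{o_pos}; the hydroxyl hydrogen is placed so the
#' D-H...A angle toward \code{acceptor} equals \code{dha} degrees.
#' @param o_pos donor oxygen position
#' @param acceptor acceptor position the O-H is aimed at
#' @param dha target D-H...A angle, degrees
#' @return MolecularStructure
#' @export
buildMethanol <- function(o_pos = c(2.9, 0, 0), acceptor = c(0, 0, 0),
                          dha = 180) {
  h <- solveDonorH(o_pos, acceptor, 0.96, dha)
  hdir <- unitVec(h - o_pos)
  # methyl carbon 108.5 deg from the O-H bond, rotated away in-plane
  u <- unitVec(acceptor - o_pos)
  p <- if (abs(u[3]) < 0.9) unitVec(pracmaCross(u, c(0, 0, 1)))
       else unitVec(pracmaCross(u, c(1, 0, 0)))
  th <- 108.5 * pi / 180
  cdir <- unitVec(cos(th) * hdir + sin(th) * p)
  cpos <- o_pos + 1.43 * cdir
  hs <- tetraDirs(unitVec(o_pos - cpos))
  coords <- rbind(o_pos, h, cpos,
                  cpos + 1.09 * matrix(unlist(hs), 3, byrow = TRUE))
  el <- c("O", "H", "C", "H", "H", "H")
  bonds <- data.frame(i = c(1, 1, 3, 3, 3), j = c(2, 3, 4, 5, 6), order = 1)
  molecularStructure(el, coords, bonds, name = "methanol")
}

## place the donor hydrogen to realize a requested D-H...A angle
solveDonorH <- function(D, A, dist_dh, theta) {
  u <- unitVec(A - D)
  if (abs(theta - 180) < 1e-9) return(D + dist_dh * u)
  p <- if (abs(u[3]) < 0.9) unitVec(pracmaCross(u, c(0, 0, 1)))
       else unitVec(pracmaCross(u, c(1, 0, 0)))
  f <- function(phi) {
    h <- D + dist_dh * (cos(phi) * u + sin(phi) * p)
    vecAngle(D - h, A - h) - theta
  }
  sol <- stats::uniroot(f, c(1e-6, pi - 0.2), tol = 1e-10)
  phi <- sol$root
  D + dist_dh * (cos(phi) * u + sin(phi) * p)
}

#' Methylamine (CH3-NH2): the classic two-donor primary amine
#' @param n_pos nitrogen position
#' @return MolecularStructure
#' @export
buildMethylamine <- function(n_pos = c(0, 0, 0)) {
  cdir <- c(1, 0, 0)
  cpos <- n_pos + 1.47 * cdir
  nh <- tetraDirs(cdir)  # three tetrahedral slots; use two for H
  ch <- tetraDirs(unitVec(n_pos - cpos), phase = pi / 3)
  coords <- rbind(n_pos,
                  n_pos + 1.01 * nh[[1]], n_pos + 1.01 * nh[[2]],
                  cpos,
                  cpos + 1.09 * ch[[1]], cpos + 1.09 * ch[[2]],
                  cpos + 1.09 * ch[[3]])
  el <- c("N", "H", "H", "C", "H", "H", "H")
  bonds <- data.frame(i = c(1, 1, 1, 4, 4, 4), j = c(2, 3, 4, 5, 6, 7),
                      order = 1)
  molecularStructure(el, coords, bonds, name = "methylamine")
}

#' Methylammonium cation (CH3-NH3+)
#' @param n_pos nitrogen position
#' @param c_dir unit direction from N toward the methyl carbon
#' @return MolecularStructure (formal charge +1 on N)
#' @export
buildMethylammonium <- function(n_pos = c(0, 0, 0), c_dir = c(1, 0, 0)) {
  c_dir <- unitVec(c_dir)
  cpos <- n_pos + 1.49 * c_dir
  nh <- tetraDirs(c_dir)
  ch <- tetraDirs(unitVec(n_pos - cpos), phase = pi / 3)
  coords <- rbind(n_pos,
                  n_pos + 1.01 * nh[[1]], n_pos + 1.01 * nh[[2]],
                  n_pos + 1.01 * nh[[3]],
                  cpos,
                  cpos + 1.09 * ch[[1]], cpos + 1.09 * ch[[2]],
                  cpos + 1.09 * ch[[3]])
  el <- c("N", "H", "H", "H", "C", "H", "H", "H")
  bonds <- data.frame(i = c(1, 1, 1, 1, 5, 5, 5),
                      j = c(2, 3, 4, 5, 6, 7, 8), order = 1)
  molecularStructure(el, coords, bonds,
                     formal_charge = c(1L, rep(0L, 7)),
                     name = "methylammonium")
}

#' Acetate anion (CH3-COO-)
#' @return MolecularStructure (formal charge -1 on one oxygen)
#' @export
buildAcetate <- function() {
  coords <- rbind(c(0, 0, 0),        # CH3 carbon
                  c(1.52, 0, 0),     # carboxylate carbon
                  c(2.13, 1.07, 0),  # O
                  c(2.13, -1.07, 0), # O (charged)
                  c(-0.36, 1.02, 0), c(-0.36, -0.51, 0.88),
                  c(-0.36, -0.51, -0.88))
  el <- c("C", "C", "O", "O", "H", "H", "H")
  bonds <- data.frame(i = c(1, 2, 2, 1, 1, 1), j = c(2, 3, 4, 5, 6, 7),
                      order = c(1, 2, 1, 1, 1, 1))
  molecularStructure(el, coords, bonds,
                     formal_charge = c(0L, 0L, 0L, -1L, 0L, 0L, 0L),
                     name = "acetate")
}

#' Propane with the terminal methyl at the origin, chain extending +x
#' @return MolecularStructure
#' @export
buildPropane <- function() {
  c1 <- c(0, 0, 0)
  c2 <- c(1.26, 0.87, 0)
  c3 <- c(2.52, 0, 0)
  h1 <- lapply(tetraDirs(unitVec(c2 - c1)), function(d) c1 + 1.09 * d)
  h3 <- lapply(tetraDirs(unitVec(c2 - c3)), function(d) c3 + 1.09 * d)
  b2 <- unitVec(unitVec(c1 - c2) + unitVec(c3 - c2))
  p2 <- unitVec(pracmaCross(unitVec(c3 - c1), b2))
  h2a <- c2 + 1.09 * unitVec(-b2 + 0.9 * p2)
  h2b <- c2 + 1.09 * unitVec(-b2 - 0.9 * p2)
  coords <- do.call(rbind, c(list(c1, c2, c3), h1, list(h2a, h2b), h3))
  el <- c("C", "C", "C", rep("H", 8))
  bonds <- data.frame(i = c(1, 2, 1, 1, 1, 2, 2, 3, 3, 3),
                      j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11), order = 1)
  molecularStructure(el, coords, bonds, name = "propane")
}

## phenyl ring in the xy-plane with the attachment carbon at ipso_pos and
## the ring extending along +x from it; returns coords/elements/bonds of
## ring carbons (1 = ipso, then around) and the 5 non-ipso hydrogens
phenylRing <- function(ipso_pos) {
  center <- ipso_pos + c(1.39, 0, 0)
  ang <- pi + (0:5) * pi / 3   # atom 1 at the ipso position
  ring <- t(vapply(ang, function(a) {
    center + 1.39 * c(cos(a), sin(a), 0)
  }, numeric(3)))
  hpos <- t(vapply(ang[-1], function(a) {
    center + 2.47 * c(cos(a), sin(a), 0)
  }, numeric(3)))
  list(coords = rbind(ring, hpos),
       el = c(rep("C", 6), rep("H", 5)),
       bonds = data.frame(i = c(1:6, 2:6),
                          j = c(2:6, 1, 7:11),
                          order = c(rep(c(2, 1), 3), rep(1, 5))))
}

#' Bromobenzene with the C-Br axis along -x and Br at \code{br_pos}
#' @param br_pos bromine position
#' @return MolecularStructure
#' @export
buildBromobenzene <- function(br_pos = c(3.3, 0, 0)) {
  ph <- phenylRing(br_pos + c(1.90, 0, 0))
  coords <- rbind(ph$coords, br_pos)
  el <- c(ph$el, "Br")
  bonds <- rbind(ph$bonds,
                 data.frame(i = 1, j = length(el), order = 1))
  molecularStructure(el, coords, bonds, name = "bromobenzene")
}

## ---- receptor fragment builders ----

recStructure <- function(el, coords, names, resid, resno = 1L,
                         chain = "A", name = "receptor", het = FALSE) {
  mol <- molecularStructure(el, coords, bonds = NULL, atom_name = names,
                            residue_id = paste(chain, resid, resno, sep = ":"),
                            is_het = het, name = name)
  perceiveBonds(mol)
}

## serine-like fragment: hydroxyl acceptor at the origin, H pointing away
## from +x (the ligand side), backbone-ish atoms trailing off to -x
buildSerineFragment <- function() {
  coords <- rbind(
    c(0, 0, 0),            # OG
    c(-0.48, 0.826, 0),    # HG
    c(-0.64, -1.26, 0),    # CB
    c(-0.42, -1.81, 0.93), # HB1
    c(-1.10, -1.90, -0.75),# HB2  (spread away)
    c(-2.03, -1.72, 0.46), # CA
    c(-2.03, -1.39, 1.50), # HA
    c(-1.74, -3.12, 0.46), # N
    c(-0.82, -3.53, 0.46), # H (on N)
    c(-2.35, -3.93, 0.46), # H2 (on N)
    c(-3.47, -1.42, 0.46), # C
    c(-3.84, -0.25, 0.46), # O
    c(-4.02, -2.35, 0.46)) # HC (aldehyde-type cap)
  recStructure(c("O", "H", "C", "H", "H", "C", "H", "N", "H", "H",
                 "C", "O", "H"),
               coords,
               c("OG", "HG", "CB", "HB1", "HB2", "CA", "HA", "N", "H",
                 "H2", "C", "O", "HC"),
               "SER", name = "serine-fragment")
}

## leucine-like fragment: one exposed methyl at (-contact, 0, 0), the rest
## of the side chain strictly farther from the ligand
buildLeucineFragment <- function(contact = 4.2) {
  cd1 <- c(-contact, 0, 0)
  cg <- cd1 + c(-1.53, 0, 0)
  cd2 <- cg + 1.53 * c(-0.33, 0.94, 0)
  cb <- cg + 1.53 * c(-0.33, -0.94, 0)
  hset <- function(cpos, back) {
    lapply(tetraDirs(unitVec(back - cpos)), function(d) cpos + 1.09 * d)
  }
  hg <- cg + 1.09 * unitVec(c(0, 0, 1))
  coords <- do.call(rbind, c(list(cd1, cg, cd2, cb, hg),
                             hset(cd1, cg), hset(cd2, cg), hset(cb, cg)))
  el <- c(rep("C", 4), rep("H", 10))
  recStructure(el, coords,
               c("CD1", "CG", "CD2", "CB", "HG", paste0("HD1", 1:3),
                 paste0("HD2", 1:3), paste0("HB", 1:3)),
               "LEU", name = "leucine-fragment")
}

## phenylalanine-like fragment: aromatic ring centroid at the origin in
## the xy-plane, methyl cap trailing off along -x
buildPheFragment <- function() {
  ph <- phenylRing(c(-1.39, 0, 0))   # ring centroid lands at the origin
  cb <- c(-2.89, 0, 0)
  hb <- lapply(tetraDirs(c(1, 0, 0)), function(d) cb + 1.09 * d)
  coords <- rbind(ph$coords, cb, do.call(rbind, hb))
  el <- c(ph$el, "C", "H", "H", "H")
  names_all <- c(paste0("CG", 1:6), paste0("HG", 1:5),
                 "CB", "HB1", "HB2", "HB3")
  recStructure(el, coords, names_all, "PHE", name = "phe-fragment")
}

## N-methylacetamide-like fragment: carbonyl oxygen (acceptor) at origin
buildAmideFragment <- function() {
  o <- c(0, 0, 0)
  c1 <- c(-1.23, 0, 0)                       # carbonyl C
  n <- c1 + 1.33 * c(-0.5, -0.866, 0)        # amide N
  cc <- c1 + 1.50 * c(-0.5, 0.866, 0)        # acetyl methyl
  hn <- n + 1.01 * c(0.5, -0.866, 0)
  cn <- n + 1.45 * c(-1, 0, 0)               # N-methyl
  hcc <- lapply(tetraDirs(unitVec(c1 - cc)), function(d) cc + 1.09 * d)
  hcn <- lapply(tetraDirs(unitVec(n - cn)), function(d) cn + 1.09 * d)
  coords <- do.call(rbind, c(list(o, c1, n, cc, hn, cn), hcc, hcn))
  el <- c("O", "C", "N", "C", "H", "C", rep("H", 6))
  recStructure(el, coords,
               c("O", "C", "N", "CA", "H", "CN", paste0("HA", 1:3),
                 paste0("HN", 1:3)),
               "NMA", name = "amide-fragment")
}

## aspartate-like fragment: carboxylate with both oxygens exposed to +x
buildAspartateFragment <- function() {
  cg <- c(0, 0, 0)
  od1 <- c(0.61, 1.07, 0)
  od2 <- c(0.61, -1.07, 0)
  cb <- c(-1.52, 0, 0)
  hb <- lapply(tetraDirs(c(1, 0, 0)), function(d) cb + 1.09 * d)
  coords <- do.call(rbind, c(list(cg, od1, od2, cb), hb))
  el <- c("C", "O", "O", "C", "H", "H", "H")
  recStructure(el, coords,
               c("CG", "OD1", "OD2", "CB", "HB1", "HB2", "HB3"),
               "ASP", name = "aspartate-fragment")
}

## ---- fixture complexes ----

#' Hydrogen-bond fixture: serine-like acceptor + methanol donor
#'
#' Exactly one ligand HBD lies within kernel range of exactly one
#' environment HBA, at the requested donor-acceptor distance and D-H...A
#' angle.
#'
#' @param distance donor-acceptor heavy-atom distance, Angstrom (1-10)
#' @param angle D-H...A angle, degrees
#' @return ProteinLigandComplex
#' @export
makeHbondFixture <- function(distance = 2.9, angle = 180) {
  if (distance <= 1 || distance >= 10) {
    stop("geometrically infeasible donor-acceptor distance: ", distance)
  }
  if (angle < 90 || angle > 180) {
    stop("geometrically infeasible D-H...A angle: ", angle)
  }
  rec <- buildSerineFragment()
  lig <- buildMethanol(o_pos = c(distance, 0, 0), acceptor = c(0, 0, 0),
                       dha = angle)
  proteinLigandComplex(rec, lig, id = sprintf("hbond_%.2f_%.0f",
                                              distance, angle))
}

#' Hydrophobic-contact fixture: leucine-like fragment + propane
#'
#' A single terminal-methyl pair at the requested contact distance; all
#' other carbon pairs lie outside the hydrophobic kernel support.
#'
#' @param contact C...C contact distance, Angstrom (1-10)
#' @return ProteinLigandComplex
#' @export
makeHydrophobicFixture <- function(contact = 4.2) {
  if (contact <= 1 || contact >= 10) {
    stop("geometrically infeasible contact distance: ", contact)
  }
  rec <- buildLeucineFragment(contact = contact)
  lig <- buildPropane()
  proteinLigandComplex(rec, lig, id = sprintf("hydrophobic_%.2f", contact))
}

#' Aromatic-stacking fixture: phenyl fragment + parallel benzene
#' @param rise centroid-centroid stacking distance (default 3.8 A)
#' @return ProteinLigandComplex
#' @export
makeAromaticStackFixture <- function(rise = 3.8) {
  rec <- buildPheFragment()
  lig <- buildBenzene(center = c(0, 0, rise), normal = c(0, 0, 1))
  proteinLigandComplex(rec, lig, id = sprintf("arstack_%.2f", rise))
}

#' Cation-pi fixture: phenyl fragment + methylammonium on the ring axis
#' @param rise cation-centroid distance (default 4.2 A)
#' @return ProteinLigandComplex
#' @export
makeCationPiFixture <- function(rise = 4.2) {
  rec <- buildPheFragment()
  lig <- buildMethylammonium(n_pos = c(0, 0, rise), c_dir = c(0, 0, 1))
  proteinLigandComplex(rec, lig, id = sprintf("cationpi_%.2f", rise))
}

#' Halogen-bond fixture: amide carbonyl acceptor + bromobenzene
#' @param distance Br...O distance (default 3.3 A)
#' @return ProteinLigandComplex
#' @export
makeHalogenBondFixture <- function(distance = 3.3) {
  rec <- buildAmideFragment()
  lig <- buildBromobenzene(br_pos = c(distance, 0, 0))
  proteinLigandComplex(rec, lig, id = sprintf("xbond_%.2f", distance))
}

#' Salt-bridge-geometry control: carboxylate + methylammonium
#'
#' Places a cationic amine against an anionic carboxylate with the N-H
#' vectors rotated off every acceptor. The descriptor has no PI/NI
#' interaction slot, so all interaction entries stay ~0 while the
#' electrostatic terms go strongly negative.
#'
#' @param distance N...carboxylate-carbon distance (default 3.5 A)
#' @return ProteinLigandComplex
#' @export
makeSaltBridgeControl <- function(distance = 3.5) {
  rec <- buildAspartateFragment()
  lig <- buildMethylammonium(n_pos = c(distance, 0, 0), c_dir = c(1, 0, 0))
  proteinLigandComplex(rec, lig, id = sprintf("saltbridge_%.2f", distance))
}

#' Null complex: methanol 50 A away from the serine fragment
#' @return ProteinLigandComplex (empty binding site at any sane cutoff)
#' @export
makeNullComplex <- function() {
  rec <- buildSerineFragment()
  lig <- buildMethanol(o_pos = c(50, 0, 0), acceptor = c(47, 0, 0))
  proteinLigandComplex(rec, lig, id = "null_complex")
}

jitterStructure <- function(mol, sd = 0.05) {
  xyz <- coordMat(mol)
  setCoords(mol, xyz + matrix(stats::rnorm(length(xyz), 0, sd),
                              ncol = 3))
}

#' Seeded panel of synthetic fixtures
#'
#' Seven complexes (H-bond, hydrophobic contact, aromatic stack,
#' cation-pi, halogen bond, salt-bridge control, far-apart null), each
#' with Gaussian coordinate jitter (sigma 0.05 A) that exercises score
#' continuity without leaving kernel plateaus. Deterministic for a fixed
#' seed.
#'
#' @param seed integer RNG seed
#' @param jitter jitter sigma in Angstrom (0 disables)
#' @return named list of ProteinLigandComplex objects
#' @export
makePanel <- function(seed = 1L, jitter = 0.05) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  panel <- list(
    hbond = makeHbondFixture(2.9, 180),
    hydrophobic = makeHydrophobicFixture(4.2),
    aromatic_stack = makeAromaticStackFixture(3.8),
    cation_pi = makeCationPiFixture(4.2),
    halogen_bond = makeHalogenBondFixture(3.3),
    salt_bridge_control = makeSaltBridgeControl(3.5),
    null_complex = makeNullComplex())
  if (jitter > 0) {
    panel <- lapply(panel, function(cplx) {
      new("ProteinLigandComplex",
          receptor = jitterStructure(receptor(cplx), jitter),
          ligand = jitterStructure(ligand(cplx), jitter),
          id = complexId(cplx))
    })
  }
  panel
}

## nonzero pose-dependent GRADE slots each panel member is built to show
## (physics terms are always live when the site is nonempty)
panelExpectedSlots <- function() {
  list(hbond = "HBD <-> HBA",
       hydrophobic = "H <-> H",
       aromatic_stack = "AR <-> AR",
       cation_pi = "PI <-> AR",
       halogen_bond = "XBD <-> XBA",
       salt_bridge_control = character(),
       null_complex = character())
}

#' Write the fixture panel to disk as PDB + SDF pairs with a manifest
#'
#' @param dir output directory (created if needed)
#' @param seed panel seed
#' @param jitter jitter sigma
#' @return path of the manifest CSV (columns id, receptor_path,
#'   ligand_path)
#' @export
writeFixturePanel <- function(dir, seed = 1L, jitter = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- makePanel(seed, jitter)
  rows <- lapply(names(panel), function(nm) {
    rp <- file.path(dir, paste0(nm, "_receptor.pdb"))
    lp <- file.path(dir, paste0(nm, "_ligand.sdf"))
    writeReceptorPDB(receptor(panel[[nm]]), rp)
    writeLigandSDF(ligand(panel[[nm]]), lp)
    data.frame(id = nm, receptor_path = rp, ligand_path = lp,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  mpath
}
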