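# Physics-based descriptor terms: unscaled Coulomb electrostatics between
# ligand and binding-site atoms, and a Morse-potential van der Waals split
# into attractive and repulsive parts with Universal Force Field (UFF)
# per-element well depths D (kcal/mol) and equilibrium distances x (A).
#
# Electrostatics are deliberately left in raw charge^2/A^x units (no
# permittivity scaling): downstream models weight descriptor elements
# anyway, so only relative magnitudes matter.
#
# Morse split per atom pair at distance r:
#   E_rep  =  D_IJ * exp(-2*alpha*(r - x_IJ))   >= 0
#   E_attr = -2*D_IJ * exp(-alpha*(r - x_IJ))   <= 0
# so the total has its minimum -D_IJ at r = x_IJ. Combining rules are
# geometric means, D_IJ = sqrt(D_I*D_J), x_IJ = sqrt(x_I*x_J), with x
# pre-multiplied by 0.5 for polar hydrogens (H bonded to N/O/S), which UFF
# itself does not special-case.

#' Bundled UFF van-der-Waals parameter table
#'
#' Per-element well depth (kcal/mol) and equilibrium distance (Angstrom)
#' covering all naturally occurring elements. Within UFF these nonbond
#' parameters depend on the element only, not on the hybridization-level
#' atom type, so an element-keyed table is exact. Override via
#' \code{gradeConfig(uffTable=)}.
#'
#' @return data.frame with columns element, D_kcal_mol, x_angstrom
#' @export
defaultUFFTable <- function() {
  path <- system.file("extdata", "uff_params.csv", package = "gradeFP")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Combined UFF pair parameters
#'
#' @param elemI,elemJ element symbols
#' @param polarI,polarJ logical: is the atom a polar hydrogen?
#' @param table UFF table (default bundled)
#' @return c(D, x): pair well depth (kcal/mol) and equilibrium distance (A)
#' @export
uffPairParams <- function(elemI, elemJ, polarI = FALSE, polarJ = FALSE,
                          table = defaultUFFTable()) {
  ri <- match(elemI, table$element)
  rj <- match(elemJ, table$element)
  if (is.na(ri)) stop("no UFF parameters for element: ", elemI)
  if (is.na(rj)) stop("no UFF parameters for element: ", elemJ)
  xi <- table$x_angstrom[ri] * (if (polarI) 0.5 else 1)
  xj <- table$x_angstrom[rj] * (if (polarJ) 0.5 else 1)
  c(D = sqrt(table$D_kcal_mol[ri] * table$D_kcal_mol[rj]),
    x = sqrt(xi * xj))
}

#' Intermolecular electrostatic term
#'
#' Sum over all ligand/environment atom pairs of q_i*q_j / r_ij^x with
#' exponent 1 (potential) or 2 (sum of pairwise force magnitudes).
#'
#' @param ligCoords,envCoords n x 3 / m x 3 coordinate matrices, Angstrom
#' @param ligQ,envQ partial charge vectors (elementary charges)
#' @param exponent 1 or 2
#' @return unscaled sum, charge^2/A^exponent
#' @export
electrostaticTerm <- function(ligCoords, envCoords, ligQ, envQ,
                              exponent = 1) {
  stopifnot(exponent %in% c(1, 2))
  n <- nrow(ligCoords); m <- nrow(envCoords)
  if (!n || !m) return(0)
  d <- crossDist(ligCoords, envCoords)
  if (any(d < 1e-6)) {
    bad <- which(d < 1e-6, arr.ind = TRUE)[1, ]
    stop(sprintf("coincident ligand atom %d and environment atom %d (r = 0)",
                 bad[1], bad[2]))
  }
  sum(outer(ligQ, envQ) / d^exponent)
}

#' Morse van-der-Waals attraction/repulsion between ligand and environment
#'
#' @param lig MolecularStructure (full receptor frame not needed)
#' @param envAtoms environment atom data.frame (element, x, y, z columns)
#' @param ligPolarH,envPolarH logical vectors marking polar hydrogens
#' @param alpha Morse well-width factor (default 1.1)
#' @param table UFF parameter table
#' @return c(attraction, repulsion) in kcal/mol-derived units
#'   (attraction <= 0, repulsion >= 0)
#' @export
morseVdw <- function(lig, envAtoms, ligPolarH = NULL, envPolarH = NULL,
                     alpha = 1.1, table = defaultUFFTable()) {
  stopifnot(alpha > 0)
  la <- lig@atoms
  n <- nrow(la); m <- nrow(envAtoms)
  if (!n || !m) return(c(attraction = 0, repulsion = 0))
  if (is.null(ligPolarH)) ligPolarH <- isPolarHydrogen(lig)
  if (is.null(envPolarH)) envPolarH <- rep(FALSE, m)
  ridx <- match(la$element, table$element)
  cidx <- match(envAtoms$element, table$element)
  if (anyNA(ridx)) stop("no UFF parameters for element: ",
                        paste(unique(la$element[is.na(ridx)]), collapse = ", "))
  if (anyNA(cidx)) stop("no UFF parameters for element: ",
                        paste(unique(envAtoms$element[is.na(cidx)]), collapse = ", "))
  Di <- table$D_kcal_mol[ridx]; Dj <- table$D_kcal_mol[cidx]
  xi <- table$x_angstrom[ridx] * ifelse(ligPolarH, 0.5, 1)
  xj <- table$x_angstrom[cidx] * ifelse(envPolarH, 0.5, 1)
  D <- sqrt(outer(Di, Dj))
  X <- sqrt(outer(xi, xj))
  r <- crossDist(as.matrix(la[, c("x", "y", "z")]),
                 as.matrix(envAtoms[, c("x", "y", "z")]))
  if (any(r < 1e-6)) {
    bad <- which(r < 1e-6, arr.ind = TRUE)[1, ]
    stop(sprintf("coincident ligand atom %d and environment atom %d (r = 0)",
                 bad[1], bad[2]))
  }
  rep_ <- sum(D * exp(-2 * alpha * (r - X)))
  attr_ <- sum(-2 * D * exp(-alpha * (r - X)))
  c(attraction = attr_, repulsion = rep_)
}

#' All four physics-based descriptor terms for a complex
#'
#' @param lig ligand MolecularStructure
#' @param envStruct environment MolecularStructure (binding-site subset)
#' @param cfg GradeConfig
#' @return named numeric: electrostatic potential, sum of pairwise
#'   electrostatic forces, VdW attraction, VdW repulsion
#' @export
physicsBlock <- function(lig, envStruct, cfg = gradeConfig()) {
  lq <- assignPartialCharges(lig, cfg$charge_scheme)$charges
  env_atoms <- envStruct@atoms
  if (!nrow(env_atoms)) {
    return(c(`electrostatic potential` = 0,
             `sum of pairwise electrostatic forces` = 0,
             `VdW attraction` = 0, `VdW repulsion` = 0))
  }
  eq <- assignPartialCharges(envStruct, cfg$charge_scheme)$charges
  lc <- coordMat(lig)
  ec <- coordMat(envStruct)
  vdw <- morseVdw(lig, env_atoms,
                  ligPolarH = isPolarHydrogen(lig),
                  envPolarH = isPolarHydrogen(envStruct),
                  alpha = cfg$alpha, table = cfg$uff_table)
  c(`electrostatic potential` = electrostaticTerm(lc, ec, lq, eq, 1),
    `sum of pairwise electrostatic forces` = electrostaticTerm(lc, ec, lq, eq, 2),
    `VdW attraction` = unname(vdw["attraction"]),
    `VdW repulsion` = unname(vdw["repulsion"]))
}
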