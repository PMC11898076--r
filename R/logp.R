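# Atomic-contribution lipophilicity. The package ships a compact
# rule-keyed increment table (inst/extdata/logp_increments.csv); the sum of
# per-heavy-atom increments is the predicted logP, and the increments
# double as hydrophobic feature weights. The table is swappable via
# gradeConfig(logp_table=): any atomic-contribution scheme exposing
# per-atom increments fits the same contract; the 0.15 placement threshold
# and weight semantics stay fixed.

defaultLogPTable <- function() {
  path <- system.file("extdata", "logp_increments.csv", package = "gradeFP")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$increment, tab$class)
}

## classify each heavy atom into an increment class; H atoms -> NA
logPClass <- function(mol) {
  a <- mol@atoms
  adj <- adjacencyList(mol)
  st <- assignSybylTypes(mol)
  hyb <- hybridization(mol)
  omap <- bondOrderMap(mol)
  arom <- unique(unlist(aromaticRings(mol)))
  isH <- a$element == "H"
  vapply(seq_len(nrow(a)), function(i) {
    el <- a$element[i]
    if (el == "H") return(NA_character_)
    nb <- adj[[i]]
    nH <- sum(isH[nb])
    heavy <- nb[!isH[nb]]
    het_nb <- any(a$element[heavy] %in% c("N", "O", "S", "P"))
    if (el == "C") {
      if (i %in% arom) return("C.ar")
      if (hyb[i] == 1L) return("C.1")
      if (hyb[i] == 2L) {
        carbonyl <- any(vapply(nb, function(q) {
          a$element[q] %in% c("O", "S") && getOrder(omap, i, q) >= 2
        }, logical(1)))
        return(if (carbonyl) "C.2.carbonyl" else "C.2.plain")
      }
      if (het_nb) return("C.3.het")
      return(switch(as.character(min(nH, 3L)),
                    "3" = "C.3.h3", "2" = "C.3.h2", "1" = "C.3.h1",
                    "0" = "C.3.h0"))
    }
    if (el == "N") {
      if (a$formal_charge[i] > 0) return("N.plus")
      return(switch(st[i], N.am = "N.am", N.ar = "N.ar", N.1 = "N.1",
                    N.pl3 = "N.pl3", N.2 = "N.2", N.4 = "N.plus",
                    "N.amine"))
    }
    if (el == "O") {
      if (st[i] == "O.co2") return("O.co2")
      if (st[i] == "O.2") return("O.2")
      return(if (nH > 0) "O.3.hydroxyl" else "O.3.ether")
    }
    if (el == "S") {
      if (nH > 0) return("S.thiol")
      return(if (st[i] == "S.2") "S.2" else "S.3")
    }
    if (el == "P") return("P")
    if (el %in% c("F", "Cl", "Br", "I")) return(el)
    "other"
  }, character(1))
}

#' Per-atom logP increments
#'
#' @param mol MolecularStructure
#' @param table named numeric increment table (default: bundled table)
#' @return numeric vector over all atoms; hydrogens contribute 0 (their
#'   lipophilicity is folded into the heavy-atom classes)
#' @export
atomLogPIncrements <- function(mol, table = defaultLogPTable()) {
  cls <- logPClass(mol)
  inc <- unname(table[cls])
  inc[is.na(inc)] <- 0
  inc
}
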