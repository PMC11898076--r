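# Topological polar surface area from fragment contributions over N and O
# environments (the classic N/O-only definition; benzene and pure
# hydrocarbons score 0). Contributions are per polar atom, selected by
# element, aromaticity, bond pattern, H count and charge.

.TPSA_CONTRIB <- list(
  # nitrogen, neutral
  N_3single_0H   = 3.24,
  N_3single_1H   = 12.03,
  N_3single_2H   = 26.02,
  N_double_0H    = 12.36,
  N_double_1H    = 23.85,
  N_triple       = 23.79,
  N_nitro        = 11.68,   # two double bonds
  N_ar_0H        = 12.89,
  N_ar_1H        = 15.79,
  # nitrogen, positively charged
  Np_4single     = 0.00,
  Np_1H          = 4.44,
  Np_2H          = 16.61,
  Np_3H          = 27.64,
  Np_ar_0H       = 4.10,
  Np_ar_1H       = 14.14,
  # oxygen
  O_2single      = 9.23,
  O_1H           = 20.23,
  O_double       = 17.07,
  O_minus        = 23.06,
  O_ar           = 13.14)

#' Topological polar surface area (N/O fragment contributions)
#'
#' @param mol MolecularStructure with explicit hydrogens
#' @return TPSA in square Angstrom
#' @export
computeTPSA <- function(mol) {
  a <- mol@atoms
  adj <- adjacencyList(mol)
  omap <- bondOrderMap(mol)
  arom <- unique(unlist(aromaticRings(mol)))
  isH <- a$element == "H"
  total <- 0
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    if (!(el %in% c("N", "O"))) next
    nb <- adj[[i]]
    nH <- sum(isH[nb])
    ords <- vapply(nb, function(q) getOrder(omap, i, q), numeric(1))
    ndouble <- sum(ords == 2)
    ntriple <- sum(ords == 3)
    aromatic <- i %in% arom
    chg <- a$formal_charge[i]
    key <- if (el == "O") {
      if (chg < 0) "O_minus"
      else if (aromatic) "O_ar"
      else if (nH >= 1) "O_1H"
      else if (ndouble >= 1) "O_double"
      else "O_2single"
    } else {
      if (chg > 0) {
        if (aromatic) {
          if (nH >= 1) "Np_ar_1H" else "Np_ar_0H"
        } else if (nH >= 3) "Np_3H"
        else if (nH == 2) "Np_2H"
        else if (nH == 1) "Np_1H"
        else "Np_4single"
      } else if (aromatic) {
        if (nH >= 1) "N_ar_1H" else "N_ar_0H"
      } else if (ntriple >= 1) "N_triple"
      else if (ndouble >= 2) "N_nitro"
      else if (ndouble == 1) {
        if (nH >= 1) "N_double_1H" else "N_double_0H"
      } else {
        if (nH >= 2) "N_3single_2H"
        else if (nH == 1) "N_3single_1H"
        else "N_3single_0H"
      }
    }
    total <- total + .TPSA_CONTRIB[[key]]
  }
  total
}
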