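# Binding-site environment extraction: whole-residue selection around the
# ligand pose. The cutoff applies between heavy atoms only; a residue is
# included when any of its heavy atoms is within the cutoff of any ligand
# heavy atom, and then contributes all of its atoms (hydrogens included).

#' Extract the binding-site environment around the ligand pose
#'
#' @param cplx ProteinLigandComplex
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 7.0)
#' @param includeHet include waters/ions/cofactors (default TRUE)
#' @return BindingSiteEnvironment
#' @export
extractBindingSite <- function(cplx, cutoff = 7.0, includeHet = TRUE) {
  stopifnot(cutoff > 0)
  rec <- receptor(cplx)
  lig <- ligand(cplx)
  ra <- rec@atoms
  if (!nrow(ra)) {
    return(new("BindingSiteEnvironment",
               atoms = cbind(ra, data.frame(receptor_index = integer())),
               sourceResidues = character(), cutoffUsed = cutoff))
  }
  la <- lig@atoms
  lig_heavy <- which(la$element != "H")
  rec_heavy <- which(ra$element != "H")
  sel_res <- character()
  if (length(lig_heavy) && length(rec_heavy)) {
    d <- crossDist(as.matrix(ra[rec_heavy, c("x", "y", "z")]),
                   as.matrix(la[lig_heavy, c("x", "y", "z")]))
    near <- rec_heavy[apply(d <= cutoff, 1, any)]
    sel_res <- unique(ra$residue_id[near])
  }
  if (!includeHet) {
    het_res <- unique(ra$residue_id[ra$is_het])
    sel_res <- setdiff(sel_res, het_res)
  }
  rows <- which(ra$residue_id %in% sel_res)
  out <- ra[rows, , drop = FALSE]
  out$receptor_index <- rows
  rownames(out) <- NULL
  new("BindingSiteEnvironment", atoms = out,
      sourceResidues = sel_res, cutoffUsed = cutoff)
}

## Restrict a receptor MolecularStructure to the environment atoms,
## keeping bonds among them. Used to run feature perception on the site.
environmentStructure <- function(rec, env) {
  idx <- env@atoms$receptor_index
  sub <- rec@atoms[idx, , drop = FALSE]
  rownames(sub) <- NULL
  remap <- integer(nrow(rec@atoms))
  remap[idx] <- seq_along(idx)
  b <- rec@bonds
  keep <- b$i %in% idx & b$j %in% idx
  nb <- data.frame(i = remap[b$i[keep]], j = remap[b$j[keep]],
                   order = b$order[keep])
  new("MolecularStructure", atoms = sub, bonds = nb,
      name = paste0(rec@name, ":site"))
}
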