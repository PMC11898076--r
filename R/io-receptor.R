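# Receptor structure input/output (PDB, mmCIF) through bio3d, with altLoc
# resolution, element deduction from atom names where the element column is
# blank, and distance-based bond perception.

#' Read a receptor structure from PDB or mmCIF
#'
#' Residue tags are populated as "chain:resid:resno[insert]". For alternate
#' locations the highest-occupancy copy is kept (ties: first listed).
#' Waters and other HETATM records are retained but flagged via the
#' \code{is_het} atom column. Covalent bonds are perceived from distances
#' (see \code{\link{perceiveBonds}}).
#'
#' @param path file path
#' @param format "PDB" or "mmCIF"; default guessed from the extension
#' @param protonate logical; if TRUE a rule-based pass adds missing polar
#'   hydrogens on O/N/S donors (default FALSE: input hydrogens are trusted)
#' @return MolecularStructure
#' @export
readReceptor <- function(path, format = c("auto", "PDB", "mmCIF"),
                         protonate = FALSE) {
  format <- match.arg(toupper(format[1]), c("AUTO", "PDB", "MMCIF"))
  if (!file.exists(path)) stop("receptor file does not exist: ", path)
  if (format == "AUTO") {
    ext <- toupper(tools::file_ext(path))
    format <- if (ext %in% c("CIF", "MMCIF")) "MMCIF" else "PDB"
  }
  obj <- if (format == "PDB") {
    tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
             error = function(e) stop("PDB parse error in ", path, ": ",
                                      conditionMessage(e)))
  } else {
    tryCatch(suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
             error = function(e) stop("mmCIF parse error in ", path, ": ",
                                      conditionMessage(e)))
  }
  at <- obj$atom
  if (!nrow(at)) stop("no atoms in receptor file ", path)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("missing coordinates in receptor file ", path)
  }
  ## altLoc resolution: keep highest occupancy per (residue, atom name)
  alt <- at$alt
  if (is.null(alt)) alt <- rep(NA_character_, nrow(at))
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  keep <- rep(TRUE, nrow(at))
  has_alt <- !is.na(alt) & alt != ""
  for (k in unique(key[has_alt])) {
    rows <- which(key == k)
    if (length(rows) > 1) {
      best <- rows[which.max(occ[rows])]   # which.max: first on ties
      keep[setdiff(rows, best)] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]
  el <- at$elesy
  if (is.null(el)) el <- rep("", nrow(at))
  el[is.na(el)] <- ""
  el <- normalizeElement(el)
  need <- !isValidElement(el)
  if (any(need)) el[need] <- elementFromAtomName(at$elety[need])
  bad <- !isValidElement(el)
  if (any(bad)) {
    stop("cannot deduce element for receptor atom(s): ",
         paste(sprintf("%s/%s %s%s", at$resid[bad], at$elety[bad],
                       at$chain[bad], at$resno[bad]), collapse = ", "))
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  resid_tag <- paste(at$chain, at$resid, paste0(at$resno, ins), sep = ":")
  is_het <- at$type == "HETATM" | at$resid %in% c("HOH", "WAT", "DOD")
  mol <- molecularStructure(el, as.matrix(at[, c("x", "y", "z")]),
                            bonds = NULL, atom_name = at$elety,
                            residue_id = resid_tag, is_het = is_het,
                            name = basename(path))
  mol <- perceiveBonds(mol)
  if (protonate) mol <- addPolarHydrogens(mol)
  mol
}

#' Add missing polar hydrogens by simple valence rules
#'
#' A deliberately small protonation estimate: hydroxyl-type oxygens (one
#' single-bonded heavy neighbor, no H) receive one H; sp3 nitrogens are
#' filled to three substituents. Hydrogens are placed 1.0 A from the heavy
#' atom along the direction opposing the mean of existing bond vectors.
#' Structures with complete hydrogens pass through unchanged.
#'
#' @param mol MolecularStructure with bonds
#' @return MolecularStructure with added hydrogens (bond table extended)
#' @export
addPolarHydrogens <- function(mol) {
  a <- mol@atoms
  adj <- adjacencyList(mol)
  omap <- bondOrderMap(mol)
  xyz <- coordMat(mol)
  st <- assignSybylTypes(mol)
  add_pos <- list(); add_parent <- integer()
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    if (!(el %in% c("N", "O", "S"))) next
    nH <- sum(a$element[adj[[i]]] == "H")
    want <- 0L
    if (el %in% c("O", "S") && st[i] %in% c("O.3", "S.3") &&
        length(adj[[i]]) - nH == 1 && nH == 0) {
      want <- 1L
    } else if (el == "N" && st[i] %in% c("N.3", "N.am")) {
      want <- max(0L, 3L - length(adj[[i]]))
    }
    if (want == 0L) next
    nb <- adj[[i]]
    dirsum <- if (length(nb)) {
      colSums(matrix(xyz[nb, , drop = FALSE], ncol = 3)) - length(nb) * xyz[i, ]
    } else c(0, 0, 1)
    base_dir <- if (vecNorm(dirsum) < 1e-8) c(0, 0, 1) else -unitVec(dirsum)
    for (h in seq_len(want)) {
      # spread multiple H around the base direction
      perp <- if (abs(base_dir[1]) < 0.9) unitVec(pracmaCross(base_dir, c(1, 0, 0)))
              else unitVec(pracmaCross(base_dir, c(0, 1, 0)))
      ang <- (h - 1) * 2 * pi / max(1, want)
      dirh <- unitVec(base_dir + 0.35 * (cos(ang) * perp +
               sin(ang) * pracmaCross(base_dir, perp)))
      add_pos[[length(add_pos) + 1L]] <- xyz[i, ] + 1.0 * dirh
      add_parent <- c(add_parent, i)
    }
  }
  if (!length(add_pos)) return(mol)
  n0 <- nrow(a)
  newa <- data.frame(element = "H",
                     x = vapply(add_pos, `[`, numeric(1), 1),
                     y = vapply(add_pos, `[`, numeric(1), 2),
                     z = vapply(add_pos, `[`, numeric(1), 3),
                     formal_charge = 0L,
                     atom_name = paste0("H", n0 + seq_along(add_pos)),
                     residue_id = a$residue_id[add_parent],
                     is_het = a$is_het[add_parent],
                     stringsAsFactors = FALSE)
  mol@atoms <- rbind(a, newa)
  mol@bonds <- rbind(mol@bonds,
                     data.frame(i = add_parent,
                                j = n0 + seq_along(add_pos), order = 1))
  mol
}

## cross product (avoid a pracma dependency for one primitive)
pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Write a receptor structure as PDB (through bio3d)
#'
#' @param mol MolecularStructure with residue tags
#' @param path output path
#' @return invisibly, the path
#' @export
writeReceptorPDB <- function(mol, path) {
  a <- mol@atoms
  parts <- strsplit(a$residue_id, ":", fixed = TRUE)
  chain <- vapply(parts, function(p) if (length(p) >= 1 && nzchar(p[1])) p[1] else "A",
                  character(1))
  resid <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "UNK",
                  character(1))
  resno <- vapply(parts, function(p) {
    if (length(p) >= 3) as.integer(sub("[A-Za-z]+$", "", p[3])) else 1L
  }, integer(1))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coordMat(mol))),
                   type = ifelse(a$is_het, "HETATM", "ATOM"),
                   resno = resno, resid = resid, chain = chain,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}
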