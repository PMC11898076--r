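# Ligand structure input/output. SDF parsing is delegated to ChemmineR;
# formal charges are recovered from the raw "M  CHG" property lines, which
# ChemmineR's atom block does not carry. MOL2 goes through bio3d.

#' Read a ligand pose from SDF or MOL2
#'
#' Requires 3-D coordinates and explicit bonds; explicit hydrogens are
#' retained, bond orders (aromatic stored as 1.5) and atom order are
#' preserved from the file.
#'
#' @param path file path
#' @param format "SDF" or "MOL2"; default guessed from the file extension
#' @param name structure name; defaults to the molecule title in the file
#' @return MolecularStructure
#' @export
readLigand <- function(path, format = c("auto", "SDF", "MOL2"), name = NULL) {
  format <- match.arg(toupper(format[1]), c("AUTO", "SDF", "MOL2"))
  if (!file.exists(path)) stop("ligand file does not exist: ", path)
  if (format == "AUTO") {
    ext <- toupper(tools::file_ext(path))
    format <- if (ext %in% c("MOL2", "ML2")) "MOL2" else "SDF"
  }
  if (format == "SDF") readLigandSDF(path, name) else readLigandMOL2(path, name)
}

readLigandSDF <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("SDF parse error in ", path, ": empty file")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(natoms) || natoms < 1) {
    stop("SDF parse error in ", path,
         ": no atoms in counts line (record 4)")
  }
  sdf <- tryCatch(ChemmineR::read.SDFset(path),
                  error = function(e) stop("SDF parse error in ", path, ": ",
                                           conditionMessage(e)))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- normalizeElement(sub("_.*$", "", rownames(ab)))
  coords <- ab[, 1:3, drop = FALSE]
  if (grepl("2D", lines[2], fixed = TRUE)) {
    stop("ligand in ", path, " carries 2-D-only coordinates (dimension ",
         "flag '2D'); a 3-D pose is required")
  }
  if (nrow(coords) >= 2 && all(coords[, 3] == 0) && all(coords[, 2] == 0)) {
    stop("ligand in ", path, " has degenerate (non-3-D) coordinates")
  }
  order <- as.numeric(bb[, 3])
  order[order == 4] <- 1.5
  bonds_df <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                         order = order)
  fc <- integer(length(elements))
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    npairs <- f[1]
    for (p in seq_len(npairs)) {
      fc[f[2 * p]] <- f[2 * p + 1]
    }
  }
  if (is.null(name)) {
    name <- trimws(lines[1])
    if (!nzchar(name)) name <- basename(path)
  }
  molecularStructure(elements, coords, bonds_df, formal_charge = fc,
                     name = name)
}

readLigandMOL2 <- function(path, name = NULL) {
  m2 <- tryCatch(bio3d::read.mol2(path),
                 error = function(e) stop("MOL2 parse error in ", path, ": ",
                                          conditionMessage(e)))
  at <- m2$atom
  if (is.null(at) || !nrow(at)) stop("MOL2 parse error in ", path,
                                     ": no atoms")
  elements <- normalizeElement(sub("\\..*$", "", at$elety))
  bad <- !isValidElement(elements)
  if (any(bad)) {
    # fall back to the atom-name column
    elements[bad] <- elementFromAtomName(at$elena[bad])
  }
  bd <- m2$bond
  order <- rep(1, NROW(bd))
  if (NROW(bd)) {
    ty <- tolower(as.character(bd$type))
    order[ty == "2"] <- 2
    order[ty == "3"] <- 3
    order[ty == "ar"] <- 1.5
  }
  bonds_df <- if (NROW(bd)) {
    data.frame(i = as.integer(bd$origin), j = as.integer(bd$target),
               order = order)
  } else NULL
  if (is.null(name)) name <- basename(path)
  molecularStructure(elements, as.matrix(at[, c("x", "y", "z")]), bonds_df,
                     atom_name = at$elena, name = name)
}

#' Write a ligand structure as an SDF (V2000) file
#'
#' In-package writer: emits coordinates at 0.0001 A precision, bond orders
#' (1.5 written as aromatic type 4) and an \code{M  CHG} block for nonzero
#' formal charges.
#'
#' @param mol MolecularStructure
#' @param path output path
#' @return invisibly, the path
#' @export
writeLigandSDF <- function(mol, path) {
  a <- mol@atoms
  b <- mol@bonds
  lines <- c(mol@name, "  gradeFP          3D", "")
  lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                            nrow(a), nrow(b)))
  for (i in seq_len(nrow(a))) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              a$x[i], a$y[i], a$z[i], a$element[i]))
  }
  for (k in seq_len(nrow(b))) {
    o <- b$order[k]
    ocode <- if (o == 1.5) 4L else as.integer(o)
    lines <- c(lines, sprintf("%3d%3d%3d  0", b$i[k], b$j[k], ocode))
  }
  chg <- which(a$formal_charge != 0)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste(sprintf("%4d%4d", grp,
                                             a$formal_charge[grp]),
                                     collapse = "")))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ligand structure as MOL2 (through bio3d)
#'
#' Sybyl atom types are assigned with \code{\link{assignSybylTypes}} for
#' N/O/S atoms; other elements get their plain element symbol.
#'
#' @param mol MolecularStructure
#' @param path output path
#' @return invisibly, the path
#' @export
writeLigandMOL2 <- function(mol, path) {
  a <- mol@atoms
  b <- mol@bonds
  st <- assignSybylTypes(mol)
  hyb <- hybridization(mol)
  elety <- ifelse(st != "OTHER", st,
                  ifelse(a$element %in% c("C", "P"),
                         paste0(a$element, ".", hyb), a$element))
  arom <- aromaticRings(mol)
  arom_atoms <- unique(unlist(arom))
  elety[a$element == "C" & seq_len(nrow(a)) %in% arom_atoms] <- "C.ar"
  ty <- as.character(b$order)
  ty[b$order == 1.5] <- "ar"
  mol2 <- list(atom = data.frame(eleno = seq_len(nrow(a)),
                                 elena = a$atom_name,
                                 x = a$x, y = a$y, z = a$z,
                                 elety = elety,
                                 resno = 1L, resid = "LIG1",
                                 charge = as.numeric(a$formal_charge),
                                 stringsAsFactors = FALSE),
               bond = data.frame(id = seq_len(nrow(b)),
                                 origin = b$i, target = b$j, type = ty,
                                 stringsAsFactors = FALSE),
               info = c(num_atoms = nrow(a), num_bonds = nrow(b),
                        num_subst = 1, num_feat = 0, num_sets = 0),
               name = mol@name)
  class(mol2) <- c("mol2")
  bio3d::write.mol2(mol2, file = path)
  invisible(path)
}
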