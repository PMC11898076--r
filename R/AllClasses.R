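#' @import methods
NULL

#' MolecularStructure: the shared substrate for ligand and receptor
#'
#' Holds explicit atoms (element, Cartesian coordinates in Angstrom, formal
#' charge, optional residue tag) and a bond table with bond orders
#' (1, 2, 3; 1.5 marks aromatic bonds as read from SDF type-4 records).
#' Atom indices in the bond table are 1-based row numbers of the atom table.
#'
#' @slot atoms data.frame with columns element, x, y, z, formal_charge,
#'   atom_name, residue_id (empty string for ligand atoms), is_het
#' @slot bonds data.frame with columns i, j, order
#' @slot name single character identifier
#' @exportClass MolecularStructure
setClass("MolecularStructure",
  representation(atoms = "data.frame", bonds = "data.frame",
                 name = "character"),
  prototype(atoms = data.frame(), bonds = data.frame(), name = ""))

setValidity("MolecularStructure", function(object) {
  a <- object@atoms
  b <- object@bonds
  msgs <- character()
  req <- c("element", "x", "y", "z", "formal_charge", "atom_name",
           "residue_id", "is_het")
  if (!all(req %in% names(a))) {
    return(paste("atoms must have columns:", paste(req, collapse = ", ")))
  }
  if (nrow(a)) {
    if (!all(isValidElement(a$element))) {
      bad <- unique(a$element[!isValidElement(a$element)])
      msgs <- c(msgs, paste("invalid element symbol(s):",
                            paste(bad, collapse = ", ")))
    }
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
      msgs <- c(msgs, "non-finite atom coordinates")
    }
  }
  if (nrow(b)) {
    if (!all(c("i", "j", "order") %in% names(b))) {
      msgs <- c(msgs, "bonds must have columns i, j, order")
    } else {
      if (any(b$i == b$j)) msgs <- c(msgs, "self-bonds are not allowed")
      if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a))) {
        msgs <- c(msgs, "bond endpoints out of atom index range")
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ProteinLigandComplex: a receptor structure plus a ligand pose
#'
#' Receptor and ligand share one Cartesian frame; the ligand pose is taken
#' as given (poses are inputs, no docking is performed).
#'
#' @slot receptor MolecularStructure
#' @slot ligand MolecularStructure
#' @slot id single character identifier
#' @exportClass ProteinLigandComplex
setClass("ProteinLigandComplex",
  representation(receptor = "MolecularStructure",
                 ligand = "MolecularStructure", id = "character"),
  prototype(id = "complex"))

#' BindingSiteEnvironment: receptor atoms proximal to the ligand pose
#'
#' Whole residues are included when any of their heavy atoms lies within
#' the cutoff of any ligand heavy atom.
#'
#' @slot atoms data.frame subset of the receptor atom table, plus a
#'   receptor_index column referring back to the full receptor
#' @slot sourceResidues character vector of included residue tags
#' @slot cutoffUsed numeric, Angstrom
#' @exportClass BindingSiteEnvironment
setClass("BindingSiteEnvironment",
  representation(atoms = "data.frame", sourceResidues = "character",
                 cutoffUsed = "numeric"))

#' DescriptorVector: an ordered, named, fixed-length float vector
#'
#' @slot values named numeric vector (length 35 for GRADE, 177 for X-GRADE)
#' @slot variant "GRADE" or "XGRADE"
#' @slot layout data.frame with columns index (0-based), name, section
#' @slot provenance list (complex id, variant, parameter-table checksum)
#' @exportClass DescriptorVector
setClass("DescriptorVector",
  representation(values = "numeric", variant = "character",
                 layout = "data.frame", provenance = "list"))

setValidity("DescriptorVector", function(object) {
  n_expect <- if (object@variant == "GRADE") 35L else 177L
  if (length(object@values) != n_expect) {
    return(sprintf("variant %s requires %d values, got %d",
                   object@variant, n_expect, length(object@values)))
  }
  if (nrow(object@layout) != n_expect) return("layout/value length mismatch")
  if (anyDuplicated(object@layout$name)) return("layout names not unique")
  if (!all(is.finite(object@values))) return("non-finite descriptor values")
  TRUE
})

## ---- accessors ----

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))
#' @export
setGeneric("receptor", function(x) standardGeneric("receptor"))
#' @export
setGeneric("ligand", function(x) standardGeneric("ligand"))
#' @export
setGeneric("complexId", function(x) standardGeneric("complexId"))
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))
#' @export
setGeneric("descriptorVariant", function(x) standardGeneric("descriptorVariant"))
#' @export
setGeneric("descriptorLayoutOf", function(x) standardGeneric("descriptorLayoutOf"))

#' @describeIn MolecularStructure atom table accessor
#' @param x object
#' @export
setMethod("atoms", "MolecularStructure", function(x) x@atoms)
#' @describeIn MolecularStructure bond table accessor
#' @export
setMethod("bonds", "MolecularStructure", function(x) x@bonds)
#' @describeIn MolecularStructure name accessor
#' @export
setMethod("structureName", "MolecularStructure", function(x) x@name)
#' @describeIn ProteinLigandComplex receptor accessor
#' @param x object
#' @export
setMethod("receptor", "ProteinLigandComplex", function(x) x@receptor)
#' @describeIn ProteinLigandComplex ligand accessor
#' @export
setMethod("ligand", "ProteinLigandComplex", function(x) x@ligand)
#' @describeIn ProteinLigandComplex id accessor
#' @export
setMethod("complexId", "ProteinLigandComplex", function(x) x@id)
#' @describeIn BindingSiteEnvironment atom table accessor
#' @export
setMethod("atoms", "BindingSiteEnvironment", function(x) x@atoms)
#' @describeIn DescriptorVector values accessor
#' @param x object
#' @export
setMethod("descriptorValues", "DescriptorVector", function(x) x@values)
#' @describeIn DescriptorVector variant accessor
#' @export
setMethod("descriptorVariant", "DescriptorVector", function(x) x@variant)
#' @describeIn DescriptorVector layout accessor
#' @export
setMethod("descriptorLayoutOf", "DescriptorVector", function(x) x@layout)

## ---- show methods ----

setMethod("show", "MolecularStructure", function(object) {
  a <- object@atoms
  cat("MolecularStructure:", object@name, "\n")
  cat(" ", nrow(a), "atoms (", sum(a$element != "H"), "heavy ),",
      nrow(object@bonds), "bonds\n")
  if (nrow(a)) {
    cat("  elements:",
        paste(names(sort(table(a$element), decreasing = TRUE)),
              collapse = " "), "\n")
  }
})

setMethod("show", "ProteinLigandComplex", function(object) {
  cat("ProteinLigandComplex:", object@id, "\n")
  cat("  receptor:", nrow(object@receptor@atoms), "atoms |  ligand:",
      nrow(object@ligand@atoms), "atoms\n")
})

setMethod("show", "BindingSiteEnvironment", function(object) {
  cat("BindingSiteEnvironment:", nrow(object@atoms), "atoms from",
      length(object@sourceResidues), "residues (cutoff",
      object@cutoffUsed, "A)\n")
})

setMethod("show", "DescriptorVector", function(object) {
  cat("DescriptorVector [", object@variant, "], length ",
      length(object@values), "\n", sep = "")
  v <- object@values
  show_n <- min(8L, length(v))
  for (k in seq_len(show_n)) {
    cat(sprintf("  [%2d] %-38s %g\n", k - 1L, names(v)[k], v[[k]]))
  }
  if (length(v) > show_n) cat("  ...\n")
})

## ---- constructors ----

#' Create a MolecularStructure from atom and bond tables
#'
#' @param elements character vector of element symbols
#' @param coords n x 3 numeric matrix, Angstrom
#' @param bonds data.frame(i, j, order); may be empty
#' @param formal_charge integer vector (default all 0)
#' @param atom_name character vector (default element + index)
#' @param residue_id character vector (default "")
#' @param is_het logical vector (default FALSE)
#' @param name structure name
#' @return MolecularStructure
#' @export
molecularStructure <- function(elements, coords, bonds = NULL,
                               formal_charge = 0L, atom_name = NULL,
                               residue_id = "", is_het = FALSE,
                               name = "mol") {
  n <- length(elements)
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == n)
  if (is.null(atom_name)) atom_name <- paste0(elements, seq_len(n))
  a <- data.frame(element = as.character(elements),
                  x = coords[, 1], y = coords[, 2], z = coords[, 3],
                  formal_charge = as.integer(rep_len(formal_charge, n)),
                  atom_name = rep_len(as.character(atom_name), n),
                  residue_id = rep_len(as.character(residue_id), n),
                  is_het = rep_len(as.logical(is_het), n),
                  stringsAsFactors = FALSE)
  if (is.null(bonds) || !NROW(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.numeric(bonds$order))
  }
  new("MolecularStructure", atoms = a, bonds = bonds, name = name)
}

#' Pair a receptor and a ligand pose into a complex
#'
#' @param receptor,ligand MolecularStructure objects in one coordinate frame
#' @param id complex identifier
#' @return ProteinLigandComplex
#' @export
proteinLigandComplex <- function(receptor, ligand, id = "complex") {
  new("ProteinLigandComplex", receptor = receptor, ligand = ligand, id = id)
}

## coordinate matrix helper used throughout
coordMat <- function(mol) {
  as.matrix(mol@atoms[, c("x", "y", "z")])
}

## replace coordinates, preserving everything else
setCoords <- function(mol, coords) {
  mol@atoms$x <- coords[, 1]
  mol@atoms$y <- coords[, 2]
  mol@atoms$z <- coords[, 3]
  mol
}
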