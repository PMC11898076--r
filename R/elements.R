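# Element bookkeeping: periodic-table symbols, covalent radii used for
# receptor bond perception, and PEOE electronegativity parameters.

.ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr")

isValidElement <- function(x) x %in% .ELEMENT_SYMBOLS

## Normalize an element symbol coming from file columns ("CL", "cl" -> "Cl").
normalizeElement <- function(x) {
  x <- trimws(x)
  out <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  out[x == ""] <- ""
  out
}

## Covalent radii (Angstrom, Cordero 2008 values for the common elements).
## Used only for distance-based bond perception on receptor structures.
.COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07,
  S = 1.05, Cl = 1.02, K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Co = 1.26,
  Ni = 1.24, Cu = 1.32, Zn = 1.22, Ga = 1.22, Ge = 1.20, As = 1.19,
  Se = 1.20, Br = 1.20, Rb = 2.20, Sr = 1.95, Mo = 1.54, Ag = 1.45,
  Cd = 1.44, In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39,
  Cs = 2.44, Ba = 2.15, Pt = 1.36, Au = 1.36, Hg = 1.32, Pb = 1.46)

covalentRadius <- function(element) {
  r <- .COVALENT_RADII[element]
  r[is.na(r)] <- 1.5  # generous default for exotic elements
  unname(r)
}

## Guess the element from a PDB atom name when the element column is absent.
## PDB convention: columns 13-14 hold the element, digits/primes decorate.
elementFromAtomName <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", trimws(nm))
    if (nchar(nm) == 0) return("")
    two <- normalizeElement(substr(nm, 1, 2))
    if (nchar(nm) >= 2 && isValidElement(two) &&
        two %in% c("Cl", "Br", "Fe", "Zn", "Mg", "Mn", "Na", "Ca", "Cu",
                   "Se", "Ni", "Co", "Cd", "Hg")) {
      return(two)
    }
    one <- normalizeElement(substr(nm, 1, 1))
    if (isValidElement(one)) one else ""
  }, character(1), USE.NAMES = FALSE)
}

## PEOE (Gasteiger-Marsili) electronegativity polynomial coefficients
## a + b*q + c*q^2 by orbital type. Keys: element + hybridization class.
.PEOE_PARAMS <- rbind(
  H    = c(7.17, 6.24, -0.56),
  C.3  = c(7.98, 9.18, 1.88),
  C.2  = c(8.79, 9.32, 1.51),
  C.1  = c(10.39, 9.45, 0.73),
  N.3  = c(11.54, 10.82, 1.36),
  N.2  = c(12.87, 11.15, 0.85),
  N.1  = c(15.68, 11.70, -0.27),
  O.3  = c(14.18, 12.92, 1.39),
  O.2  = c(17.07, 13.79, 0.47),
  F    = c(14.66, 13.85, 2.31),
  Cl   = c(11.00, 9.69, 1.35),
  Br   = c(10.08, 8.47, 1.16),
  I    = c(9.90, 7.96, 0.96),
  S.3  = c(10.14, 9.13, 1.38),
  S.2  = c(10.88, 9.49, 1.33),
  P.3  = c(8.90, 8.24, 0.96))

peoeParams <- function(key) {
  p <- .PEOE_PARAMS[key, , drop = FALSE]
  rownames(p) <- NULL
  p
}
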