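# Descriptor layouts. GRADE: 13 pose-independent ligand entries + 22
# pose-dependent entries (4 coverage, 7 interaction-type sum/max-sum
# pairs, 4 physics terms) = 35. X-GRADE: 31 ligand entries + 146
# pose-dependent entries = 177, where the H-bond related families are
# resolved by Sybyl subtype:
#   * coverage enumerated over the full 13-class subtype vocabulary
#     (12 Sybyl types + OTHER) for env HBA and env HBD: 2*2*13 = 52
#   * HBD<->HBA and HBA<->HBD score pairs expanded once over the ligand
#     feature subtype (9 HBD classes, 11 HBA classes) and once over the
#     environment feature subtype (11, 9): 2*(20 + 20) = 80
#   * the five non-H-bond pairs and 4 physics terms as in GRADE: 14
# 52 + 80 + 14 = 146. The family order follows the GRADE backbone
# (coverage, PI<->AR, AR<->PI, H<->H, AR<->AR, H-bond families,
# XBD<->XBA, physics). A hard length assertion (35/177) guards the layout.

.COVERAGE_VOCAB <- c("OTHER", .SYBYL_VOCAB)

.GRADE_PAIRS <- c("PI:AR", "AR:PI", "H:H", "AR:AR", "HBD:HBA", "HBA:HBD",
                  "XBD:XBA")

pairLabel <- function(pair) sub(":", " <-> ", pair, fixed = TRUE)

sumMaxNames <- function(label, first_interaction = FALSE) {
  sum_name <- if (first_interaction) {
    paste(label, "interaction score sum")
  } else paste(label, "score sum")
  c(sum_name, paste(label, "score max. sum"))
}

.PHYSICS_NAMES <- c("electrostatic potential",
                    "sum of pairwise electrostatic forces",
                    "VdW attraction", "VdW repulsion")

ligandBlockNames <- function(variant) {
  if (variant == "GRADE") {
    c("PI feature count", "NI feature count", "AR feature count",
      "H feature count", "HBD feature count", "HBA feature count",
      "XBD feature count", "XBA feature count", "heavy atom count",
      "rotatable bond count", "total hydrophobic feature weight",
      "XlogP", "TPSA")
  } else {
    c("PI feature count", "NI feature count", "AR feature count",
      "H feature count", "HBD feature count", "HBA feature count",
      "XBD feature count", "XBA feature count",
      paste(.HBD_SUBTYPES, "HBD feature count"),
      paste(.HBA_SUBTYPES, "HBA feature count"),
      "heavy atom count", "rotatable bond count",
      "total hydrophobic feature weight", "XlogP", "TPSA")
  }
}

poseDependentNames <- function(variant) {
  if (variant == "GRADE") {
    cov <- c("HBA coverage sum", "HBA coverage max. sum",
             "HBD coverage sum", "HBD coverage max. sum")
    pairs <- unlist(lapply(seq_along(.GRADE_PAIRS), function(k) {
      sumMaxNames(pairLabel(.GRADE_PAIRS[k]), first_interaction = (k == 1))
    }))
    nm <- c(cov, pairs, .PHYSICS_NAMES)
  } else {
    cov <- unlist(lapply(c("HBA", "HBD"), function(X) {
      unlist(lapply(.COVERAGE_VOCAB, function(s) {
        c(sprintf("%s %s coverage sum", s, X),
          sprintf("%s %s coverage max. sum", s, X))
      }))
    }))
    hbond_family <- function(ligType, envType, ligVocab, envVocab) {
      lig_side <- unlist(lapply(c("OTHER", ligVocab), function(s) {
        sumMaxNames(sprintf("%s(%s) <-> %s", ligType, s, envType))
      }))
      env_side <- unlist(lapply(c("OTHER", envVocab), function(s) {
        sumMaxNames(sprintf("%s <-> %s(%s)", ligType, envType, s))
      }))
      c(lig_side, env_side)
    }
    nm <- c(cov,
            sumMaxNames("PI <-> AR", first_interaction = TRUE),
            sumMaxNames("AR <-> PI"),
            sumMaxNames("H <-> H"),
            sumMaxNames("AR <-> AR"),
            hbond_family("HBD", "HBA", .HBD_SUBTYPES, .HBA_SUBTYPES),
            hbond_family("HBA", "HBD", .HBA_SUBTYPES, .HBD_SUBTYPES),
            sumMaxNames("XBD <-> XBA"),
            .PHYSICS_NAMES)
    stopifnot(length(nm) == 146L)   # guards the systematic expansion
  }
  nm
}

#' Descriptor layout for a variant
#'
#' @param variant "GRADE" or "XGRADE"
#' @return data.frame with columns index (0-based), name, section
#'   (ligand / coverage / interaction / physics)
#' @export
descriptorLayout <- function(variant = c("GRADE", "XGRADE")) {
  variant <- normVariant(variant)
  lig <- ligandBlockNames(variant)
  pd <- poseDependentNames(variant)
  nm <- c(lig, pd)
  n_cov <- if (variant == "GRADE") 4L else 52L
  n_int <- length(pd) - n_cov - 4L
  section <- c(rep("ligand", length(lig)), rep("coverage", n_cov),
               rep("interaction", n_int), rep("physics", 4L))
  expect <- if (variant == "GRADE") 35L else 177L
  stopifnot(length(nm) == expect, !anyDuplicated(nm))
  data.frame(index = seq_along(nm) - 1L, name = nm, section = section,
             stringsAsFactors = FALSE)
}
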