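# Interaction-type parameter bundles driving the distance/angle kernels.
# Each scored ligand-type/environment-type pair carries a distance window
# (min, ideal_lo, ideal_hi, max in Angstrom), zero or more angle
# constraints (kind, ideal, tolerance in degrees) and a flag marking the
# hydrophobic pair whose weighting factor C_ij is the product of feature
# weights. The table is shipped as editable YAML-compatible defaults and
# can be overridden wholesale from a config file.
#
# Angle constraint kinds:
#   dha_lig / dha_env  D-H...A angle at the donor hydrogen (donor on the
#                      ligand / environment side)
#   cxa_lig            C-X...A sigma-hole angle at the halogen (ligand side)
#   plane              angle between the two aromatic plane normals
#   offset             angle between the centroid-centroid vector and the
#                      ligand ring normal (stack offset control)
#   axial_lig/axial_env  angle between a ring normal (ligand/env side) and
#                      the centroid-to-cation vector
# plane/offset/axial angles are folded to [0, 90] degrees (normal sign is
# arbitrary); dha/cxa angles live on [0, 180].

interactionParam <- function(dmin, dlo, dhi, dmax, angles = list(),
                             uses_weights = FALSE) {
  stopifnot(dmin <= dlo, dlo <= dhi, dhi <= dmax)
  for (a in angles) {
    stopifnot(is.character(a$kind), a$tol > 0)
  }
  list(dist = c(min = dmin, ideal_lo = dlo, ideal_hi = dhi, max = dmax),
       angles = angles, uses_weights = uses_weights)
}

#' Default interaction-type parameter table
#'
#' The seven scored ligand/environment type pairs (ligand type first):
#' PI:AR, AR:PI, H:H, AR:AR, HBD:HBA, HBA:HBD, XBD:XBA. Values follow
#' standard pharmacophore interaction geometry; every number is
#' overridable via a config file (\code{\link{readInteractionParams}}).
#'
#' @return named list of parameter bundles
#' @export
defaultInteractionParams <- function() {
  list(
    "PI:AR" = interactionParam(3.0, 3.4, 4.5, 5.5,
      angles = list(list(kind = "axial_env", ideal = 0, tol = 40))),
    "AR:PI" = interactionParam(3.0, 3.4, 4.5, 5.5,
      angles = list(list(kind = "axial_lig", ideal = 0, tol = 40))),
    "H:H" = interactionParam(3.0, 3.5, 4.5, 5.5, uses_weights = TRUE),
    "AR:AR" = interactionParam(3.0, 3.3, 4.0, 5.5,
      angles = list(list(kind = "plane", ideal = 0, tol = 40),
                    list(kind = "offset", ideal = 0, tol = 45))),
    "HBD:HBA" = interactionParam(2.5, 2.8, 3.2, 3.8,
      angles = list(list(kind = "dha_lig", ideal = 180, tol = 50))),
    "HBA:HBD" = interactionParam(2.5, 2.8, 3.2, 3.8,
      angles = list(list(kind = "dha_env", ideal = 180, tol = 50))),
    "XBD:XBA" = interactionParam(2.8, 3.0, 3.6, 4.0,
      angles = list(list(kind = "cxa_lig", ideal = 165, tol = 45))))
}

#' Write an interaction parameter table to a YAML config file
#'
#' @param params named list as from \code{\link{defaultInteractionParams}}
#' @param path output path
#' @return invisibly, the path
#' @export
writeInteractionParams <- function(params, path) {
  ser <- lapply(params, function(p) {
    list(distance = as.list(p$dist), angles = p$angles,
         uses_weights = p$uses_weights)
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read an interaction parameter table from a YAML config file
#'
#' @param path config path (sections keyed by "LIGTYPE:ENVTYPE")
#' @return named list of parameter bundles
#' @export
readInteractionParams <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(p) {
    d <- p$distance
    interactionParam(d$min, d$ideal_lo, d$ideal_hi, d$max,
                     angles = if (is.null(p$angles)) list() else p$angles,
                     uses_weights = isTRUE(p$uses_weights))
  })
  names(out) <- names(raw)
  out
}

#' Assemble a run configuration
#'
#' Defaults reproduce the method's stated constants: Morse well-width
#' factor alpha = 1.1, hydrophobic placement threshold 0.15, binding-site
#' cutoff 7.0 A.
#'
#' @param variant "GRADE" or "XGRADE"
#' @param cutoff binding-site heavy-atom cutoff, Angstrom
#' @param alpha Morse well-width factor (dimensionless)
#' @param hydrophobicThreshold minimum logP increment for H features
#' @param chargeScheme "mmff94" (OpenBabel, with automatic PEOE fallback)
#'   or "peoe" (in-package Gasteiger-Marsili)
#' @param includeHet include waters/ions in the environment
#' @param protonate run the rule-based protonation pass on the receptor
#' @param params interaction parameter table
#' @param logpTable named increment table
#' @param uffTable UFF parameter data.frame
#' @return classed list ("GradeConfig")
#' @export
gradeConfig <- function(variant = "GRADE", cutoff = 7.0, alpha = 1.1,
                        hydrophobicThreshold = 0.15,
                        chargeScheme = c("mmff94", "peoe"),
                        includeHet = TRUE, protonate = FALSE,
                        params = defaultInteractionParams(),
                        logpTable = defaultLogPTable(),
                        uffTable = defaultUFFTable()) {
  stopifnot(cutoff > 0, alpha > 0, hydrophobicThreshold >= 0)
  cfg <- list(variant = normVariant(variant), cutoff = cutoff, alpha = alpha,
              hydrophobic_threshold = hydrophobicThreshold,
              charge_scheme = match.arg(chargeScheme),
              include_het = includeHet, protonate = protonate,
              params = params, logp_table = logpTable,
              uff_table = uffTable)
  class(cfg) <- "GradeConfig"
  cfg
}

## checksum of the numeric parameter content, for provenance fields
configChecksum <- function(cfg) {
  s <- paste(cfg$variant, cfg$cutoff, cfg$alpha, cfg$hydrophobic_threshold,
             cfg$charge_scheme,
             paste(unlist(lapply(cfg$params, function(p) p$dist)),
                   collapse = ","),
             paste(round(cfg$logp_table, 6), collapse = ","),
             sep = "|")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}
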