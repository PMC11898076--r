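# Descriptor assembly: run perception, scoring and physics over a complex
# and fill the layout in order. Stage failures are re-signalled with the
# stage name attached; an empty binding site is legal and produces an
# all-zero pose-dependent block.

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

featOfType <- function(f, ty, sub = NULL) {
  rows <- f$type == ty
  if (!is.null(sub)) rows <- rows & f$subtype == sub
  f[rows, , drop = FALSE]
}

#' Compute a GRADE or X-GRADE descriptor vector for a complex
#'
#' @param cplx ProteinLigandComplex
#' @param variant "GRADE" or "XGRADE" (overrides the config's variant)
#' @param config GradeConfig (defaults: cutoff 7 A, alpha 1.1,
#'   hydrophobic threshold 0.15)
#' @return DescriptorVector
#' @export
assembleDescriptor <- function(cplx, variant = NULL,
                               config = gradeConfig()) {
  cfg <- config
  if (!is.null(variant)) cfg$variant <- normVariant(variant)
  variant <- cfg$variant
  lig <- ligand(cplx)
  rec <- receptor(cplx)

  profile <- stageTry("ligand-profile",
    ligandProfile(lig, cfg$hydrophobic_threshold, cfg$logp_table))
  lig_block <- stageTry("pose-independent-vector",
    poseIndependentVector(profile, variant))
  ligF <- profile$features

  env <- stageTry("binding-site",
    extractBindingSite(cplx, cfg$cutoff, cfg$include_het))
  envStruct <- stageTry("binding-site", environmentStructure(rec, env))
  envF <- stageTry("environment-features",
    perceiveFeatures(envStruct, cfg$hydrophobic_threshold, cfg$logp_table))

  P <- cfg$params
  hb_par <- P[["HBD:HBA"]]

  cov_pair <- function(envType, sub = NULL) {
    atoms_nc <- nonComplementaryAtoms(lig, ligF, envType)
    ef <- featOfType(envF, envType, sub)
    c(coverageSum(atoms_nc, ef, hb_par),
      coverageMaxSum(atoms_nc, ef, hb_par))
  }
  int_pair <- function(pair, ligSub = NULL, envSub = NULL) {
    ty <- strsplit(pair, ":", fixed = TRUE)[[1]]
    lf <- featOfType(ligF, ty[1], ligSub)
    ef <- featOfType(envF, ty[2], envSub)
    c(aggregateSum(lf, ef, P[[pair]]), aggregateMaxSum(lf, ef, P[[pair]]))
  }

  pd <- stageTry("scoring", {
    if (variant == "GRADE") {
      c(cov_pair("HBA"), cov_pair("HBD"),
        unlist(lapply(.GRADE_PAIRS, int_pair)))
    } else {
      cov <- unlist(lapply(c("HBA", "HBD"), function(X) {
        unlist(lapply(.COVERAGE_VOCAB, function(s) cov_pair(X, s)))
      }))
      hb_family <- function(pair, ligVocab, envVocab) {
        lig_side <- unlist(lapply(c("OTHER", ligVocab), function(s) {
          int_pair(pair, ligSub = s)
        }))
        env_side <- unlist(lapply(c("OTHER", envVocab), function(s) {
          int_pair(pair, envSub = s)
        }))
        c(lig_side, env_side)
      }
      c(cov,
        int_pair("PI:AR"), int_pair("AR:PI"), int_pair("H:H"),
        int_pair("AR:AR"),
        hb_family("HBD:HBA", .HBD_SUBTYPES, .HBA_SUBTYPES),
        hb_family("HBA:HBD", .HBA_SUBTYPES, .HBD_SUBTYPES),
        int_pair("XBD:XBA"))
    }
  })

  phys <- stageTry("physics", physicsBlock(lig, envStruct, cfg))

  layout <- descriptorLayout(variant)
  values <- c(unname(lig_block), unname(pd), unname(phys))
  stopifnot(length(values) == nrow(layout))
  names(values) <- layout$name
  new("DescriptorVector", values = values, variant = variant,
      layout = layout,
      provenance = list(complex_id = complexId(cplx), variant = variant,
                        config_checksum = configChecksum(cfg)))
}

#' Compute a descriptor straight from receptor and ligand files
#'
#' Thin wrapper: read, pair, assemble.
#'
#' @param receptorPath PDB/mmCIF file
#' @param ligandPath SDF/MOL2 file
#' @param variant "GRADE" or "XGRADE"
#' @param config GradeConfig
#' @param id complex identifier (default: file stem pair)
#' @return DescriptorVector
#' @export
computeDescriptor <- function(receptorPath, ligandPath, variant = "GRADE",
                              config = gradeConfig(), id = NULL) {
  rec <- stageTry("read-receptor",
                  readReceptor(receptorPath, protonate = config$protonate))
  lig <- stageTry("read-ligand", readLigand(ligandPath))
  if (is.null(id)) {
    id <- paste(tools::file_path_sans_ext(basename(receptorPath)),
                tools::file_path_sans_ext(basename(ligandPath)), sep = "__")
  }
  assembleDescriptor(proteinLigandComplex(rec, lig, id = id),
                     variant = variant, config = config)
}
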