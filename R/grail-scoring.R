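# GRAIL feature-pair interaction scores. The score of a ligand feature i
# against an environment feature j is
#     FIS_ij = C_ij * DS_ij * AS_ij
# with DS and AS in [0, 1]. C_ij is 1 except for hydrophobic pairs, where
# it is the product of the two feature weights (logP increments). Per
# interaction type the descriptor stores the plain double sum of FIS and
# the "max sum": for each ligand feature the maximum over environment
# partners, summed over ligand features.

#' Distance kernel: plateau with cubic smoothstep ramps
#'
#' 1 on [ideal_lo, ideal_hi], 0 outside [min, max], smoothstep in between
#' (exact 0.5 at ramp midpoints).
#'
#' @param r distance(s), Angstrom
#' @param params interaction parameter bundle (uses \code{params$dist})
#' @return numeric in [0, 1], vectorized over r
#' @export
distanceScore <- function(r, params) {
  d <- params$dist
  out <- numeric(length(r))
  lo_ramp <- r >= d["min"] & r < d["ideal_lo"]
  plateau <- r >= d["ideal_lo"] & r <= d["ideal_hi"]
  hi_ramp <- r > d["ideal_hi"] & r <= d["max"]
  if (d["ideal_lo"] > d["min"]) {
    out[lo_ramp] <- smoothstep((r[lo_ramp] - d["min"]) /
                                 (d["ideal_lo"] - d["min"]))
  } else {
    out[lo_ramp] <- 1
  }
  out[plateau] <- 1
  if (d["max"] > d["ideal_hi"]) {
    out[hi_ramp] <- 1 - smoothstep((r[hi_ramp] - d["ideal_hi"]) /
                                     (d["max"] - d["ideal_hi"]))
  } else {
    out[hi_ramp] <- 1
  }
  out
}

## single angle-constraint kernel on the deviation from ideal
angleKernel <- function(deviation, tol) {
  1 - smoothstep(deviation / tol)
}

featPos <- function(row) c(row$x, row$y, row$z)
featDir <- function(row) c(row$dirx, row$diry, row$dirz)
featAux <- function(row) c(row$auxx, row$auxy, row$auxz)

## fold an angle to [0, 90] (plane-normal sign is arbitrary)
fold90 <- function(ang) ifelse(ang > 90, 180 - ang, ang)

#' Angle-dependent score for one feature pair
#'
#' Product over the type's angle constraints; types with no angle
#' constraint return 1. A constraint whose required geometry (direction or
#' auxiliary point) is missing is dropped with a warning.
#'
#' @param f_lig,f_env single-row feature data.frames
#' @param params interaction parameter bundle
#' @return numeric in [0, 1]
#' @export
angleScore <- function(f_lig, f_env, params) {
  if (!length(params$angles)) return(1)
  p_l <- featPos(f_lig); p_e <- featPos(f_env)
  score <- 1
  for (con in params$angles) {
    dev <- tryCatch({
      switch(con$kind,
        dha_lig = {
          h <- featAux(f_lig)
          if (any(is.na(h))) stop("no donor hydrogen")
          abs(con$ideal - vecAngle(p_l - h, p_e - h))
        },
        dha_env = {
          h <- featAux(f_env)
          if (any(is.na(h))) stop("no donor hydrogen")
          abs(con$ideal - vecAngle(p_e - h, p_l - h))
        },
        cxa_lig = {
          cpos <- featAux(f_lig)
          if (any(is.na(cpos))) stop("no halogen-bound carbon")
          abs(con$ideal - vecAngle(cpos - p_l, p_e - p_l))
        },
        plane = {
          nl <- featDir(f_lig); ne <- featDir(f_env)
          if (any(is.na(nl)) || any(is.na(ne))) stop("missing ring normal")
          abs(con$ideal - fold90(vecAngle(nl, ne)))
        },
        offset = {
          nl <- featDir(f_lig)
          if (any(is.na(nl))) stop("missing ring normal")
          abs(con$ideal - fold90(vecAngle(nl, p_e - p_l)))
        },
        axial_lig = {
          nl <- featDir(f_lig)
          if (any(is.na(nl))) stop("missing ring normal")
          abs(con$ideal - fold90(vecAngle(nl, p_e - p_l)))
        },
        axial_env = {
          ne <- featDir(f_env)
          if (any(is.na(ne))) stop("missing ring normal")
          abs(con$ideal - fold90(vecAngle(ne, p_l - p_e)))
        },
        stop("unknown angle kind: ", con$kind))
    }, error = function(e) {
      warning("angle constraint '", con$kind, "' dropped: ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
    if (is.na(dev)) next
    score <- score * angleKernel(dev, con$tol)
  }
  score
}

#' Full GRAIL score for one ligand/environment feature pair
#'
#' @param f_lig,f_env single-row feature data.frames
#' @param params interaction parameter bundle
#' @return list(ds, as_, c, fis)
#' @export
pairScore <- function(f_lig, f_env, params) {
  r <- vecNorm(featPos(f_lig) - featPos(f_env))
  ds <- distanceScore(r, params)
  as_ <- if (ds > 0) angleScore(f_lig, f_env, params) else 0
  cw <- if (isTRUE(params$uses_weights)) f_lig$weight * f_env$weight else 1
  list(ds = ds, as_ = as_, c = cw, fis = cw * ds * as_)
}

## FIS matrix: rows = ligand features, cols = environment features
pairScoreMatrix <- function(ligFeats, envFeats, params) {
  n <- nrow(ligFeats); m <- nrow(envFeats)
  if (!n || !m) return(matrix(0, n, m))
  out <- matrix(0, n, m)
  # distance prefilter keeps the angle work bounded
  d <- crossDist(as.matrix(ligFeats[, c("x", "y", "z")]),
                 as.matrix(envFeats[, c("x", "y", "z")]))
  dmax <- params$dist["max"]
  for (i in seq_len(n)) {
    for (j in which(d[i, ] <= dmax)) {
      out[i, j] <- pairScore(ligFeats[i, ], envFeats[j, ], params)$fis
    }
  }
  out
}

#' Sum aggregation of GRAIL scores for one interaction type
#'
#' @param ligFeats ligand features of the pair's ligand type
#' @param envFeats environment features of the pair's environment type
#' @param params interaction parameter bundle
#' @return double sum of FIS over all pairs (0 when either side is empty)
#' @export
aggregateSum <- function(ligFeats, envFeats, params) {
  sum(pairScoreMatrix(ligFeats, envFeats, params))
}

#' Max-sum aggregation of GRAIL scores for one interaction type
#'
#' For each ligand feature the best environment partner's score, summed
#' over ligand features; always bounded above by \code{aggregateSum}.
#'
#' @inheritParams aggregateSum
#' @return sum over ligand features of the row maxima (0 when empty)
#' @export
aggregateMaxSum <- function(ligFeats, envFeats, params) {
  m <- pairScoreMatrix(ligFeats, envFeats, params)
  if (!nrow(m) || !ncol(m)) return(0)
  sum(apply(m, 1, max))
}

## pseudo H-bond score matrix between bare ligand heavy atoms and
## environment H-bonding features: distance kernel only
coverageMatrix <- function(atomCoords, envFeats, params) {
  n <- nrow(atomCoords); m <- nrow(envFeats)
  if (!n || !m) return(matrix(0, n, m))
  d <- crossDist(atomCoords, as.matrix(envFeats[, c("x", "y", "z")]))
  matrix(distanceScore(as.numeric(d), params), n, m)
}

#' Binding-site H-bond coverage (sum form)
#'
#' Quantifies how strongly environment H-bonding features of one type are
#' sterically covered by ligand heavy atoms that cannot form the
#' complementary interaction. Scored with the H-bond distance kernel only
#' (a bare carbon defines no donor axis).
#'
#' @param atomCoords k x 3 matrix of the non-complementary ligand heavy
#'   atoms
#' @param envFeats environment features of the covered type (HBA or HBD)
#' @param params H-bond interaction parameter bundle (distance part used)
#' @return sum of pseudo-scores
#' @export
coverageSum <- function(atomCoords, envFeats, params) {
  sum(coverageMatrix(atomCoords, envFeats, params))
}

#' Binding-site H-bond coverage (max-sum form)
#'
#' Per ligand atom the best-covered environment feature, summed.
#'
#' @inheritParams coverageSum
#' @return sum of per-atom maxima
#' @export
coverageMaxSum <- function(atomCoords, envFeats, params) {
  m <- coverageMatrix(atomCoords, envFeats, params)
  if (!nrow(m) || !ncol(m)) return(0)
  sum(apply(m, 1, max))
}

## ligand heavy atoms NOT complementary to environment type X:
## complementary(HBA) = HBD, complementary(HBD) = HBA. An atom is excluded
## when any of its features has the complementary type.
nonComplementaryAtoms <- function(lig, ligFeats, envType) {
  comp <- if (envType == "HBA") "HBD" else "HBA"
  a <- lig@atoms
  heavy <- which(a$element != "H")
  blocked <- unique(unlist(ligFeats$parents[ligFeats$type == comp]))
  rows <- setdiff(heavy, blocked)
  as.matrix(a[rows, c("x", "y", "z"), drop = FALSE])
}
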