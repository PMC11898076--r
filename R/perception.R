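# Structure perception: adjacency, distance-based bond perception for
# receptors, ring finding, aromaticity, hybridization, Sybyl atom typing,
# rotatable-bond and polar-hydrogen classification.
#
# Ligands arrive with explicit bond orders (SDF/MOL2); receptors from PDB
# carry no bonds, so bonds are perceived from covalent radii and a minimal
# bond-order refinement (short terminal C-O contacts become carbonyls).

## adjacency list: integer vectors of neighbor atom indices
adjacencyList <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  adj
}

## order lookup matrix-free: named by "i-j" with i < j
bondOrderMap <- function(mol) {
  b <- mol@bonds
  key <- paste(pmin(b$i, b$j), pmax(b$i, b$j), sep = "-")
  stats::setNames(b$order, key)
}

getOrder <- function(omap, i, j) {
  unname(omap[paste(min(i, j), max(i, j), sep = "-")])
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of covalent
#' radii plus 0.45 A (and above 0.4 A). Intended for receptor structures
#' read from PDB, which carry no connectivity. A refinement pass upgrades
#' short terminal C-O contacts (< 1.28 A) to double bonds so that carbonyl
#' groups are recognized downstream.
#'
#' @param mol MolecularStructure without (or with incomplete) bonds
#' @return MolecularStructure with a perceived bond table (orders 1/2)
#' @export
perceiveBonds <- function(mol) {
  a <- mol@atoms
  n <- nrow(a)
  if (n < 2) {
    mol@bonds <- data.frame(i = integer(), j = integer(), order = numeric())
    return(mol)
  }
  xyz <- coordMat(mol)
  rad <- covalentRadius(a$element)
  ii <- jj <- integer()
  # residue-aware would be faster; n is small for fixtures, keep simple
  d <- crossDist(xyz, xyz)
  lim <- outer(rad, rad, "+") + 0.45
  hit <- which(d < lim & d > 0.4 & upper.tri(d), arr.ind = TRUE)
  # never bond two hydrogens, nor hydrogen to more than its nearest partner
  keep <- !(a$element[hit[, 1]] == "H" & a$element[hit[, 2]] == "H")
  hit <- hit[keep, , drop = FALSE]
  # each H keeps only its closest heavy partner
  isH <- a$element == "H"
  if (any(isH) && nrow(hit)) {
    hidx <- which(isH)
    drop <- logical(nrow(hit))
    for (h in hidx) {
      rows <- which(hit[, 1] == h | hit[, 2] == h)
      if (length(rows) > 1) {
        dd <- d[cbind(hit[rows, 1], hit[rows, 2])]
        drop[rows[-which.min(dd)]] <- TRUE
      }
    }
    hit <- hit[!drop, , drop = FALSE]
  }
  ord <- rep(1, nrow(hit))
  # carbonyl refinement: terminal O (one heavy neighbor, no H) at < 1.28 A
  if (nrow(hit)) {
    deg <- tabulate(c(hit[, 1], hit[, 2]), nbins = n)
    for (k in seq_len(nrow(hit))) {
      p <- hit[k, 1]; q <- hit[k, 2]
      eo <- sort(a$element[c(p, q)])
      if (identical(eo, c("C", "O"))) {
        o_at <- if (a$element[p] == "O") p else q
        if (deg[o_at] == 1 && d[p, q] < 1.28) ord[k] <- 2
      }
    }
  }
  mol@bonds <- data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
                          order = ord)
  mol
}

## Smallest rings (size 3..8) through every bond, unique set.
findRings <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- adjacencyList(mol)
  b <- mol@bonds
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    # BFS shortest path i -> j avoiding the direct bond
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[i] <- 0L
    queue <- i
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (cur == i && nb == j) next
        if (is.na(dist[nb])) {
          dist[nb] <- dist[cur] + 1L
          prev[nb] <- cur
          queue <- c(queue, nb)
        }
      }
      if (!is.na(dist[j])) break
    }
    if (is.na(dist[j]) || dist[j] > 7L) next
    path <- j
    while (path[1] != i) path <- c(prev[path[1]], path)
    ring <- sort(path)
    key <- paste(ring, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

## Aromatic ring detection.
## With real bond orders: Hueckel-style electron count over the ring.
## Without (distance-perceived, all orders 1): geometric criterion --
## planar ring of C/N atoms each with <= 3 heavy neighbors.
aromaticRings <- function(mol, rings = NULL) {
  if (is.null(rings)) rings <- findRings(mol)
  if (!length(rings)) return(list())
  a <- mol@atoms
  omap <- bondOrderMap(mol)
  adj <- adjacencyList(mol)
  has_orders <- any(mol@bonds$order > 1)
  xyz <- coordMat(mol)
  heavyDeg <- vapply(adj, function(nb) sum(a$element[nb] != "H"), integer(1))
  keep <- vapply(rings, function(ring) {
    el <- a$element[ring]
    if (length(ring) < 5 || length(ring) > 7) return(FALSE)
    if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
    if (!has_orders) {
      return(all(el %in% c("C", "N")) &&
             all(heavyDeg[ring] <= 3) &&
             planeDeviation(xyz[ring, , drop = FALSE]) < 0.15)
    }
    m <- length(ring)
    pi_e <- 0
    for (idx in seq_len(m)) {
      at <- ring[idx]
      nb_ring <- intersect(adj[[at]], ring)
      ords_ring <- vapply(nb_ring, function(nb) getOrder(omap, at, nb),
                          numeric(1))
      if (any(ords_ring == 1.5)) { pi_e <- pi_e + 1; next }
      all_ords <- vapply(adj[[at]], function(nb) getOrder(omap, at, nb),
                         numeric(1))
      if (any(ords_ring == 2)) {
        pi_e <- pi_e + 1
      } else if (a$element[at] %in% c("N", "O", "S") && all(all_ords <= 1)) {
        pi_e <- pi_e + 2      # lone pair donated into the ring
      } else if (a$element[at] == "C" && any(all_ords == 2)) {
        pi_e <- pi_e + 0      # exocyclic double bond, sp2 but contributes 0
      } else {
        return(FALSE)         # saturated center breaks conjugation
      }
    }
    pi_e %% 4 == 2
  }, logical(1))
  rings[keep]
}

## sp hybridization class from bond orders: 1 = sp, 2 = sp2, 3 = sp3
hybridization <- function(mol) {
  a <- mol@atoms
  omap <- bondOrderMap(mol)
  adj <- adjacencyList(mol)
  arom_atoms <- unique(unlist(aromaticRings(mol)))
  vapply(seq_len(nrow(a)), function(i) {
    ords <- vapply(adj[[i]], function(nb) getOrder(omap, i, nb), numeric(1))
    if (!length(ords)) return(3L)
    if (any(ords == 3) || sum(ords == 2) >= 2) return(1L)
    if (any(ords >= 1.5) || i %in% arom_atoms) return(2L)
    3L
  }, integer(1))
}

#' Classify polar hydrogens
#'
#' A hydrogen is polar iff its single bonded heavy neighbor is nitrogen,
#' oxygen, or sulfur.
#'
#' @param mol MolecularStructure with explicit hydrogens and bonds
#' @return logical vector over atoms (FALSE for non-hydrogens)
#' @export
isPolarHydrogen <- function(mol) {
  a <- mol@atoms
  adj <- adjacencyList(mol)
  vapply(seq_len(nrow(a)), function(i) {
    if (a$element[i] != "H") return(FALSE)
    nb <- adj[[i]]
    any(a$element[nb] %in% c("N", "O", "S"))
  }, logical(1))
}

#' Assign Sybyl atom subtypes to N, O and S atoms
#'
#' Vocabulary: N.1, N.2, N.3, N.4, N.ar, N.am, N.pl3, O.2, O.3, O.co2,
#' S.2, S.3. Atoms outside the vocabulary (including all non-N/O/S
#' elements) map to "OTHER".
#'
#' @param mol MolecularStructure with bonds (orders used when present)
#' @return character vector of subtypes, one per atom
#' @export
assignSybylTypes <- function(mol) {
  a <- mol@atoms
  n <- nrow(a)
  adj <- adjacencyList(mol)
  omap <- bondOrderMap(mol)
  arom_atoms <- unique(unlist(aromaticRings(mol)))
  isH <- a$element == "H"
  heavyNb <- lapply(adj, function(nb) nb[!isH[nb]])
  hCount <- vapply(adj, function(nb) sum(isH[nb]), integer(1))

  ordersOf <- function(i) {
    vapply(adj[[i]], function(nb) getOrder(omap, i, nb), numeric(1))
  }
  # terminal O with no H, attached to given center
  terminalOs <- function(center) {
    nb <- heavyNb[[center]]
    os <- nb[a$element[nb] == "O"]
    os[vapply(os, function(o) {
      length(heavyNb[[o]]) == 1 && hCount[o] == 0
    }, logical(1))]
  }

  out <- rep("OTHER", n)
  for (i in seq_len(n)) {
    el <- a$element[i]
    if (!(el %in% c("N", "O", "S"))) next
    ords <- ordersOf(i)
    if (el == "O") {
      parents <- heavyNb[[i]]
      is_coo <- FALSE
      if (length(parents) == 1 && hCount[i] == 0) {
        p <- parents[1]
        if (a$element[p] %in% c("C", "P") && length(terminalOs(p)) >= 2) {
          is_coo <- TRUE
        }
      }
      out[i] <- if (is_coo) "O.co2"
        else if (any(ords >= 2) || (i %in% arom_atoms)) "O.2"
        else "O.3"
    } else if (el == "N") {
      conn <- length(adj[[i]])
      if (i %in% arom_atoms) {
        out[i] <- "N.ar"
      } else if (any(ords == 3)) {
        out[i] <- "N.1"
      } else {
        # amide: single-bonded to a carbonyl/thiocarbonyl carbon
        amide <- any(vapply(heavyNb[[i]], function(p) {
          if (a$element[p] != "C") return(FALSE)
          if (getOrder(omap, i, p) != 1) return(FALSE)
          any(vapply(adj[[p]], function(q) {
            a$element[q] %in% c("O", "S") && getOrder(omap, p, q) >= 2
          }, logical(1)))
        }, logical(1)))
        if (amide) {
          out[i] <- "N.am"
        } else if (any(ords == 2) || any(ords == 1.5)) {
          out[i] <- "N.2"
        } else if (conn == 4 || a$formal_charge[i] > 0) {
          out[i] <- "N.4"
        } else {
          # trigonal planar when conjugated to an sp2/aromatic neighbor
          conj <- any(vapply(heavyNb[[i]], function(p) {
            (p %in% arom_atoms) ||
              any(vapply(adj[[p]], function(q) getOrder(omap, p, q) >= 1.5,
                         logical(1)))
          }, logical(1)))
          out[i] <- if (conj) "N.pl3" else "N.3"
        }
      }
    } else if (el == "S") {
      out[i] <- if (any(ords >= 2) || (i %in% arom_atoms)) "S.2" else "S.3"
    }
  }
  out
}

## Rotatable bonds: acyclic single bonds between two non-terminal heavy
## atoms; amide C-N excluded.
countRotatableBonds <- function(mol) {
  a <- mol@atoms
  b <- mol@bonds
  if (!nrow(b)) return(0L)
  adj <- adjacencyList(mol)
  isH <- a$element == "H"
  heavyDeg <- vapply(adj, function(nb) sum(!isH[nb]), integer(1))
  ring_atoms <- findRings(mol)
  in_ring_bond <- function(i, j) {
    any(vapply(ring_atoms, function(r) all(c(i, j) %in% r), logical(1)))
  }
  omap <- bondOrderMap(mol)
  n_rot <- 0L
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (b$order[k] != 1) next
    if (isH[i] || isH[j]) next
    if (heavyDeg[i] < 2 || heavyDeg[j] < 2) next
    if (in_ring_bond(i, j)) next
    # amide C-N exclusion
    amide <- FALSE
    for (pair in list(c(i, j), c(j, i))) {
      ci <- pair[1]; ni <- pair[2]
      if (a$element[ci] == "C" && a$element[ni] == "N") {
        has_carbonyl <- any(vapply(adj[[ci]], function(q) {
          a$element[q] %in% c("O", "S") && getOrder(omap, ci, q) >= 2
        }, logical(1)))
        if (has_carbonyl) amide <- TRUE
      }
    }
    if (amide) next
    n_rot <- n_rot + 1L
  }
  n_rot
}
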