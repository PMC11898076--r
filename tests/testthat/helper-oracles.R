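# Independent brute-force oracles. These re-derive the scoring math from
# scratch (own kernels, plain double loops) so they stay independent of
# the package implementation they check.

oracle_smooth <- function(x) {
  x <- pmin(1, pmax(0, x))
  3 * x^2 - 2 * x^3
}

oracle_dist_kernel <- function(r, d) {
  if (r < d["min"] || r > d["max"]) return(0)
  if (r >= d["ideal_lo"] && r <= d["ideal_hi"]) return(1)
  if (r < d["ideal_lo"]) {
    return(oracle_smooth((r - d["min"]) / (d["ideal_lo"] - d["min"])))
  }
  1 - oracle_smooth((r - d["ideal_hi"]) / (d["max"] - d["ideal_hi"]))
}

## naive all-pairs FIS sums for an angle-free interaction type
oracle_pair_sums <- function(ligFeats, envFeats, params) {
  n <- nrow(ligFeats); m <- nrow(envFeats)
  total <- 0; max_total <- 0
  for (i in seq_len(n)) {
    best <- 0
    for (j in seq_len(m)) {
      r <- sqrt(sum((c(ligFeats$x[i], ligFeats$y[i], ligFeats$z[i]) -
                       c(envFeats$x[j], envFeats$y[j], envFeats$z[j]))^2))
      cw <- if (isTRUE(params$uses_weights)) {
        ligFeats$weight[i] * envFeats$weight[j]
      } else 1
      fis <- cw * oracle_dist_kernel(r, params$dist)
      total <- total + fis
      if (fis > best) best <- fis
    }
    max_total <- max_total + best
  }
  list(sum = total, max_sum = max_total)
}

oracle_coverage <- function(atomCoords, envFeats, params) {
  n <- nrow(atomCoords); m <- nrow(envFeats)
  total <- 0; max_total <- 0
  for (i in seq_len(n)) {
    best <- 0
    for (j in seq_len(m)) {
      r <- sqrt(sum((atomCoords[i, ] -
                       c(envFeats$x[j], envFeats$y[j], envFeats$z[j]))^2))
      s <- oracle_dist_kernel(r, params$dist)
      total <- total + s
      if (s > best) best <- s
    }
    max_total <- max_total + best
  }
  list(sum = total, max_sum = max_total)
}

oracle_electrostatic <- function(lc, ec, lq, eq, x) {
  total <- 0
  for (i in seq_len(nrow(lc))) {
    for (j in seq_len(nrow(ec))) {
      r <- sqrt(sum((lc[i, ] - ec[j, ])^2))
      total <- total + lq[i] * eq[j] / r^x
    }
  }
  total
}

oracle_morse <- function(lc, ec, Di, Dj, xi, xj, alpha) {
  att <- 0; rep_ <- 0
  for (i in seq_len(nrow(lc))) {
    for (j in seq_len(nrow(ec))) {
      r <- sqrt(sum((lc[i, ] - ec[j, ])^2))
      D <- sqrt(Di[i] * Dj[j]); X <- sqrt(xi[i] * xj[j])
      rep_ <- rep_ + D * exp(-2 * alpha * (r - X))
      att <- att - 2 * D * exp(-alpha * (r - X))
    }
  }
  c(attraction = att, repulsion = rep_)
}

## random angle-free feature sets in a small box
random_features <- function(n, type = "H") {
  data.frame(type = type, subtype = "OTHER",
             x = runif(n, -4, 4), y = runif(n, -4, 4), z = runif(n, -4, 4),
             dirx = NA_real_, diry = NA_real_, dirz = NA_real_,
             auxx = NA_real_, auxy = NA_real_, auxz = NA_real_,
             weight = runif(n, 0.15, 1), parent = seq_len(n),
             parents = I(as.list(seq_len(n))), stringsAsFactors = FALSE)
}

rigid_transform_complex <- function(cplx, rot, trans) {
  move <- function(mol) {
    xyz <- as.matrix(mol@atoms[, c("x", "y", "z")])
    xyz2 <- sweep(xyz %*% t(rot), 2, trans, "+")
    mol@atoms$x <- xyz2[, 1]; mol@atoms$y <- xyz2[, 2]
    mol@atoms$z <- xyz2[, 3]
    mol
  }
  methods::new("ProteinLigandComplex", receptor = move(receptor(cplx)),
               ligand = move(ligand(cplx)), id = complexId(cplx))
}

random_rotation_matrix <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## config that avoids the external charge tool: deterministic in-R path
peoe_config <- function(variant = "GRADE") {
  gradeConfig(variant = variant, chargeScheme = "peoe")
}
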