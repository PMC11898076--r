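# Small geometry helpers shared across modules. All coordinates are in
# Angstroms and all angles in degrees unless stated otherwise.

vecNorm <- function(v) sqrt(sum(v * v))

unitVec <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

## Angle in degrees between two 3-vectors.
vecAngle <- function(a, b) {
  ca <- sum(a * b) / (vecNorm(a) * vecNorm(b))
  ca <- min(1, max(-1, ca))
  acos(ca) * 180 / pi
}

## Cubic smoothstep: 0 at x <= 0, 1 at x >= 1, 3x^2 - 2x^3 between.
smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

## Pairwise Euclidean distance matrix between two coordinate matrices (n x 3).
crossDist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Random proper rotation matrix (uniform via QR of a Gaussian matrix).
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Apply a rigid-body transform (rotation matrix + translation) to an
## n x 3 coordinate matrix.
applyRigid <- function(coords, rot, trans) {
  sweep(coords %*% t(rot), 2, trans, "+")
}

## Least-squares plane normal for >= 3 points; returns a unit 3-vector.
planeNormal <- function(coords) {
  c0 <- sweep(coords, 2, colMeans(coords))
  sv <- svd(c0)
  unitVec(sv$v[, 3])
}

## Maximum deviation of points from their least-squares plane, Angstrom.
planeDeviation <- function(coords) {
  n <- planeNormal(coords)
  c0 <- sweep(coords, 2, colMeans(coords))
  max(abs(c0 %*% n))
}
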