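# Small 3-D geometry helpers shared by the geometry, network and comparison
# stages. All coordinates are in Angstrom unless a function says otherwise.

vecNorm <- function(v) sqrt(sum(v * v))

unitVector <- function(v) {
  n <- vecNorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

## Rodrigues rotation matrix: angle in degrees about a (not necessarily unit)
## axis through the origin.
rotationMatrix <- function(angle_deg, axis = c(0, 0, 1)) {
  u <- unitVector(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## In-plane orthonormal basis (e1, e2) perpendicular to `normal`, right-handed
## about -normal, so that atan2(p.e2, p.e1) increases anticlockwise when the
## plane is viewed from the lumenal (-normal) side. The choice of e1 is
## deterministic but arbitrary; only angle differences are meaningful.
lumenalViewBasis <- function(normal) {
  n <- unitVector(normal)
  ref <- diag(3)[, which.min(abs(n))]
  e1 <- unitVector(ref - sum(ref * n) * n)
  e2 <- crossProduct(-n, e1)
  list(e1 = e1, e2 = e2, normal = n)
}

crossProduct <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Angles (radians, in [0, 2*pi)) of points about an axis through `center`,
## measured in the lumenal-view convention above. `points` is an n x 3 matrix.
lumenalViewAngles <- function(points, normal, center) {
  b <- lumenalViewBasis(normal)
  rel <- sweep(matrix(points, ncol = 3), 2, center)
  a <- atan2(rel %*% b$e2, rel %*% b$e1)
  as.numeric(a %% (2 * pi))
}

## Deterministic 1-D two-means split (Lloyd iterations from the range
## endpoints). Returns the midpoint of the gap between the two clusters.
twoMeansGapSplit <- function(x, max_iter = 100L) {
  stopifnot(length(x) >= 2)
  c1 <- min(x); c2 <- max(x)
  if (c2 - c1 < .Machine$double.eps) return(c1)
  for (i in seq_len(max_iter)) {
    upper <- abs(x - c2) < abs(x - c1)
    if (!any(upper) || all(upper)) break
    n1 <- mean(x[!upper]); n2 <- mean(x[upper])
    if (identical(c(n1, n2), c(c1, c2))) break
    c1 <- n1; c2 <- n2
  }
  upper <- abs(x - c2) < abs(x - c1)
  (max(x[!upper]) + min(x[upper])) / 2
}

## Row-wise euclidean norms of an n x 3 matrix.
rowNorms <- function(m) sqrt(rowSums(m * m))
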