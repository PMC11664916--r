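## Small geometry and determinism helpers shared across modules.

## Run expr with a fixed RNG seed, restoring global RNG state afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

## Rigid transform application: X n x 3, returns X R^T + t.
.applyTransform <- function(X, R, t) {
  X <- as.matrix(X)
  sweep(X %*% t(R), 2L, -as.numeric(t))
}

## Deterministic random rotation via quaternion.
.randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

## Rotation about axis by angle (radians), Rodrigues form.
.axisRotation <- function(axis, angle) {
  u <- .unit(axis)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Least-squares rigid transform (Kabsch) mapping A onto B (both n x 3).
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2L, ca), sweep(B, 2L, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = as.numeric(cb - R %*% ca))
}

## 42 fixed ray directions: icosahedron vertices plus edge midpoints.
.icosaDirections <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  ## edges = vertex pairs at the minimal chord distance
  D2 <- as.matrix(dist(V))^2
  mind <- min(D2[D2 > 1e-9])
  idx <- which(D2 > 1e-9 & D2 < mind + 1e-9 & upper.tri(D2), arr.ind = TRUE)
  M <- (V[idx[, 1], , drop = FALSE] + V[idx[, 2], , drop = FALSE]) / 2
  M <- M / sqrt(rowSums(M^2))
  rbind(V, M)
}

## Pairwise squared distances between rows of A (n x 3) and B (m x 3).
.crossDist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

## For each row of A, index and squared distance of the nearest row of B.
## Ties broken by lowest B index (which.max on logical / max.col "first").
## Chunked so memory stays bounded for large clouds.
.nearestNeighbour <- function(A, B, chunk = 512L) {
  n <- nrow(A)
  idx <- integer(n); d2 <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    M <- .crossDist2(A[s:e, , drop = FALSE], B)
    j <- max.col(-M, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- M[cbind(seq_len(e - s + 1L), j)]
  }
  list(index = idx, dist2 = d2)
}

## Cell-list spatial index: for each query point, does any atom lie closer
## than its per-atom threshold? Returns logical vector "clash-free".
## Identical results to the all-pairs rule by construction; only the
## candidate set is pruned (cell size >= max threshold).
.clashFree <- function(points, atomXYZ, thresholds) {
  if (nrow(atomXYZ) == 0L) return(rep(TRUE, nrow(points)))
  cs <- max(thresholds)
  origin <- apply(rbind(points, atomXYZ), 2L, min)
  acell <- floor(sweep(atomXYZ, 2L, origin) / cs)
  akey <- paste(acell[, 1], acell[, 2], acell[, 3], sep = ",")
  atomIdx <- split(seq_len(nrow(atomXYZ)), akey)
  pcell <- floor(sweep(points, 2L, origin) / cs)
  pkey <- paste(pcell[, 1], pcell[, 2], pcell[, 3], sep = ",")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ok <- rep(TRUE, nrow(points))
  for (k in unique(pkey)) {
    pi <- which(pkey == k)
    base <- pcell[pi[1L], ]
    nb <- sweep(off, 2L, -base)
    nbk <- paste(nb[, 1], nb[, 2], nb[, 3], sep = ",")
    cand <- unlist(atomIdx[nbk], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    D2 <- .crossDist2(points[pi, , drop = FALSE],
                      atomXYZ[cand, , drop = FALSE])
    thr2 <- matrix(thresholds[cand]^2, nrow = length(pi),
                   ncol = length(cand), byrow = TRUE)
    ok[pi] <- !apply(D2 < thr2, 1L, any)
  }
  ok
}
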