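# Independent reference implementations used as oracles. Deliberately
# naive (double loops, direct formula evaluation) and kept free of the
# production code paths they check.

# all-pairs directional overlap: % of a-points with a property-compatible
# b-point within eps after applying (R, t) to a
oracleOverlap <- function(a, b, R, t, eps = 1, useProps = TRUE) {
  A <- pointCoords(a) %*% t(R) + matrix(t, nPoints(a), 3, byrow = TRUE)
  B <- pointCoords(b)
  pa <- pointProps(a); pb <- pointProps(b)
  db <- 0.1 * max(abs(pa$electrostatic), 0)
  nhit <- 0L
  for (i in seq_len(nrow(A))) {
    found <- FALSE
    for (j in seq_len(nrow(B))) {
      if (sum((A[i, ] - B[j, ])^2) > eps^2) next
      if (!useProps) { found <- TRUE; break }
      ea <- pa$electrostatic[i]; eb <- pb$electrostatic[j]
      okSign <- abs(ea) <= db || abs(eb) <= db || sign(ea) == sign(eb)
      if (okSign &&
          abs(pa$hbond_donor[i] - pb$hbond_donor[j]) <= 0.5 &&
          abs(pa$hbond_acceptor[i] - pb$hbond_acceptor[j]) <= 0.5) {
        found <- TRUE; break
      }
    }
    if (found) nhit <- nhit + 1L
  }
  100 * nhit / nrow(A)
}

# direct evaluation of the composite score formula from its definition
oracleScore <- function(a, b, R, t, eps = 1) {
  o12 <- oracleOverlap(a, b, R, t, eps)
  Ri <- t(R); ti <- as.numeric(-Ri %*% t)
  o21 <- oracleOverlap(b, a, Ri, ti, eps)
  sym <- if (o12 + o21 > 0) 2 * o12 * o21 / (o12 + o21) else 0
  A <- pointCoords(a) %*% t(R) + matrix(t, nPoints(a), 3, byrow = TRUE)
  B <- pointCoords(b)
  pa <- pointProps(a); pb <- pointProps(b)
  enorm <- max(max(abs(pa$electrostatic)), 1e-12)
  dsum <- 0; npair <- 0L
  for (i in seq_len(nrow(A))) {
    d2 <- colSums((t(B) - A[i, ])^2)
    j <- which.min(d2)
    if (d2[j] > eps^2) next
    npair <- npair + 1L
    dsum <- dsum +
      mean(c(min(1, abs(pa$electrostatic[i] - pb$electrostatic[j]) / enorm),
             abs(pa$hbond_donor[i] - pb$hbond_donor[j]),
             abs(pa$hbond_acceptor[i] - pb$hbond_acceptor[j]),
             abs(pa$hydrophobicity[i] - pb$hydrophobicity[j]),
             abs(pa$buriedness[i] - pb$buriedness[j])))
  }
  prop <- if (npair == 0L) 1 else dsum / npair
  0.7 * (1 - sym / 100) + 0.3 * prop
}

# electrostatic potential at a point from explicit charge sites,
# evaluated straight from the formula sum q / (4 r^2)
oraclePotential <- function(point, siteXYZ, q, cutoff = 12) {
  s <- 0
  for (k in seq_len(nrow(siteXYZ))) {
    r <- sqrt(sum((point - siteXYZ[k, ])^2))
    if (r <= cutoff) s <- s + q[k] / (4 * r^2)
  }
  s
}

sortRows <- function(M) M[do.call(order, as.data.frame(M)), , drop = FALSE]

# hollow rectangular box fixture: carbon shell on the faces of a cube,
# interior clear span `inner`^3, two-atom ligand at the centre
makeHollowBox <- function(inner = 6, wall = 2.4, spacing = 1.2) {
  h <- inner / 2 + wall
  ax <- seq(-h, h, by = spacing)
  g <- as.matrix(expand.grid(ax, ax, ax))
  onFace <- apply(abs(g), 1, max) > inner / 2 + 0.3
  shell <- g[onFace, , drop = FALSE]
  lig <- rbind(c(-0.7, 0, 0), c(0.7, 0, 0))
  fad <- cbind(-h - 2.5, rbind(c(1.4, 0), c(0.7, 1.212), c(-0.7, 1.212),
                               c(-1.4, 0), c(-0.7, -1.212), c(0.7, -1.212)))
  n <- nrow(shell) + nrow(fad) + nrow(lig)
  df <- data.frame(
    serial = seq_len(n),
    name = c(rep("CA", nrow(shell)),
             c("N5", "C4A", "C5A", "N10", "C9A", "C10"), c("C1", "C2")),
    element = c(rep("C", nrow(shell)),
                c("N", "C", "C", "N", "C", "C"), c("C", "C")),
    resname = c(rep("ALA", nrow(shell)), rep("FAD", 6), rep("OCA", 2)),
    chain = c(rep("A", nrow(shell) + 6), "L", "L"),
    resno = c(seq_len(nrow(shell)), rep(600L, 6), 500L, 500L),
    x = c(shell[, 1], fad[, 1], lig[, 1]),
    y = c(shell[, 2], fad[, 2], lig[, 2]),
    z = c(shell[, 3], fad[, 3], lig[, 3]),
    het = c(rep(FALSE, nrow(shell)), rep(TRUE, 8)),
    occ = 1, stringsAsFactors = FALSE)
  s <- new("ProteinStructure", atoms = df, id = "hollowbox")
  lspec <- LigandSpec("OCA", "L", 500L, "C1", c("C1", "C2"))
  list(structure = s, ligand = lspec,
       frame = locateFlavin(s, ligand = lspec))
}

# minimal MatchResult constructor for filter tests
mkMatch <- function(score, ov12, ov21, id = "t") {
  new("MatchResult", rotation = diag(3), translation = c(0, 0, 0),
      totalScore = score, overlap12 = ov12, overlap21 = ov21,
      flavinSameSide = TRUE, electroOK = TRUE, templateId = "tmpl",
      targetId = id)
}

# fixed-column PDB record line
pdbLine <- function(record, serial, name, alt, resname, chain, resno,
                    x, y, z, occ = 1, elem = "C") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, sprintf(" %-3s", name), alt, resname, chain,
          resno, x, y, z, occ, 0, elem)
}
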