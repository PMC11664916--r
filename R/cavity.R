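## Cavity point-cloud procreation and physico-chemical annotation.
##
## The proprietary platform the field uses publishes neither its point
## placement nor its per-point property definitions; the grid / ramp / ray
## definitions here are this package's own reconstruction with the same
## intent: geometry + electrostatics + H-bonding + hydrophobicity +
## buriedness, computed at virtual points in the empty active-site space.

.VDW <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
          F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
.vdwRadius <- function(element) {
  r <- .VDW[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

## Heavy atoms that occlude space: everything except the ligand residue,
## hydrogens and waters. The cofactor counts as cavity wall.
.occluders <- function(atomDf, lig = NULL) {
  keep <- atomDf$element != "H" &
    !(atomDf$resname %in% c("HOH", "WAT", "DOD"))
  if (!is.null(lig))
    keep <- keep & !(atomDf$resname == lig@resname &
                       atomDf$chain == lig@chain &
                       atomDf$resno == lig@resno)
  atomDf[keep, , drop = FALSE]
}

## Regular grid over the ligand bounding box padded by `pad` on all
## sides, constructed in flavin-frame coordinates (origin at N5, axes
## from the frame basis) so that cavity procreation is equivariant under
## rigid transforms of the structure: the grid travels with the protein
## instead of being pinned to world axes.
.cavityGrid <- function(ligXYZ, spacing, pad, frame) {
  B <- .frameBasis(frame)
  local <- sweep(ligXYZ, 2L, frame@n5) %*% B
  ## snap the origin to the spacing lattice so grids at different
  ## paddings nest (growing the reach only ever adds points); the
  ## half-cell offset keeps grid points off the lattice of the frame
  ## origin, so rays and clash thresholds never sit on exact ties with
  ## the cofactor atoms that define the frame
  lo <- spacing * (floor((apply(local, 2L, min) - pad) / spacing) + 0.5)
  hi <- apply(local, 2L, max) + pad
  ax <- lapply(1:3, function(i)
    lo[i] + spacing * seq(0L, floor((hi[i] - lo[i]) / spacing)))
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  sweep(g %*% t(B), 2L, -frame@n5)
}

## Ray directions for buriedness, rotated into the structure's flavin
## frame (equivariance again).
.frameDirections <- function(frame) .icosaDirections() %*% t(.frameBasis(frame))

## Fraction of the 42 fixed ray directions that hit an occluding atom
## sphere with the projection of the hit within (0, maxDist].
.buriedness <- function(points, atomXYZ, radii, dirs, maxDist = 8) {
  nd <- nrow(dirs)
  if (nrow(atomXYZ) == 0L) return(numeric(nrow(points)))
  r2 <- radii^2
  vapply(seq_len(nrow(points)), function(i) {
    rel <- sweep(atomXYZ, 2L, points[i, ])
    tproj <- rel %*% t(dirs)                 # atoms x directions
    perp2 <- rowSums(rel^2) - tproj^2
    hit <- tproj > 0 & tproj <= maxDist & perp2 <= r2
    sum(colSums(hit) > 0) / nd
  }, numeric(1))
}

## Reference buriedness: per point, per direction, plain arithmetic loop.
.buriednessSlow <- function(points, atomXYZ, radii, dirs, maxDist = 8) {
  if (nrow(atomXYZ) == 0L) return(numeric(nrow(points)))
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    rel <- sweep(atomXYZ, 2L, points[i, ])
    n2 <- rowSums(rel^2)
    nhit <- 0L
    for (d in seq_len(nrow(dirs))) {
      tp <- rel[, 1] * dirs[d, 1] + rel[, 2] * dirs[d, 2] +
        rel[, 3] * dirs[d, 3]
      if (any(tp > 0 & tp <= maxDist & n2 - tp^2 <= radii^2))
        nhit <- nhit + 1L
    }
    out[i] <- nhit / nrow(dirs)
  }
  out
}

#' Procreate the cavity point cloud around the bound ligand
#'
#' Seeds a regular grid over the (truncated) ligand's bounding box padded
#' by `maxLigandDistance` and keeps a grid point iff (a) it clears every
#' occluding heavy atom by that atom's van der Waals radius plus
#' `overlapFactor * probeRadius`, (b) it lies within `maxLigandDistance`
#' of a retained ligand heavy atom, and (c) its buriedness (fraction of 42
#' fixed ray directions hitting protein within 8 Angstrom) reaches
#' `buriednessMin`, which excludes bulk-solvent points. Ligand atoms
#' themselves are treated as empty space. Point placement uses a
#' cell-list spatial index; [bruteForceCavity()] is the all-pairs
#' reference enumeration with identical results.
#'
#' @param s a [ProteinStructure-class] (ligand already truncated as
#'   desired).
#' @param spec the [LigandSpec-class].
#' @param frame the [FlavinFrame-class] from [locateFlavin()].
#' @param gridSpacing grid spacing in Angstrom, in \[0.3, 2\] (default
#'   0.8).
#' @param probeRadius solvent probe radius in Angstrom (default 1.4).
#' @param maxLigandDistance maximum distance from a ligand heavy atom in
#'   Angstrom (default 5).
#' @param buriednessMin minimum buriedness in \[0,1\] (default 0.4; set to
#'   0 to disable the filter).
#' @param overlapFactor fraction of the probe radius added to the atom
#'   vdW radius for the clash rule (default 0.5).
#' @return A [CavityCloud-class] with buriedness filled in and the other
#'   properties zero until [annotateProperties()] is applied.
#' @examples
#' toy <- makeToyEnzyme(seed = 1)
#' fr <- locateFlavin(toy$structure, ligand = toy$ligand)
#' cl <- procreateCavity(toy$structure, toy$ligand, fr)
#' nPoints(cl)
#' @export
procreateCavity <- function(s, spec, frame, gridSpacing = 0.8,
                            probeRadius = 1.4, maxLigandDistance = 5.0,
                            buriednessMin = 0.4, overlapFactor = 0.5) {
  if (missing(frame) || !is(frame, "FlavinFrame"))
    .err("catalocavity_value_error", "a FlavinFrame is required")
  if (gridSpacing < 0.3 || gridSpacing > 2)
    .err("catalocavity_value_error", "gridSpacing must lie in [0.3, 2]")
  a <- atoms(s)
  lig <- .ligandAtoms(a, spec)
  lig <- lig[lig$element != "H", , drop = FALSE]
  if (nrow(lig) == 0L)
    .err("catalocavity_ligand_error",
         sprintf("ligand %s:%s:%d not found in '%s'", spec@resname,
                 spec@chain, spec@resno, s@id))
  occ <- .occluders(a, spec)
  occXYZ <- as.matrix(occ[, c("x", "y", "z")])
  radii <- .vdwRadius(occ$element)
  ligXYZ <- as.matrix(lig[, c("x", "y", "z")])
  grid <- .cavityGrid(ligXYZ, gridSpacing, maxLigandDistance, frame)
  keep <- .clashFree(grid, occXYZ, radii + overlapFactor * probeRadius)
  pts <- grid[keep, , drop = FALSE]
  if (nrow(pts)) {
    d2 <- .crossDist2(pts, ligXYZ)
    nearLig <- apply(d2, 1L, min) <= maxLigandDistance^2
    pts <- pts[nearLig, , drop = FALSE]
  }
  bur <- numeric(0)
  if (nrow(pts)) {
    bur <- .buriedness(pts, occXYZ, radii, .frameDirections(frame))
    if (buriednessMin > 0) {
      keepB <- bur >= buriednessMin
      pts <- pts[keepB, , drop = FALSE]
      bur <- bur[keepB]
    }
  }
  if (nrow(pts) == 0L)
    .err("catalocavity_empty_cavity_error",
         sprintf("no cavity points survive the filters for '%s'", s@id))
  cloud <- CavityCloud(coords = pts, frame = frame,
                       gridSpacing = gridSpacing, sourceId = s@id)
  cloud@props$buriedness <- bur
  cloud
}

#' Brute-force reference enumeration of cavity points
#'
#' All-pairs re-implementation of the [procreateCavity()] keep rules
#' (full distance matrices, per-point ray loop) used as the independent
#' reference for validating the spatial-index implementation. Returns the
#' kept coordinates only.
#'
#' @inheritParams procreateCavity
#' @return n x 3 matrix of kept grid points.
#' @export
bruteForceCavity <- function(s, spec, frame = NULL, gridSpacing = 0.8,
                             probeRadius = 1.4, maxLigandDistance = 5.0,
                             buriednessMin = 0.4, overlapFactor = 0.5) {
  if (is.null(frame)) frame <- locateFlavin(s, ligand = spec)
  a <- atoms(s)
  lig <- .ligandAtoms(a, spec)
  lig <- lig[lig$element != "H", , drop = FALSE]
  occ <- .occluders(a, spec)
  occXYZ <- as.matrix(occ[, c("x", "y", "z")])
  radii <- .vdwRadius(occ$element)
  ligXYZ <- as.matrix(lig[, c("x", "y", "z")])
  grid <- .cavityGrid(ligXYZ, gridSpacing, maxLigandDistance, frame)
  thr <- radii + overlapFactor * probeRadius
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    dx <- occXYZ[, 1] - grid[i, 1]
    dy <- occXYZ[, 2] - grid[i, 2]
    dz <- occXYZ[, 3] - grid[i, 3]
    if (nrow(occXYZ) && any(dx * dx + dy * dy + dz * dz < thr^2)) next
    dl <- sqrt(min((ligXYZ[, 1] - grid[i, 1])^2 +
                     (ligXYZ[, 2] - grid[i, 2])^2 +
                     (ligXYZ[, 3] - grid[i, 3])^2))
    keep[i] <- dl <= maxLigandDistance
  }
  pts <- grid[keep, , drop = FALSE]
  if (buriednessMin > 0 && nrow(pts)) {
    bur <- .buriednessSlow(pts, occXYZ, radii, .frameDirections(frame))
    pts <- pts[bur >= buriednessMin, , drop = FALSE]
  }
  pts
}

## Integer residue-template charges: Arg/Lys +1 on the side-chain N
## centre, Asp/Glu -1 on the carboxylate midpoint. Parameter-free and
## sign-correct, which is all the downstream triage uses.
.chargeSites <- function(atomDf) {
  prot <- atomDf[atomDf$element != "H", , drop = FALSE]
  sites <- list(
    ARG = list(atoms = c("NE", "NH1", "NH2"), q = +1),
    LYS = list(atoms = "NZ", q = +1),
    ASP = list(atoms = c("OD1", "OD2"), q = -1),
    GLU = list(atoms = c("OE1", "OE2"), q = -1))
  out <- list()
  for (rn in names(sites)) {
    sub <- prot[prot$resname == rn & prot$name %in% sites[[rn]]$atoms, ,
                drop = FALSE]
    if (nrow(sub) == 0L) next
    for (key in unique(paste(sub$chain, sub$resno))) {
      g <- sub[paste(sub$chain, sub$resno) == key, , drop = FALSE]
      out[[length(out) + 1L]] <- c(colMeans(as.matrix(g[, c("x", "y", "z")])),
                                   sites[[rn]]$q)
    }
  }
  if (!length(out))
    return(list(xyz = matrix(0, 0, 3), q = numeric(0)))
  M <- do.call(rbind, out)
  list(xyz = M[, 1:3, drop = FALSE], q = M[, 4])
}

.DONOR_SIDE <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                    HIS = c("ND1", "NE2"), ASN = "ND2", GLN = "NE2",
                    TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH")
.ACCEPTOR_SIDE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                       ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
                       SER = "OG", THR = "OG1", TYR = "OH")

.hbAtoms <- function(atomDf, table, backboneName) {
  sel <- (!atomDf$het & atomDf$name == backboneName)
  for (rn in names(table))
    sel <- sel | (atomDf$resname == rn & atomDf$name %in% table[[rn]])
  atomDf[sel & atomDf$element != "H", , drop = FALSE]
}

## Linear H-bond ramp: 1 at <= 2.5 A, 0 at >= 4.0 A.
.hbRamp <- function(d) pmin(pmax((4.0 - d) / 1.5, 0), 1)

#' Annotate cavity points with physico-chemical properties
#'
#' Fills the per-point property vector of a cloud:
#' \describe{
#'   \item{electrostatic}{\eqn{\sum_a q_a / (\epsilon(r) r_a)} over charged
#'     protein sites within `elecCutoff`, with the distance-dependent
#'     dielectric \eqn{\epsilon(r) = 4r}, i.e. \eqn{q/(4r^2)} per site.
#'     Charges are residue-template integers (Arg/Lys +1, Asp/Glu -1).}
#'   \item{hbond_donor / hbond_acceptor}{max over donor / acceptor protein
#'     atoms of a linear distance ramp 1 to 0 between 2.5 and 4.0
#'     Angstrom.}
#'   \item{hydrophobicity}{fraction of occluding heavy atoms within 4.5
#'     Angstrom that are apolar carbons.}
#'   \item{buriedness}{fraction of 42 fixed icosahedral ray directions
#'     hitting an occluding atom within 8 Angstrom.}
#' }
#' Empty neighbourhoods yield zeros.
#'
#' @param cloud a [CavityCloud-class].
#' @param s the source [ProteinStructure-class].
#' @param spec optional [LigandSpec-class]; ligand atoms are excluded from
#'   all property sums when given.
#' @param elecCutoff electrostatic cutoff in Angstrom (default 12).
#' @return The annotated [CavityCloud-class].
#' @export
annotateProperties <- function(cloud, s, spec = NULL, elecCutoff = 12) {
  pts <- pointCoords(cloud)
  a <- atoms(s)
  occ <- .occluders(a, spec)
  occXYZ <- as.matrix(occ[, c("x", "y", "z")])
  props <- cloud@props

  ch <- .chargeSites(occ)
  if (length(ch$q)) {
    d2 <- .crossDist2(pts, ch$xyz)
    contrib <- sweep(1 / (4 * pmax(d2, 1e-12)), 2L, ch$q, "*")
    contrib[d2 > elecCutoff^2] <- 0
    props$electrostatic <- rowSums(contrib)
  } else props$electrostatic <- numeric(nrow(pts))

  for (kind in c("hbond_donor", "hbond_acceptor")) {
    tab <- if (kind == "hbond_donor") .DONOR_SIDE else .ACCEPTOR_SIDE
    bb <- if (kind == "hbond_donor") "N" else "O"
    hb <- .hbAtoms(occ, tab, bb)
    props[[kind]] <- if (nrow(hb) == 0L) numeric(nrow(pts)) else {
      d <- sqrt(.crossDist2(pts, as.matrix(hb[, c("x", "y", "z")])))
      apply(.hbRamp(d), 1L, max)
    }
  }

  if (nrow(occXYZ)) {
    d2 <- .crossDist2(pts, occXYZ)
    near <- d2 <= 4.5^2
    apolar <- occ$element == "C" & occ$name != "C"
    cnt <- rowSums(near)
    hyd <- rowSums(near & matrix(apolar, nrow(pts), nrow(occXYZ),
                                 byrow = TRUE))
    props$hydrophobicity <- ifelse(cnt > 0, hyd / cnt, 0)
    props$buriedness <- .buriedness(pts, occXYZ, .vdwRadius(occ$element),
                                    .frameDirections(cloud@frame))
  } else {
    props$hydrophobicity <- numeric(nrow(pts))
    props$buriedness <- numeric(nrow(pts))
  }
  cloud@props <- props
  validObject(cloud)
  cloud
}

#' Does the cloud near the flavin N5 stabilise a negative charge?
#'
#' A cavity suited to carboxylate photodecarboxylation should present a
#' positive electrostatic environment next to the flavin, where the
#' substrate carboxylate binds. Returns `TRUE` iff the mean electrostatic
#' value over cloud points within `radius` of the frame's N5 is strictly
#' positive, `FALSE` if not, and `NA` (inconclusive) if no points lie
#' within `radius`.
#'
#' @param cloud an annotated [CavityCloud-class].
#' @param radius neighbourhood radius around N5 in Angstrom (default 4).
#' @return logical(1), possibly `NA`.
#' @export
negativeChargeStabilization <- function(cloud, radius = 4.0) {
  pts <- pointCoords(cloud)
  d2 <- .crossDist2(pts, matrix(cloud@frame@n5, 1L, 3L))[, 1L]
  sel <- d2 <= radius^2
  if (!any(sel)) return(NA)
  mean(cloud@props$electrostatic[sel]) > 0
}

#' Apply a rigid transform to a cavity cloud
#'
#' Transforms point coordinates and the anchor frame; properties are
#' carried along unchanged.
#'
#' @param cloud a [CavityCloud-class].
#' @param R 3 x 3 rotation matrix.
#' @param t numeric(3) translation.
#' @return The transformed [CavityCloud-class].
#' @export
transformCloud <- function(cloud, R = diag(3), t = c(0, 0, 0)) {
  fr <- cloud@frame
  cloud@coords <- .applyTransform(cloud@coords, R, t)
  cloud@frame <- FlavinFrame(
    n5 = as.numeric(R %*% fr@n5 + t),
    ringCentroid = as.numeric(R %*% fr@ringCentroid + t),
    ringNormal = as.numeric(R %*% fr@ringNormal))
  cloud
}
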