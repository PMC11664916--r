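## Rigid cloud-vs-cloud registration, the total-score / overlap filters
## and the two automated triage checks.
##
## The published thresholds (total score < 0.05, overlaps > 70% / > 10%,
## 30% for larger pools) come with no score formula; the composite score
## implemented here is a documented reconstruction on [0,1] calibrated so
## that a self-match scores 0 and fully disjoint clouds score 1, which
## preserves the "lower is better" ordering the filters rely on.

## Orthonormal basis of a flavin frame: z = ring normal, x = in-plane
## projection of (centroid -> N5), y = z x x. The centroid->N5 direction
## fixes the in-plane orientation the ring's N10->N5 axis would fix.
.frameBasis <- function(frame) {
  z <- .unit(frame@ringNormal)
  v <- frame@n5 - frame@ringCentroid
  v <- v - z * sum(v * z)
  if (sqrt(sum(v^2)) < 1e-9) {
    ## degenerate (N5 on the normal axis): deterministic fallback
    v <- c(1, 0, 0) - z * z[1]
    if (sqrt(sum(v^2)) < 1e-9) v <- c(0, 1, 0) - z * z[2]
  }
  x <- .unit(v)
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

.elecDeadBand <- function(cloud) 0.1 * max(abs(cloud@props$electrostatic), 0)

## Property compatibility between matched points: same electrostatic sign
## (values inside the dead-band are wildcards) and donor/acceptor scores
## within 0.5.
.propCompatible <- function(pa, ia, pb, ib, deadBand) {
  ea <- pa$electrostatic[ia]; eb <- pb$electrostatic[ib]
  signOK <- abs(ea) <= deadBand | abs(eb) <= deadBand |
    (sign(ea) == sign(eb))
  signOK &
    abs(pa$hbond_donor[ia] - pb$hbond_donor[ib]) <= 0.5 &
    abs(pa$hbond_acceptor[ia] - pb$hbond_acceptor[ib]) <= 0.5
}

#' Directional overlap between two clouds under a transform
#'
#' Percentage of `a`'s points that have at least one `b`-point within
#' `epsilon` Angstrom (after mapping `a` into `b`'s frame with the given
#' transform) that is also property-compatible: same electrostatic sign
#' (|value| below the dead-band, 10% of `a`'s maximum |electrostatic|, is
#' treated as wildcard) and donor/acceptor scores within 0.5. Set
#' `useProperties = FALSE` for purely geometric overlap.
#'
#' @param a,b [CavityCloud-class] objects (`a` is the moving cloud).
#' @param R,t rigid transform mapping `a` coordinates into `b`'s frame.
#' @param epsilon match radius in Angstrom (> 0; default 1).
#' @param useProperties include property compatibility (default `TRUE`).
#' @return Percentage in \[0, 100\].
#' @export
overlapFraction <- function(a, b, R = diag(3), t = c(0, 0, 0),
                            epsilon = 1.0, useProperties = TRUE) {
  if (epsilon <= 0)
    .err("catalocavity_value_error", "epsilon must be > 0")
  A <- .applyTransform(pointCoords(a), R, t)
  B <- pointCoords(b)
  if (nrow(A) == 0L) return(0)
  if (nrow(B) == 0L) return(0)
  d2 <- .crossDist2(A, B)
  within <- d2 <= epsilon^2
  if (useProperties) {
    db <- .elecDeadBand(a)
    hit <- vapply(seq_len(nrow(A)), function(i) {
      j <- which(within[i, ])
      length(j) > 0 &&
        any(.propCompatible(a@props, rep(i, length(j)), b@props, j, db))
    }, logical(1))
  } else hit <- rowSums(within) > 0
  100 * sum(hit) / nrow(A)
}

## Mean normalised property distance over geometrically matched pairs:
## for each a-point, the nearest b-point within epsilon; per-pair distance
## is the mean of |delta| over the four bounded properties plus the
## electrostatic |delta| normalised by a's maximum |value| and capped at
## 1. No matched pairs -> 1 (maximal mismatch).
.propDistance <- function(a, b, R, t, epsilon) {
  A <- .applyTransform(pointCoords(a), R, t)
  B <- pointCoords(b)
  nn <- .nearestNeighbour(A, B)
  sel <- nn$dist2 <= epsilon^2
  if (!any(sel)) return(1)
  ia <- which(sel); ib <- nn$index[sel]
  pa <- a@props; pb <- b@props
  enorm <- max(max(abs(pa$electrostatic)), 1e-12)
  de <- pmin(1, abs(pa$electrostatic[ia] - pb$electrostatic[ib]) / enorm)
  dd <- abs(pa$hbond_donor[ia] - pb$hbond_donor[ib])
  da <- abs(pa$hbond_acceptor[ia] - pb$hbond_acceptor[ib])
  dh <- abs(pa$hydrophobicity[ia] - pb$hydrophobicity[ib])
  db <- abs(pa$buriedness[ia] - pb$buriedness[ib])
  mean((de + dd + da + dh + db) / 5)
}

#' Total score of a cloud match (lower = better)
#'
#' Composite dissimilarity in \[0,1\]:
#' `0.7 * (1 - symOverlap/100) + 0.3 * propDistance`, where `symOverlap`
#' is the harmonic mean of the two directional overlaps and
#' `propDistance` is the mean normalised property distance over matched
#' pairs (1 when nothing matches). Identical clouds score 0; fully
#' disjoint clouds score 1.
#'
#' @inheritParams overlapFraction
#' @return numeric(1) in \[0,1\].
#' @export
totalScore <- function(a, b, R = diag(3), t = c(0, 0, 0), epsilon = 1.0) {
  o12 <- overlapFraction(a, b, R, t, epsilon)
  Rinv <- t(R); tinv <- as.numeric(-Rinv %*% t)
  o21 <- overlapFraction(b, a, Rinv, tinv, epsilon)
  sym <- if (o12 + o21 > 0) 2 * o12 * o21 / (o12 + o21) else 0
  0.7 * (1 - sym / 100) + 0.3 * .propDistance(a, b, R, t, epsilon)
}

#' Is the flavin on the same side of the matched point cloud?
#'
#' Automated version of the visual triage that rejects matching scenes in
#' which the point clouds align but the cofactors point in opposite
#' directions. After mapping the template (cloud and frame) into the
#' target's frame, returns `TRUE` iff (a) the angle between the two ring
#' normals is below 90 degrees and (b) the target N5 lies on the same
#' side of the template cloud's centroid plane (normal = template ring
#' normal) as the template N5.
#'
#' @param template,target [CavityCloud-class] objects with frames.
#' @param R,t rigid transform mapping the template into the target frame.
#' @return logical(1).
#' @export
flavinSameSide <- function(template, target, R = diag(3), t = c(0, 0, 0)) {
  tm <- transformCloud(template, R, t)
  n <- tm@frame@ringNormal
  if (sum(n * target@frame@ringNormal) <= 0) return(FALSE)
  ctr <- colMeans(pointCoords(tm))
  sTemplate <- sum((tm@frame@n5 - ctr) * n)
  sTarget <- sum((target@frame@n5 - ctr) * n)
  sTemplate * sTarget > 0
}

#' Rigidly align a template cloud onto a target cloud
#'
#' Initialises the transform by superposing the two flavin frames (N5 on
#' N5, ring normal on ring normal, in-plane orientation by the
#' centroid-to-N5 axis), then refines it by ICP: nearest-neighbour pairs
#' within `2 * epsilon`, least-squares rigid update (Kabsch), up to
#' `maxIter` iterations or until the score improves by less than `tol`.
#' The returned transform is the one minimising [totalScore()] along the
#' refinement trajectory. If no point pairs lie within `2 * epsilon`
#' after frame superposition, the worst-case result (overlaps 0, total
#' score 1) is returned rather than an error.
#'
#' @param template,target annotated [CavityCloud-class] objects.
#' @param epsilon match radius in Angstrom (default 1).
#' @param maxIter maximum ICP iterations (default 50).
#' @param tol score-improvement convergence tolerance (default 1e-6).
#' @return A [MatchResult-class] (triage flags filled in).
#' @examples
#' p <- makeCloudPair(seed = 1, nPoints = 50, overlapTarget = 100)
#' alignClouds(p$cloudA, p$cloudB)
#' @export
alignClouds <- function(template, target, epsilon = 1.0, maxIter = 50L,
                        tol = 1e-6) {
  if (nPoints(template) == 0L || nPoints(target) == 0L)
    .err("catalocavity_value_error", "clouds must be non-empty")
  Bs <- .frameBasis(template@frame)
  Bt <- .frameBasis(target@frame)
  R <- Bt %*% t(Bs)
  t <- as.numeric(target@frame@n5 - R %*% template@frame@n5)
  A0 <- pointCoords(template)
  B <- pointCoords(target)

  nn0 <- .nearestNeighbour(.applyTransform(A0, R, t), B)
  if (!any(nn0$dist2 <= (2 * epsilon)^2)) {
    res <- new("MatchResult", rotation = R, translation = t,
               totalScore = 1, overlap12 = 0, overlap21 = 0,
               flavinSameSide = flavinSameSide(template, target, R, t),
               electroOK = NA, templateId = template@sourceId,
               targetId = target@sourceId)
    return(res)
  }

  best <- list(R = R, t = t, score = totalScore(template, target, R, t,
                                                epsilon))
  prev <- best$score
  for (it in seq_len(maxIter)) {
    A <- .applyTransform(A0, R, t)
    nn <- .nearestNeighbour(A, B)
    sel <- nn$dist2 <= (2 * epsilon)^2
    if (sum(sel) < 3L) break
    upd <- .kabsch(A0[sel, , drop = FALSE],
                   B[nn$index[sel], , drop = FALSE])
    R <- upd$R; t <- upd$t
    sc <- totalScore(template, target, R, t, epsilon)
    if (sc < best$score) best <- list(R = R, t = t, score = sc)
    if (abs(prev - sc) < tol) break
    prev <- sc
  }
  R <- best$R; t <- best$t
  o12 <- overlapFraction(template, target, R, t, epsilon)
  Rinv <- base::t(R); tinv <- as.numeric(-Rinv %*% t)
  o21 <- overlapFraction(target, template, Rinv, tinv, epsilon)
  new("MatchResult", rotation = R, translation = t,
      totalScore = best$score, overlap12 = o12, overlap21 = o21,
      flavinSameSide = flavinSameSide(template, target, R, t),
      electroOK = negativeChargeStabilization(target),
      templateId = template@sourceId, targetId = target@sourceId)
}

#' Filter match results by the published thresholds
#'
#' Keeps results with `totalScore < scoreMax` AND `overlap12 > ov12Min`
#' AND `overlap21 > ov21Min` (or `strictOv21` for larger candidate
#' pools), all strict inequalities, preserving input order. The triage
#' flags (`flavinSameSide`, `electroOK`) annotate but never remove a
#' result, mirroring a visual-inspection step.
#'
#' @param results list of [MatchResult-class] objects.
#' @param scoreMax total-score gate (default 0.05).
#' @param ov12Min template-in-target overlap gate in percent (default 70).
#' @param ov21Min target-in-template overlap gate (default 10).
#' @param strictOv21 stricter reverse-overlap gate for larger pools
#'   (default 30).
#' @param largePool use `strictOv21` instead of `ov21Min` (default
#'   `FALSE`; pools above ~100 targets are the intended trigger).
#' @return The kept subset of `results`, same order.
#' @export
filterMatches <- function(results, scoreMax = 0.05, ov12Min = 70,
                          ov21Min = 10, strictOv21 = 30,
                          largePool = FALSE) {
  gate21 <- if (isTRUE(largePool)) strictOv21 else ov21Min
  keep <- vapply(results, function(r)
    r@totalScore < scoreMax && r@overlap12 > ov12Min &&
      r@overlap21 > gate21, logical(1))
  results[keep]
}

#' Tabulate match results
#'
#' @param results list of [MatchResult-class] objects.
#' @param kept optional list of kept results (e.g. from
#'   [filterMatches()]) used to fill the `kept` column.
#' @return data.frame with one row per result: template_id, target_id,
#'   total_score, overlap_1to2, overlap_2to1, flavin_same_side,
#'   electro_ok, kept.
#' @export
matchTable <- function(results, kept = NULL) {
  keptIds <- if (is.null(kept)) character(0) else
    vapply(kept, function(r) paste(r@templateId, r@targetId), "")
  do.call(rbind, lapply(results, function(r) data.frame(
    template_id = r@templateId, target_id = r@targetId,
    total_score = r@totalScore, overlap_1to2 = r@overlap12,
    overlap_2to1 = r@overlap21, flavin_same_side = r@flavinSameSide,
    electro_ok = r@electroOK,
    kept = paste(r@templateId, r@targetId) %in% keptIds,
    stringsAsFactors = FALSE)))
}
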