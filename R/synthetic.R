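## Deterministic generators emulating every input the funnel consumes,
## with planted ground truth recorded in a manifest. Same seed, same
## output; all randomness goes through one seeded RNG scope that
## restores global RNG state on exit.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
           "F","P","S","T","W","Y","V")

#' Toy enzyme structure with a buried tunnel cavity, flavin and fatty acid
#'
#' Emulates the geometry the cavity stage operates on: a cylindrical
#' shell of apolar carbon pseudo-residues forming a buried tunnel, a
#' linear fatty-acid ligand threaded along the axis, a planar six-atom
#' flavin mimic (atoms named N5, N10, C4A, C5A, C9A, C10) at the tunnel
#' head with its ring normal facing the substrate, and optionally a
#' charged side-chain mimic (arginine +1 or aspartate -1) near N5. The
#' manifest records exact atom counts and the cavity point count obtained
#' by the brute-force reference enumeration at default cavity parameters.
#'
#' @param seed integer seed; same seed, same structure.
#' @param nShellAtoms approximate number of shell atoms (default 300).
#' @param tunnelLength tunnel length in Angstrom (>= 6; default 14).
#' @param tunnelRadius shell radius in Angstrom (default 4; must exceed
#'   the clash clearance, else a value error).
#' @param ligandCarbons chain length of the fatty-acid ligand (default 8,
#'   i.e. octanoic acid).
#' @param argNearN5 place an arginine-like +1 site near N5 (default
#'   `TRUE`).
#' @param aspNearN5 place an aspartate-like -1 site near N5 instead
#'   (default `FALSE`; overrides `argNearN5`).
#' @param flavinAtEnd place the flavin at the far tunnel end (normal
#'   pointing back along the tunnel), for opposite-side scenes (default
#'   `FALSE`).
#' @param pose optional list(R, t) rigid transform applied to all
#'   coordinates.
#' @param id structure id.
#' @param path optional path; when given the structure is also written as
#'   a PDB file.
#' @return list with `structure` ([ProteinStructure-class]), `ligand`
#'   ([LigandSpec-class]), `frame` ([FlavinFrame-class]) and `manifest`
#'   (atom counts, brute-force cavity point count, seed).
#' @export
makeToyEnzyme <- function(seed, nShellAtoms = 300L, tunnelLength = 14,
                          tunnelRadius = 4, ligandCarbons = 8L,
                          argNearN5 = TRUE, aspNearN5 = FALSE,
                          flavinAtEnd = FALSE, pose = NULL,
                          id = sprintf("toy%d", seed), path = NULL) {
  if (tunnelLength < 6)
    .err("catalocavity_value_error", "tunnelLength must be >= 6 Angstrom")
  if (tunnelRadius - 2.4 < 0.4)
    .err("catalocavity_value_error",
         "tunnel narrower than the ligand clearance; widen tunnelRadius")
  ligandCarbons <- as.integer(ligandCarbons)
  if (ligandCarbons < 2L)
    .err("catalocavity_value_error", "ligandCarbons must be >= 2")
  .withSeed(seed, {
    cstep <- 1.5
    cx <- 1.5 + cstep * (seq_len(ligandCarbons) - 1)
    ligXYZ <- cbind(cx, 0, 0)
    ligNames <- paste0("C", seq_len(ligandCarbons))
    ligXYZ <- rbind(ligXYZ,
                    c(cx[1] - 0.4, 1.15, 0), c(cx[1] - 0.4, -1.15, 0))
    ligNames <- c(ligNames, "O1", "O2")
    ligElem <- c(rep("C", ligandCarbons), "O", "O")

    xa <- -2.0
    xb <- max(tunnelLength, max(cx) + 1.0) + 1.0
    m <- max(10L, round(2 * pi * tunnelRadius / 1.2))
    nCapRing <- sum(2 * pi * seq(1.3, tunnelRadius - 0.1, by = 1.3) / 1.2)
    dx <- (xb - xa) * m / max(60, nShellAtoms - 2 * (nCapRing + 1))
    dx <- max(0.8, min(1.6, dx))
    shell <- list()
    for (x0 in seq(xa, xb, by = dx)) {
      ang <- 2 * pi * (seq_len(m) - 1) / m
      shell[[length(shell) + 1L]] <-
        cbind(x0, tunnelRadius * cos(ang), tunnelRadius * sin(ang))
    }
    ## end caps: concentric rings of atoms closing both tunnel mouths,
    ## leaving a small opening at the flavin-facing head
    cap <- function(x0, rmax, rmin = 0) {
      radii <- seq(max(rmin, 0.01), rmax - 0.1, by = 1.3)
      do.call(rbind, lapply(radii, function(r) {
        mm <- max(6L, round(2 * pi * r / 1.2))
        ang <- 2 * pi * (seq_len(mm) - 1) / mm
        cbind(x0, r * cos(ang), r * sin(ang))
      }))
    }
    headX <- if (flavinAtEnd) xb + 1.2 else xa - 1.2
    tailX <- if (flavinAtEnd) xa - 1.2 else xb + 1.2
    shell[[length(shell) + 1L]] <- cap(tailX, tunnelRadius)
    shell[[length(shell) + 1L]] <- cap(headX, tunnelRadius, rmin = 2.6)
    shellXYZ <- do.call(rbind, shell)
    shellXYZ <- shellXYZ + matrix(runif(3 * nrow(shellXYZ), -0.15, 0.15),
                                  ncol = 3)

    ## flavin mimic: hexagon of radius 1.4 in a plane perpendicular to
    ## the tunnel axis, ring normal facing the ligand carboxyl carbon.
    ## The axial offset is deliberately incommensurate with the cavity
    ## grid spacing (N5 anchors the grid), so no atom sits exactly on a
    ## ray-length or clash boundary of the lattice.
    fadX <- if (flavinAtEnd) xb + 2.83 else xa - 2.83
    hex <- rbind(N5 = c(0, 1.4, 0), C4A = c(0, 0.7, 1.212),
                 C5A = c(0, -0.7, 1.212), N10 = c(0, -1.4, 0),
                 C9A = c(0, -0.7, -1.212), C10 = c(0, 0.7, -1.212))
    fadXYZ <- cbind(fadX, hex[, 2], hex[, 3])
    fadNames <- rownames(hex)
    fadElem <- ifelse(substr(fadNames, 1, 1) == "N", "N", "C")

    siteXYZ <- NULL; siteNames <- NULL; siteElem <- NULL
    siteRes <- NULL
    n5guess <- c(fadX, 1.4, 0)
    if (isTRUE(aspNearN5)) {
      sx <- if (flavinAtEnd) fadX - 1.5 else fadX + 1.5
      siteXYZ <- rbind(c(sx, 3.4, 0.6), c(sx, 3.4, -0.6))
      siteNames <- c("OD1", "OD2"); siteElem <- c("O", "O")
      siteRes <- "ASP"
    } else if (isTRUE(argNearN5)) {
      sx <- if (flavinAtEnd) fadX - 1.5 else fadX + 1.5
      siteXYZ <- rbind(c(sx, 3.5, 0))
      siteNames <- "NH1"; siteElem <- "N"
      siteRes <- "ARG"
    }

    nShell <- nrow(shellXYZ)
    df <- data.frame(
      serial = seq_len(nShell + nrow(fadXYZ) + nrow(ligXYZ) +
                         if (is.null(siteXYZ)) 0L else nrow(siteXYZ)),
      name = c(rep("CA", nShell), fadNames, ligNames,
               if (is.null(siteXYZ)) character(0) else siteNames),
      element = c(rep("C", nShell), fadElem, ligElem,
                  if (is.null(siteXYZ)) character(0) else siteElem),
      resname = c(rep("ALA", nShell), rep("FAD", nrow(fadXYZ)),
                  rep("OCA", nrow(ligXYZ)),
                  if (is.null(siteXYZ)) character(0)
                  else rep(siteRes, nrow(siteXYZ))),
      chain = c(rep("A", nShell + nrow(fadXYZ)), rep("L", nrow(ligXYZ)),
                if (is.null(siteXYZ)) character(0)
                else rep("A", nrow(siteXYZ))),
      resno = c(seq_len(nShell), rep(600L, nrow(fadXYZ)),
                rep(500L, nrow(ligXYZ)),
                if (is.null(siteXYZ)) integer(0)
                else rep(601L, nrow(siteXYZ))),
      het = c(rep(FALSE, nShell), rep(TRUE, nrow(fadXYZ)),
              rep(TRUE, nrow(ligXYZ)),
              if (is.null(siteXYZ)) logical(0)
              else rep(FALSE, nrow(siteXYZ))),
      occ = 1, stringsAsFactors = FALSE)
    xyz <- rbind(shellXYZ, fadXYZ, ligXYZ,
                 if (is.null(siteXYZ)) NULL else siteXYZ)
    if (!is.null(pose)) xyz <- .applyTransform(xyz, pose$R, pose$t)
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df <- df[, .ATOM_COLS]
    s <- new("ProteinStructure", atoms = df, id = id)
    lig <- LigandSpec(resname = "OCA", chain = "L", resno = 500L,
                      carboxylCarbon = "C1",
                      chainCarbons = paste0("C", seq_len(ligandCarbons)))
    frame <- locateFlavin(s, "FAD", ligand = lig)
    manifest <- list(
      seed = seed, id = id,
      description = "cylindrical tunnel shell + flavin mimic + fatty acid",
      nAtoms = nrow(df), nShellAtoms = nShell,
      nLigandAtoms = nrow(ligXYZ), nFlavinAtoms = nrow(fadXYZ),
      chargedSite = if (is.null(siteRes)) "none" else siteRes,
      bruteCavityCount = nrow(bruteForceCavity(s, lig)))
    if (!is.null(path)) writeStructure(s, path)
    list(structure = s, ligand = lig, frame = frame, manifest = manifest)
  })
}

#' Cloud pair related by a known rigid transform, with planted overlap
#'
#' Cloud A is sampled with a minimum point separation of `2.2 * epsilon`;
#' cloud B is the known transform applied to a subset of A (its size set
#' by `overlapTarget`) plus decoy points at least `2 * epsilon` away from
#' every transformed A point. The directional overlaps are therefore
#' exact by construction and recorded in the manifest, along with the
#' transform.
#'
#' @param seed integer seed.
#' @param nPoints points in A (and total points in B; default 200).
#' @param overlapTarget planted A-in-B overlap percentage (default 100).
#' @param rotation,translation the rigid transform (defaults: random
#'   rotation, random translation in \[-10, 10\]^3).
#' @param epsilon the match radius the construction is exact for
#'   (default 1).
#' @return list with `cloudA`, `cloudB` ([CavityCloud-class]) and
#'   `manifest` (`rotation`, `translation`, `overlapAB`, `overlapBA`,
#'   `mappedA`, `mappedB`: index bookkeeping of the planted
#'   correspondence).
#' @export
makeCloudPair <- function(seed, nPoints = 200L, overlapTarget = 100,
                          rotation = NULL, translation = NULL,
                          epsilon = 1.0) {
  if (overlapTarget < 0 || overlapTarget > 100)
    .err("catalocavity_value_error", "overlapTarget must lie in [0, 100]")
  .withSeed(seed, {
    nPoints <- as.integer(nPoints)
    minSep <- 2.2 * epsilon
    L <- max(10, minSep * ceiling(nPoints^(1 / 3)) * 2.0)
    sampleSep <- function(n, avoid = NULL, sep = minSep) {
      acc <- matrix(numeric(0), 0, 3)
      guard <- 0L
      while (nrow(acc) < n) {
        guard <- guard + 1L
        if (guard > 200000L)
          .err("catalocavity_value_error",
               "could not place points at the required separation")
        p <- matrix(runif(3, 0, L), 1, 3)
        if (nrow(acc) && min(.crossDist2(p, acc)) < sep^2) next
        if (!is.null(avoid) && nrow(avoid) &&
            min(.crossDist2(p, avoid)) < sep^2) next
        acc <- rbind(acc, p)
      }
      acc
    }
    A <- sampleSep(nPoints)
    propsA <- data.frame(electrostatic = rnorm(nPoints),
                         hbond_donor = runif(nPoints),
                         hbond_acceptor = runif(nPoints),
                         hydrophobicity = runif(nPoints),
                         buriedness = runif(nPoints))
    ctr <- colMeans(A)
    frameA <- FlavinFrame(n5 = ctr + 1.5 * .unit(rnorm(3)),
                          ringCentroid = ctr, ringNormal = .unit(rnorm(3)))
    R <- if (is.null(rotation)) .randomRotation() else rotation
    t <- if (is.null(translation)) runif(3, -10, 10) else translation
    nSub <- round(overlapTarget / 100 * nPoints)
    mappedA <- if (nSub > 0) sort(sample.int(nPoints, nSub)) else integer(0)
    Amap <- .applyTransform(A, R, t)
    Bmapped <- Amap[mappedA, , drop = FALSE]
    nDecoy <- nPoints - nSub
    Bdecoy <- if (nDecoy > 0) {
      ## decoys: >= 2 eps from every A point, then carried through the
      ## same transform (rigid, so the separation is preserved and
      ## neither direction ever picks a decoy up)
      dec <- sampleSep(nDecoy, avoid = A, sep = 2 * epsilon)
      .applyTransform(dec, R, t)
    } else matrix(numeric(0), 0, 3)
    B <- rbind(Bmapped, Bdecoy)
    propsB <- rbind(propsA[mappedA, , drop = FALSE],
                    data.frame(electrostatic = rnorm(nDecoy),
                               hbond_donor = runif(nDecoy),
                               hbond_acceptor = runif(nDecoy),
                               hydrophobicity = runif(nDecoy),
                               buriedness = runif(nDecoy)))
    ord <- sample.int(nrow(B))
    B <- B[ord, , drop = FALSE]
    propsB <- propsB[ord, , drop = FALSE]
    rownames(propsB) <- NULL
    mappedB <- match(seq_len(nSub), ord)
    frameB <- FlavinFrame(
      n5 = as.numeric(R %*% frameA@n5 + t),
      ringCentroid = as.numeric(R %*% frameA@ringCentroid + t),
      ringNormal = as.numeric(R %*% frameA@ringNormal))
    cloudA <- CavityCloud(A, propsA, frameA, gridSpacing = 1,
                          sourceId = sprintf("pairA_%d", seed))
    cloudB <- CavityCloud(B, propsB, frameB, gridSpacing = 1,
                          sourceId = sprintf("pairB_%d", seed))
    list(cloudA = cloudA, cloudB = cloudB,
         manifest = list(seed = seed, rotation = R, translation = t,
                         epsilon = epsilon,
                         overlapAB = 100 * nSub / nPoints,
                         overlapBA = 100 * nSub / nrow(B),
                         mappedA = mappedA, mappedB = mappedB))
  })
}

#' BLAST hit table with planted pass/fail structure
#'
#' Generates an outfmt-6-style 14-column table (with qcovs/scovs) in
#' which exactly `nPass` rows satisfy the identity/coverage rule
#' (`minIdentity`/`minCov` bidirectional); every other row violates at
#' least one threshold by a clear margin. Row order is shuffled.
#'
#' @param seed integer seed.
#' @param nHits total rows (default 50).
#' @param nPass planted passing rows (default 23; must be <= nHits).
#' @param minIdentity,minCov the thresholds the plant is built around
#'   (defaults 30 / 80).
#' @param query query id (default "REF").
#' @param subjects optional subject ids (length `nHits`).
#' @param path optional path to also write the table as TSV (no header).
#' @return list with `hits` (data.frame in [readBlastTable()] layout)
#'   and `manifest` (`passIds`, logical `pass` in row order).
#' @export
makeBlastTable <- function(seed, nHits = 50L, nPass = 23L,
                           minIdentity = 30, minCov = 80, query = "REF",
                           subjects = NULL, path = NULL) {
  if (nPass > nHits)
    .err("catalocavity_value_error", "nPass must be <= nHits")
  .withSeed(seed, {
    if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(nHits))
    pass <- c(rep(TRUE, nPass), rep(FALSE, nHits - nPass))
    pident <- numeric(nHits); qcov <- numeric(nHits); scov <- numeric(nHits)
    for (i in seq_len(nHits)) {
      if (pass[i]) {
        pident[i] <- runif(1, minIdentity + 0.5, 95)
        qcov[i] <- runif(1, minCov + 0.5, 100)
        scov[i] <- runif(1, minCov + 0.5, 100)
      } else {
        mode <- sample(c("id", "qcov", "scov", "all"), 1)
        pident[i] <- if (mode %in% c("id", "all"))
          runif(1, 5, minIdentity - 0.5) else runif(1, minIdentity + 0.5, 95)
        qcov[i] <- if (mode %in% c("qcov", "all"))
          runif(1, 10, minCov - 0.5) else runif(1, minCov + 0.5, 100)
        scov[i] <- if (mode %in% c("scov", "all"))
          runif(1, 10, minCov - 0.5) else runif(1, minCov + 0.5, 100)
      }
    }
    len <- sample(150:600, nHits, replace = TRUE)
    hits <- data.frame(
      query_id = query, subject_id = subjects,
      pct_identity = round(pident, 1), align_length = len,
      mismatches = round(len * (1 - pident / 100)),
      gap_opens = sample(0:5, nHits, replace = TRUE),
      qstart = 1L, qend = len, sstart = 1L, send = len,
      evalue = signif(10^runif(nHits, -150, -3), 3),
      bitscore = round(runif(nHits, 50, 900), 1),
      qcov = round(qcov, 1), scov = round(scov, 1),
      stringsAsFactors = FALSE)
    ord <- sample.int(nHits)
    hits <- hits[ord, , drop = FALSE]
    pass <- pass[ord]
    rownames(hits) <- NULL
    if (!is.null(path))
      utils::write.table(hits, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    list(hits = hits, manifest = list(seed = seed, pass = pass,
                                      passIds = hits$subject_id[pass]))
  })
}

#' Sequence families with planted cluster structure and conserved residues
#'
#' Builds `nFamilies` families by point-mutating unrelated family seeds,
#' which are themselves heavy mutants of one common reference. Windows of
#' +/- 10 residues around the conserved positions (reference arginine
#' `refPos`, plus cysteine 432 and tyrosine 466 by default) are never
#' mutated, so global alignments stay anchored there and the
#' residue-position mapping is exact; the only change ever made inside a
#' window is the planted arginine-to-lysine substitution itself. Within a
#' family, members differ by ~3% substitutions (pairwise identity >= ~94%);
#' between families identity stays below ~40%.
#'
#' @param seed integer seed.
#' @param nFamilies,membersPerFamily family layout (default 5 x 10).
#' @param refLength reference length (default 520; must exceed all
#'   conserved positions).
#' @param argConservedFraction fraction of members keeping the arginine
#'   (default 1); the exact member subset is drawn deterministically.
#' @param argDropIds optional explicit member ids that lose the arginine
#'   (overrides `argConservedFraction`).
#' @param refPos conserved arginine position (default 451).
#' @param triadPos further conserved positions given residues C and Y
#'   (default `c(432, 466)`).
#' @param fastaPath,referencePath optional output FASTA paths.
#' @return list with `sequences` (named character), `reference` (named
#'   character(1), id "REF"), and `manifest` (`family` and
#'   `argConserved` named by member id, `representatives`: the expected
#'   greedy-cluster representative per family).
#' @export
makeSequenceFamilies <- function(seed, nFamilies = 5L,
                                 membersPerFamily = 10L, refLength = 520L,
                                 argConservedFraction = 1,
                                 argDropIds = NULL, refPos = 451L,
                                 triadPos = c(432L, 466L),
                                 fastaPath = NULL, referencePath = NULL) {
  refLength <- as.integer(refLength)
  if (refLength < max(c(refPos, triadPos)) + 10L)
    .err("catalocavity_value_error",
         "refLength too short for the conserved positions")
  .withSeed(seed, {
    ref <- sample(.AA20, refLength, replace = TRUE)
    ref[refPos] <- "R"
    if (length(triadPos) >= 1) ref[triadPos[1]] <- "C"
    if (length(triadPos) >= 2) ref[triadPos[2]] <- "Y"
    protected <- unique(unlist(lapply(c(refPos, triadPos), function(p)
      max(1L, p - 10L):min(refLength, p + 10L))))
    mutable <- setdiff(seq_len(refLength), protected)
    mutate <- function(x, n) {
      pos <- sample(mutable, n)
      for (p in pos) x[p] <- sample(setdiff(.AA20, x[p]), 1)
      x
    }
    fams <- lapply(seq_len(nFamilies), function(k)
      mutate(ref, round(0.65 * length(mutable))))
    seqs <- list()
    family <- character(0)
    for (k in seq_len(nFamilies)) {
      for (j in seq_len(membersPerFamily)) {
        idm <- sprintf("F%d_M%02d", k, j)
        seqs[[idm]] <- mutate(fams[[k]], round(0.03 * length(mutable)))
        family[idm] <- sprintf("F%d", k)
      }
    }
    ids <- names(seqs)
    if (is.null(argDropIds)) {
      nKeep <- round(argConservedFraction * length(ids))
      keepArg <- sort(sample.int(length(ids), nKeep))
      argDropIds <- ids[-keepArg]
    }
    argConserved <- setNames(!(ids %in% argDropIds), ids)
    for (idm in argDropIds) seqs[[idm]][refPos] <- "K"
    out <- vapply(seqs, paste, "", collapse = "")
    reference <- setNames(paste(ref, collapse = ""), "REF")
    reps <- vapply(split(ids, family[ids]), function(v) sort(v)[1], "")
    if (!is.null(fastaPath)) writeFastaAA(out, fastaPath)
    if (!is.null(referencePath)) writeFastaAA(reference, referencePath)
    list(sequences = out, reference = reference,
         manifest = list(seed = seed, family = family,
                         argConserved = argConserved,
                         representatives = reps, refPos = refPos))
  })
}

#' Docking cluster table with planted score matrix and top-k
#'
#' Plants per-pair docking clusters with random energies (kcal/mol,
#' negative) and distances (Angstrom) and records, via an independent
#' naive computation, the expected combined-score matrix, per-candidate
#' sums and per-group top-k shortlist.
#'
#' @param seed integer seed.
#' @param nCandidates,nLigands table shape (defaults 14 x 25).
#' @param candidateIds,ligandIds optional explicit ids.
#' @param groups optional named group labels; default: first half
#'   "blast", second half "pdb".
#' @param maxClusters max clusters per pair (default 4).
#' @param missingFraction fraction of candidate-ligand pairs without any
#'   cluster (default 0.05).
#' @param k shortlist size per group (default 5).
#' @param path optional TSV output path.
#' @return list with `clusters` (data.frame), `groups`, and `manifest`
#'   (`scores` matrix, `sums`, `topk`).
#' @export
makeDockingTable <- function(seed, nCandidates = 14L, nLigands = 25L,
                             candidateIds = NULL, ligandIds = NULL,
                             groups = NULL, maxClusters = 4L,
                             missingFraction = 0.05, k = 5L,
                             path = NULL) {
  .withSeed(seed, {
    if (is.null(candidateIds))
      candidateIds <- sprintf("cand%02d", seq_len(nCandidates))
    if (is.null(ligandIds))
      ligandIds <- sprintf("lig%02d", seq_len(nLigands))
    nCandidates <- length(candidateIds); nLigands <- length(ligandIds)
    if (is.null(groups)) {
      half <- ceiling(nCandidates / 2)
      groups <- setNames(c(rep("blast", half),
                           rep("pdb", nCandidates - half)), candidateIds)
    }
    rows <- list()
    for (ci in candidateIds) for (li in ligandIds) {
      if (runif(1) < missingFraction) next
      nc <- sample.int(maxClusters, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = ci, ligand_id = li, cluster_id = seq_len(nc),
        energy = round(runif(nc, -9, -2), 2),
        distance = round(runif(nc, 2.2, 8), 2),
        stringsAsFactors = FALSE)
    }
    clusters <- do.call(rbind, rows)
    rownames(clusters) <- NULL
    ## independent naive bookkeeping of the expected outcome
    scores <- matrix(0, nCandidates, nLigands,
                     dimnames = list(candidateIds, ligandIds))
    for (ci in candidateIds) for (li in ligandIds) {
      g <- clusters[clusters$candidate_id == ci &
                      clusters$ligand_id == li, , drop = FALSE]
      if (nrow(g) == 0L) next
      g <- g[order(g$distance, g$energy, g$cluster_id), , drop = FALSE]
      scores[ci, li] <- abs(g$energy[1] / g$distance[1])
    }
    sums <- rowSums(scores)
    topk <- unlist(lapply(sort(unique(groups)), function(gl) {
      ids <- names(groups)[groups == gl]
      s <- sums[ids]
      ids[order(-s, ids)][seq_len(min(k, length(ids)))]
    }), use.names = FALSE)
    if (!is.null(path)) writeDockingTable(clusters, path)
    list(clusters = clusters, groups = groups,
         manifest = list(seed = seed, scores = scores, sums = sums,
                         topk = topk, k = k))
  })
}
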