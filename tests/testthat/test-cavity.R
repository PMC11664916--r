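test_that("hollow-box cavity equals the brute-force enumeration", {
  box <- makeHollowBox()
  cl <- procreateCavity(box$structure, box$ligand, box$frame,
                        gridSpacing = 1.0)
  bf <- bruteForceCavity(box$structure, box$ligand, box$frame,
                         gridSpacing = 1.0)
  expect_gt(nPoints(cl), 0)
  expect_equal(sortRows(pointCoords(cl)), sortRows(bf),
               ignore_attr = TRUE)
})

test_that("spatial-index and all-pairs cavities agree on toy enzymes", {
  for (seed in 1:4) {
    toy <- makeToyEnzyme(seed, tunnelRadius = 3.5 + 0.3 * seed,
                         ligandCarbons = 6L + seed)
    cl <- procreateCavity(toy$structure, toy$ligand, toy$frame)
    bf <- bruteForceCavity(toy$structure, toy$ligand, toy$frame)
    expect_equal(sortRows(pointCoords(cl)), sortRows(bf),
                 ignore_attr = TRUE)
    expect_equal(nPoints(cl), toy$manifest$bruteCavityCount)
  }
})

test_that("grid points inside atoms are excluded, free space is kept", {
  box <- makeHollowBox()
  cl <- procreateCavity(box$structure, box$ligand, box$frame,
                        gridSpacing = 1.0)
  pts <- pointCoords(cl)
  a <- atoms(box$structure)
  occ <- a[a$resname != "OCA", c("x", "y", "z")]
  ## no kept point closer to an occluding atom centre than its own vdW
  ## radius (let alone the probe-augmented threshold)
  dmin <- apply(pts, 1, function(p)
    sqrt(min(colSums((t(as.matrix(occ)) - p)^2))))
  expect_true(all(dmin >= 1.52))
  ## with no protein atoms and the buriedness filter off, every grid
  ## point within reach of the ligand survives
  bare <- new("ProteinStructure",
              atoms = a[a$resname %in% c("OCA", "FAD"), ], id = "bare")
  frame <- locateFlavin(bare, ligand = box$ligand)
  clBare <- procreateCavity(bare, box$ligand, frame, gridSpacing = 1.0,
                            buriednessMin = 0)
  ligXYZ <- as.matrix(a[a$resname == "OCA", c("x", "y", "z")])
  grid <- catalocavity:::.cavityGrid(ligXYZ, 1.0, 5.0, frame)
  fad <- a[a$resname == "FAD", , drop = FALSE]
  fadXYZ <- as.matrix(fad[, c("x", "y", "z")])
  fadThr <- ifelse(fad$element == "N", 1.55, 1.7) + 0.7
  expectKeep <- apply(grid, 1, function(p) {
    d <- sqrt(colSums((t(fadXYZ) - p)^2))
    min(colSums((t(ligXYZ) - p)^2)) <= 25 &&
      all(d >= fadThr)  # the flavin mimic still occludes
  })
  expect_equal(nPoints(clBare), sum(expectKeep))
})

test_that("an empty cavity raises a dedicated error", {
  box <- makeHollowBox(inner = 1.2)  # too tight for any point
  expect_error(
    procreateCavity(box$structure, box$ligand, box$frame,
                    gridSpacing = 1.0, maxLigandDistance = 2.5),
    class = "catalocavity_empty_cavity_error")
})

test_that("electrostatic annotation matches the direct formula", {
  toy <- makeToyEnzyme(seed = 9, argNearN5 = TRUE)
  cl <- annotateProperties(
    procreateCavity(toy$structure, toy$ligand, toy$frame),
    toy$structure, toy$ligand)
  a <- atoms(toy$structure)
  nh1 <- as.numeric(a[a$name == "NH1", c("x", "y", "z")])
  pts <- pointCoords(cl)
  expected <- vapply(seq_len(nrow(pts)), function(i)
    oraclePotential(pts[i, ], matrix(nh1, 1, 3), +1), numeric(1))
  expect_equal(cl@props$electrostatic, expected, tolerance = 1e-12)
  ## a single positive source forces a positive sign everywhere in range
  expect_true(all(cl@props$electrostatic >= 0))
})

test_that("hbond ramp hits its documented midpoint", {
  ## arginine NH1 nitrogen at exactly 3.25 A from a probe point:
  ## midpoint of the 2.5-4.0 A ramp
  df <- data.frame(serial = 1:2, name = c("NH1", "C1"),
                   element = c("N", "C"), resname = c("ARG", "OCA"),
                   chain = c("A", "L"), resno = c(1L, 500L),
                   x = c(3.25, 0), y = c(0, 0), z = c(0, 0),
                   het = c(FALSE, TRUE), occ = 1,
                   stringsAsFactors = FALSE)
  s <- new("ProteinStructure", atoms = df, id = "ramp")
  frame <- FlavinFrame(c(0, 0, 1), c(0, 0, 0), c(0, 0, 1))
  cl <- CavityCloud(matrix(c(0, 0, 0), 1, 3), frame = frame)
  lig <- LigandSpec("OCA", "L", 500L, "C1", c("C1", "C2"))
  ann <- annotateProperties(cl, s, lig)
  expect_equal(ann@props$hbond_donor, 0.5, tolerance = 1e-9)
  expect_equal(ann@props$hbond_acceptor, 0)
})

test_that("two known charges give the hand-evaluated potential", {
  sites <- rbind(c(5, 0, 0), c(0, -3, 0))
  q <- c(+1, -1)
  df <- data.frame(
    serial = 1:3, name = c("NZ", "OD1", "OD2"),
    element = c("N", "O", "O"), resname = c("LYS", "ASP", "ASP"),
    chain = "A", resno = c(1L, 2L, 2L),
    x = c(5, 0, 0), y = c(0, -3, -3), z = c(0, 0.0, 0.0),
    het = FALSE, occ = 1, stringsAsFactors = FALSE)
  s <- new("ProteinStructure", atoms = df, id = "charges")
  frame <- FlavinFrame(c(0, 0, 1), c(0, 0, 0), c(0, 0, 1))
  cl <- CavityCloud(matrix(c(0, 0, 0), 1, 3), frame = frame)
  ann <- annotateProperties(cl, s)
  expect_equal(ann@props$electrostatic,
               oraclePotential(c(0, 0, 0), sites, q), tolerance = 1e-12)
})

test_that("negative-charge stabilization tracks the planted site sign", {
  argToy <- makeToyEnzyme(seed = 10, argNearN5 = TRUE)
  clArg <- annotateProperties(
    procreateCavity(argToy$structure, argToy$ligand, argToy$frame),
    argToy$structure, argToy$ligand)
  expect_true(negativeChargeStabilization(clArg))
  aspToy <- makeToyEnzyme(seed = 10, argNearN5 = FALSE, aspNearN5 = TRUE)
  clAsp <- annotateProperties(
    procreateCavity(aspToy$structure, aspToy$ligand, aspToy$frame),
    aspToy$structure, aspToy$ligand)
  expect_false(negativeChargeStabilization(clAsp))
  ## matches the sign of the brute-force mean over the N5 neighbourhood
  for (cl in list(clArg, clAsp)) {
    pts <- pointCoords(cl)
    sel <- sqrt(colSums((t(pts) - cl@frame@n5)^2)) <= 4
    expect_equal(negativeChargeStabilization(cl),
                 mean(cl@props$electrostatic[sel]) > 0)
  }
  ## no points near N5 -> inconclusive, not FALSE
  far <- CavityCloud(matrix(c(50, 50, 50), 1, 3),
                     frame = clArg@frame, sourceId = "far")
  expect_true(is.na(negativeChargeStabilization(far)))
})

test_that("cavity procreation and annotation are rigid-equivariant", {
  toy <- makeToyEnzyme(seed = 11)
  cl0 <- annotateProperties(
    procreateCavity(toy$structure, toy$ligand, toy$frame),
    toy$structure, toy$ligand)
  for (seed in 1:2) {
    R <- withr::with_seed(seed, catalocavity:::.randomRotation())
    tr <- withr::with_seed(seed + 50, runif(3, -15, 15))
    st <- transformStructure(toy$structure, R, tr)
    frT <- locateFlavin(st, ligand = toy$ligand)
    clT <- annotateProperties(procreateCavity(st, toy$ligand, frT),
                              st, toy$ligand)
    ref <- transformCloud(cl0, R, tr)
    expect_equal(nPoints(clT), nPoints(ref))
    o1 <- do.call(order, as.data.frame(pointCoords(clT)))
    o2 <- do.call(order, as.data.frame(pointCoords(ref)))
    expect_equal(pointCoords(clT)[o1, ], pointCoords(ref)[o2, ],
                 tolerance = 1e-6, ignore_attr = TRUE)
    smooth <- c("electrostatic", "hbond_donor", "hbond_acceptor",
                "hydrophobicity")
    expect_equal(as.matrix(pointProps(clT)[o1, smooth]),
                 as.matrix(pointProps(ref)[o2, smooth]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    ## buriedness is a discrete ray-hit count (k/42): a ray exactly
    ## grazing an atom sphere can flip by one under re-derivation of the
    ## frame, so it is compared at single-ray resolution
    expect_equal(pointProps(clT)$buriedness[o1],
                 pointProps(ref)$buriedness[o2], tolerance = 1 / 42 + 1e-9)
  }
})

test_that("kept-point counts respond monotonically to the reach parameters", {
  toy <- makeToyEnzyme(seed = 12)
  n <- function(...) nPoints(procreateCavity(toy$structure, toy$ligand,
                                             toy$frame, ...))
  expect_lte(n(maxLigandDistance = 3), n(maxLigandDistance = 5))
  expect_lte(n(maxLigandDistance = 5), n(maxLigandDistance = 7))
  expect_gte(n(probeRadius = 1.0), n(probeRadius = 1.4))
  expect_gte(n(probeRadius = 1.4), n(probeRadius = 2.0))
})
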