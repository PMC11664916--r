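test_that("a cloud matched to itself is a perfect match", {
  p <- makeCloudPair(seed = 21, nPoints = 80, overlapTarget = 100)
  m <- alignClouds(p$cloudA, p$cloudA)
  expect_equal(m@rotation, diag(3), tolerance = 1e-8)
  expect_equal(m@translation, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(m@totalScore, 0, tolerance = 1e-12)
  expect_equal(m@overlap12, 100)
  expect_equal(m@overlap21, 100)
  expect_true(m@flavinSameSide)
})

test_that("registration recovers a planted rigid transform", {
  for (seed in 22:25) {
    p <- makeCloudPair(seed = seed, nPoints = 150, overlapTarget = 100)
    m <- alignClouds(p$cloudA, p$cloudB)
    expect_lt(norm(m@rotation - p$manifest$rotation, "F"), 1e-4)
    expect_lt(max(abs(m@translation - p$manifest$translation)), 1e-4)
    expect_lt(m@totalScore, 1e-6)
  }
})

test_that("disjoint clouds yield the worst-case result, not an error", {
  p <- makeCloudPair(seed = 26, nPoints = 100, overlapTarget = 0)
  m <- alignClouds(p$cloudA, p$cloudB)
  expect_equal(m@overlap12, 0)
  expect_equal(m@overlap21, 0)
  expect_equal(m@totalScore, 1)
})

test_that("directional overlaps count asymmetrically", {
  ## 10 points of a all inside b (40 points): a->b 100 %, b->a 25 %
  frame <- FlavinFrame(c(0, 0, 1), c(0, 0, 0), c(0, 0, 1))
  big <- as.matrix(expand.grid(seq(0, 12, 3), seq(0, 12, 3),
                               c(0, 3)))[1:40, ]
  a <- CavityCloud(big[1:10, ], frame = frame, sourceId = "a")
  b <- CavityCloud(big, frame = frame, sourceId = "b")
  expect_equal(overlapFraction(a, b), 100)
  expect_equal(overlapFraction(b, a), 25)
})

test_that("overlap and score match the all-pairs oracle on random pairs", {
  for (seed in 27:31) {
    tgt <- c(100, 75, 50, 25, 0)[seed - 26]
    p <- makeCloudPair(seed = seed, nPoints = 60, overlapTarget = tgt)
    R <- p$manifest$rotation; tr <- p$manifest$translation
    Ri <- t(R); ti <- as.numeric(-Ri %*% tr)
    expect_identical(overlapFraction(p$cloudA, p$cloudB, R, tr),
                     oracleOverlap(p$cloudA, p$cloudB, R, tr))
    expect_identical(overlapFraction(p$cloudB, p$cloudA, Ri, ti),
                     oracleOverlap(p$cloudB, p$cloudA, Ri, ti))
    expect_equal(totalScore(p$cloudA, p$cloudB, R, tr),
                 oracleScore(p$cloudA, p$cloudB, R, tr),
                 tolerance = 1e-12)
  }
})

test_that("totalScore spans [0, 1] with the documented endpoints", {
  p <- makeCloudPair(seed = 32, nPoints = 80, overlapTarget = 100)
  R <- p$manifest$rotation; tr <- p$manifest$translation
  expect_equal(totalScore(p$cloudA, p$cloudB, R, tr), 0, tolerance = 1e-12)
  d <- makeCloudPair(seed = 33, nPoints = 80, overlapTarget = 0)
  expect_equal(totalScore(d$cloudA, d$cloudB, d$manifest$rotation,
                          d$manifest$translation), 1)
})

test_that("common rigid transforms leave overlaps and score invariant", {
  p <- makeCloudPair(seed = 34, nPoints = 80, overlapTarget = 60)
  R <- p$manifest$rotation; tr <- p$manifest$translation
  s0 <- totalScore(p$cloudA, p$cloudB, R, tr)
  o0 <- overlapFraction(p$cloudA, p$cloudB, R, tr)
  Q <- withr::with_seed(7, catalocavity:::.randomRotation())
  u <- c(4, -2, 9)
  a2 <- transformCloud(p$cloudA, Q, u)
  b2 <- transformCloud(p$cloudB, Q, u)
  ## transform mapping a2 onto b2: conjugated by (Q, u)
  R2 <- Q %*% R %*% t(Q)
  t2 <- as.numeric(Q %*% tr + u - R2 %*% u)
  expect_equal(overlapFraction(a2, b2, R2, t2), o0, tolerance = 1e-9)
  expect_equal(totalScore(a2, b2, R2, t2), s0, tolerance = 1e-9)
})

test_that("flavin side triage flags constructed opposite-side scenes", {
  for (seed in 35:38) {
    p <- makeCloudPair(seed = seed, nPoints = 60, overlapTarget = 100)
    a <- p$cloudA
    expect_true(flavinSameSide(a, a))
    ## reflect the target frame through the cloud's centroid plane:
    ## anti-parallel normals (Figure-2D-type scene) -> FALSE
    n <- a@frame@ringNormal
    ctr <- colMeans(pointCoords(a))
    reflect <- function(x) x - 2 * sum((x - ctr) * n) * n
    bad <- a
    bad@frame <- FlavinFrame(n5 = reflect(a@frame@n5),
                             ringCentroid = reflect(a@frame@ringCentroid),
                             ringNormal = -n)
    expect_false(flavinSameSide(a, bad))
    ## same normal but N5 moved to the other side of the cloud plane:
    ## still an opposite-side scene
    bad2 <- a
    bad2@frame <- FlavinFrame(n5 = reflect(a@frame@n5),
                              ringCentroid = reflect(a@frame@ringCentroid),
                              ringNormal = n)
    expect_false(flavinSameSide(a, bad2))
  }
})

test_that("match filtering applies the published strict gates", {
  results <- list(
    mkMatch(0.047, 75, 12, "pass_small"),   # the published near-gate case
    mkMatch(0.05, 90, 50, "boundary_score"),  # score == gate -> removed
    mkMatch(0.04, 70, 50, "boundary_ov12"),   # overlap == gate -> removed
    mkMatch(0.01, 80, 10, "boundary_ov21"),
    mkMatch(0.01, 80, 12, "pass_low21"),
    mkMatch(0.06, 95, 95, "fail_score"))
  kept <- filterMatches(results)
  expect_equal(vapply(kept, function(r) r@targetId, ""),
               c("pass_small", "pass_low21"))
  ## larger candidate pools demand > 30 % reverse overlap
  keptLarge <- filterMatches(results, largePool = TRUE)
  expect_equal(vapply(keptLarge, function(r) r@targetId, ""),
               character(0))
  keptLarge2 <- filterMatches(c(results, list(mkMatch(0.01, 80, 35, "big"))),
                              largePool = TRUE)
  expect_equal(vapply(keptLarge2, function(r) r@targetId, ""), "big")
})

test_that("relaxing filter thresholds never shrinks the kept set", {
  set.seed(40)
  results <- lapply(seq_len(30), function(i)
    mkMatch(runif(1, 0, 0.1), runif(1, 40, 100), runif(1, 0, 60),
            sprintf("r%02d", i)))
  ids <- function(rs) vapply(rs, function(r) r@targetId, "")
  base <- ids(filterMatches(results))
  expect_true(all(base %in% ids(filterMatches(results, scoreMax = 0.08))))
  expect_true(all(base %in% ids(filterMatches(results, ov12Min = 60))))
  expect_true(all(base %in% ids(filterMatches(results, ov21Min = 5))))
})

test_that("self-match is never beaten by another target", {
  p <- makeCloudPair(seed = 41, nPoints = 80, overlapTarget = 70)
  self <- alignClouds(p$cloudA, p$cloudA)@totalScore
  other <- alignClouds(p$cloudA, p$cloudB)@totalScore
  expect_lte(self, other)
})

test_that("epsilon must be positive", {
  p <- makeCloudPair(seed = 42, nPoints = 20, overlapTarget = 100)
  expect_error(overlapFraction(p$cloudA, p$cloudB, epsilon = 0),
               class = "catalocavity_value_error")
})
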