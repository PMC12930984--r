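maskOf <- function(arr, kind = "head") {
  new("VoxelMask", voxels = array(arr, dim(arr)), kind = kind,
      sourceScanId = "t")
}

test_that("impacted and removed percentages match hand counts", {
  o <- array(0, c(3, 3, 3))
  o[1:10] <- 1                        # 10-voxel head
  head <- maskOf(o > 0)
  d <- o
  d[1:4] <- 0.5                       # 4 altered, none removed
  expect_equal(impactedVoxels(newScan(o), newScan(d), head), 40)
  expect_equal(removedVoxels(newScan(o), newScan(d), head), 0)
  d2 <- o
  d2[1:3] <- 0                        # 3 of 10 zeroed
  expect_equal(removedVoxels(newScan(o), newScan(d2), head), 30)
  expect_equal(impactedVoxels(newScan(o), newScan(o), head), 0)
  # a +1 global shift impacts every head voxel at zero tolerance
  expect_equal(impactedVoxels(newScan(o), newScan(o + 1), head), 100)
  expect_error(impactedVoxels(newScan(o), newScan(d), maskOf(o > 2)),
               "empty")
})

test_that("brain impact confines numerator and denominator to the brain", {
  o <- array(1, c(3, 3, 3))
  brain <- array(FALSE, c(3, 3, 3))
  brain[1:8] <- TRUE                  # 8-voxel brain
  bm <- maskOf(brain, "brain")
  d <- o
  d[9:12] <- 0                        # outside the brain
  expect_equal(unname(brainImpact(newScan(o), newScan(d), bm)), c(0, 0))
  d2 <- o
  d2[1:2] <- c(0, 0.5)                # 2 altered, 1 zeroed
  expect_equal(unname(brainImpact(newScan(o), newScan(d2), bm)),
               c(25, 12.5))
  expect_equal(unname(brainImpact(newScan(o), newScan(o * 0), bm)),
               c(100, 100))
})

test_that("brain-to-head ratio is a plain voxel-count ratio", {
  h <- array(TRUE, c(3, 3, 3))
  b <- array(FALSE, c(3, 3, 3))
  b[1:8] <- TRUE
  expect_equal(brainToHeadRatio(maskOf(b, "brain"), maskOf(h)), 8 / 27)
  expect_equal(round(brainToHeadRatio(maskOf(b, "brain"), maskOf(h)), 4),
               0.2963)
  expect_equal(brainToHeadRatio(maskOf(h, "brain"), maskOf(h)), 1)
  expect_equal(brainToHeadRatio(maskOf(b & !b, "brain"), maskOf(h)), 0)
  expect_error(brainToHeadRatio(maskOf(b, "brain"), maskOf(h & !h)),
               "empty")
})

test_that("all five measures equal the brute-force oracle on random pairs", {
  for (seed in 1:25) {
    p <- randomTinyPair(seed)
    got <- volumetricFeatures(newScan(p$o), newScan(p$d), maskOf(p$head),
                              maskOf(p$brain, "brain"))
    want <- bruteVolumetrics(p$o, p$d, p$head, p$brain)
    expect_equal(unlist(got), want, tolerance = 0)
    expect_lte(got$head_removed_pct, got$head_impacted_pct)
    expect_lte(got$brain_removed_pct, got$brain_impacted_pct)
  }
})

test_that("measures are invariant under simultaneous axis permutation", {
  p <- randomTinyPair(99)
  base <- volumetricFeatures(newScan(p$o), newScan(p$d), maskOf(p$head),
                             maskOf(p$brain, "brain"))
  perm <- c(3, 1, 2)
  alt <- volumetricFeatures(newScan(aperm(p$o, perm)),
                            newScan(aperm(p$d, perm)),
                            maskOf(aperm(p$head, perm)),
                            maskOf(aperm(p$brain, perm), "brain"))
  expect_equal(alt, base)
})

test_that("impacted fraction is monotone non-increasing in the tolerance", {
  p <- randomTinyPair(7)
  eps <- sort(runif(8, 0, 1))
  vals <- vapply(eps, function(e)
    impactedVoxels(newScan(p$o), newScan(p$d), maskOf(p$head), e),
    numeric(1))
  expect_true(all(diff(vals) <= 0))
})
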