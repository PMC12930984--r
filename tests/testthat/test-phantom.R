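test_that("phantom generation is deterministic and geometrically sane", {
  sp <- phantomSpec(gridSize = 48, seed = 5, subjectSeed = 9)
  p1 <- generatePhantom(sp)
  p2 <- generatePhantom(sp)
  expect_identical(p1@scan@intensities, p2@scan@intensities)
  expect_identical(p1@headMask@voxels, p2@headMask@voxels)
  # brain strictly inside head
  expect_false(any(p1@brainMask@voxels & !p1@headMask@voxels))
  bhr <- brainToHeadRatio(p1@brainMask, p1@headMask)
  expect_gt(bhr, 0.2)
  expect_lt(bhr, 0.8)
  # facial features intersect the head surface and are visible frontally
  s <- normalizeScan(p1@scan)
  img <- renderView(s, headMask(s), viewSpec("frontal", 64L))
  noNose <- p1
  noNose@scan@intensities[p1@featureVoxels$nose] <- 0
  s2 <- normalizeScan(noNose@scan)
  img2 <- renderView(s2, headMask(s2), viewSpec("frontal", 64L))
  expect_gt(sum(img != img2), 0)
})

test_that("same subject seed shares anatomy, different scan seeds differ", {
  a <- generatePhantom(phantomSpec(gridSize = 48, subjectSeed = 3, seed = 1))
  b <- generatePhantom(phantomSpec(gridSize = 48, subjectSeed = 3, seed = 2))
  c <- generatePhantom(phantomSpec(gridSize = 48, subjectSeed = 4, seed = 1))
  expect_identical(a@headMask@voxels, b@headMask@voxels)  # same shape
  expect_false(identical(a@scan@intensities, b@scan@intensities))  # new noise
  expect_false(identical(a@headMask@voxels, c@headMask@voxels))  # new shape
})

test_that("simulated defacing zeroes features surface-inward and obeys accounting", {
  ph <- generatePhantom(phantomSpec(gridSize = 48, seed = 6))
  nHead <- maskCount(ph@headMask)
  featShare <- 100 * length(unique(unlist(ph@featureVoxels))) / nHead
  # full removal: head loss equals the features' share of head voxels
  defFull <- simulateDefacing(ph, defaceSimSpec())
  expect_equal(removedVoxels(ph@scan, defFull, ph@headMask), featShare,
               tolerance = 1e-10)
  expect_equal(removedVoxels(ph@scan, defFull, ph@brainMask), 0)
  # no-op defacing is the identity
  defNone <- simulateDefacing(ph, defaceSimSpec(removal = c(
    nose = 0, left_eye = 0, right_eye = 0, mouth = 0)))
  expect_identical(defNone@intensities, ph@scan@intensities)
  # pure global perturbation impacts everything, removes nothing
  defPert <- simulateDefacing(ph, defaceSimSpec(
    removal = c(nose = 0, left_eye = 0, right_eye = 0, mouth = 0),
    globalPerturbation = 0.002, method = "mrideface"))
  expect_equal(impactedVoxels(ph@scan, defPert, ph@headMask), 100)
  expect_equal(removedVoxels(ph@scan, defPert, ph@headMask), 0)
  # brain clip zeroes the requested brain fraction
  defClip <- simulateDefacing(ph, defaceSimSpec(
    removal = c(nose = 0, left_eye = 0, right_eye = 0, mouth = 0),
    brainClip = 0.1, method = "fsldeface"))
  expect_equal(removedVoxels(ph@scan, defClip, ph@brainMask), 10,
               tolerance = 0.1)
  # partial removal leaves the inner (deep) voxels: the retained voxels
  # are the ones closest to the head center in the removal ordering
  defHalf <- simulateDefacing(ph, defaceSimSpec(removal = c(
    nose = 0.5, left_eye = 0, right_eye = 0, mouth = 0)))
  idx <- ph@featureVoxels$nose
  zeroed <- idx[defHalf@intensities[idx] == 0]
  expect_setequal(zeroed, idx[seq_len(round(0.5 * length(idx)))])
})

test_that("strict and lenient label rules match their definitions", {
  strict <- groundTruthRule("strict")
  lenient <- groundTruthRule("lenient")
  allGone <- defaceSimSpec()
  expect_identical(labelDefacing(allGone, strict), 0L)
  expect_identical(labelDefacing(allGone, lenient), 0L)
  onePartial <- defaceSimSpec(removal = c(nose = 0.7, left_eye = 1,
                                          right_eye = 1, mouth = 1))
  expect_identical(labelDefacing(onePartial, strict), 1L)
  expect_identical(labelDefacing(onePartial, lenient), 0L)
  oneSevere <- defaceSimSpec(removal = c(nose = 0.2, left_eye = 1,
                                         right_eye = 1, mouth = 1))
  expect_identical(labelDefacing(oneSevere, lenient), 1L)
  twoPartial <- defaceSimSpec(removal = c(nose = 0.7, left_eye = 0.6,
                                          right_eye = 1, mouth = 1))
  expect_identical(labelDefacing(twoPartial, strict), 1L)
  expect_identical(labelDefacing(twoPartial, lenient), 1L)
})

test_that("cohort manifests hit the design: size, balance, determinism", {
  man <- generateCohortManifest(nSubjects = 20, scansPerSubject = c(2, 2),
                                classBalance = 0.4, seed = 3)
  expect_identical(nrow(man), 20L * 2L * 4L)
  expect_identical(length(unique(man$subject_id)), 20L)
  expect_lt(abs(mean(man$label_lenient) - 0.4), 0.05)
  man2 <- generateCohortManifest(nSubjects = 20, scansPerSubject = c(2, 2),
                                 classBalance = 0.4, seed = 3)
  expect_identical(man, man2)
  # labels re-derive exactly from the stored sim parameters
  relab <- vapply(seq_len(nrow(man)), function(j)
    labelDefacing(defacingQC:::manifestSim(man[j, ]),
                  groundTruthRule("lenient")), integer(1))
  expect_identical(relab, man$label_lenient)
})

test_that("cohorts materialize on disk with the suffix naming convention", {
  td <- tempfile(); dir.create(td)
  man <- generateCohort(td, gridSize = 32, nSubjects = 2,
                        scansPerSubject = c(1, 1),
                        methods = c("pydeface", "mrideface"), seed = 2)
  expect_true(file.exists(file.path(td, "manifest.csv")))
  for (j in seq_len(nrow(man))) {
    expect_true(file.exists(file.path(
      td, paste0(man$scan_id[j], "_", man$method[j], ".nii.gz"))))
  }
  sid <- man$scan_id[1]
  expect_true(file.exists(file.path(td, paste0(sid, ".nii.gz"))))
  expect_true(file.exists(file.path(td, paste0(sid, "_brainmask.nii.gz"))))
  # defaced volume on disk reproduces the in-memory simulation
  row <- man[1, ]
  ph <- defacingQC:::manifestPhantom(row, 32, 0.02)
  def <- simulateDefacing(ph, defacingQC:::manifestSim(row))
  reread <- readScan(file.path(td, paste0(row$scan_id, "_", row$method,
                                          ".nii.gz")))
  expect_equal(reread@intensities, def@intensities, tolerance = 0)
})

test_that("increasing removal never raises fsim or lowers head loss", {
  ph <- generatePhantom(phantomSpec(gridSize = 48, seed = 12))
  s <- normalizeScan(ph@scan)
  vO <- renderView(s, headMask(s), viewSpec("frontal", 64L))
  fs <- c(); hr <- c()
  for (r in c(0, 0.5, 1)) {
    d <- simulateDefacing(ph, defaceSimSpec(removal = c(
      nose = r, left_eye = r, right_eye = r, mouth = r)))
    sd2 <- normalizeScan(d)
    vD <- renderView(sd2, headMask(sd2), viewSpec("frontal", 64L))
    fs <- c(fs, viewFSIM(vO, vD))
    hr <- c(hr, removedVoxels(ph@scan, d, ph@headMask))
  }
  expect_true(all(diff(fs) <= 0))
  expect_true(all(diff(hr) >= 0))
})
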