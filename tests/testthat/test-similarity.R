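test_that("rmse matches a double-loop oracle and basic identities", {
  a <- matrix(0, 2, 2)
  b <- matrix(1, 2, 2)
  expect_equal(viewRMSE(a, a), 0)
  expect_equal(viewRMSE(a, b), 1)
  set.seed(3)
  x <- matrix(runif(16), 4)
  y <- matrix(runif(16), 4)
  acc <- 0
  for (i in 1:4) for (j in 1:4) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(viewRMSE(x, y), sqrt(acc / 16), tolerance = 1e-12)
  expect_error(viewRMSE(x, matrix(0, 3, 3)), "shapes differ")
})

test_that("psnr is the capped closed form of rmse", {
  cfg <- similarityConfig()
  a <- matrix(0.5, 8, 8)
  expect_equal(viewPSNR(a, a, cfg), cfg$psnrCap)
  expect_equal(viewPSNR(a, a + 0.1, cfg), 20)
  # strictly decreasing in rmse
  d <- vapply(c(0.05, 0.1, 0.2, 0.4), function(e)
    viewPSNR(a, a + e, cfg), numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("ssim identities, symmetry and bounds", {
  img <- structuredImage(48, 10)
  expect_equal(viewSSIM(img, img), 1)
  shifted <- pmin(img + 0.5, 1)
  expect_lt(viewSSIM(img, shifted), 1)
  expect_equal(viewSSIM(img, shifted), viewSSIM(shifted, img))
  # negative image on a high-contrast zero-mean pattern approaches the
  # -1 structure-agreement bound
  cb <- outer(1:48, 1:48, function(i, j) (i + j) %% 2)
  expect_lt(viewSSIM(cb, 1 - cb), -0.99)
  expect_gte(viewSSIM(cb, 1 - cb), -1)
  expect_error(viewSSIM(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("ssim agrees with the scikit-image reference implementation", {
  lines <- c(
    "import sys, numpy as np",
    "from skimage.metrics import structural_similarity",
    "with open(sys.argv[1]) as fh:",
    "    for line in fh:",
    "        fa, fb = line.split()",
    "        a, b = np.loadtxt(fa), np.loadtxt(fb)",
    "        print(float(structural_similarity(a, b, gaussian_weights=True,",
    "              sigma=1.5, use_sample_covariance=False, data_range=1.0)))")
  td <- tempfile(); dir.create(td)
  pairs <- file.path(td, "pairs.txt")
  con <- file(pairs, "w")
  rvals <- numeric(0)
  for (i in 1:4) {
    a <- structuredImage(48, i)
    b <- pmin(pmax(a + 0.2 * structuredImage(48, 50 + i) - 0.1, 0), 1)
    fa <- file.path(td, paste0("a", i, ".txt"))
    fb <- file.path(td, paste0("b", i, ".txt"))
    write.table(a, fa, row.names = FALSE, col.names = FALSE)
    write.table(b, fb, row.names = FALSE, col.names = FALSE)
    cat(fa, fb, "\n", file = con)
    rvals <- c(rvals, viewSSIM(a, b))
  }
  close(con)
  py <- as.numeric(runPythonLines(lines, pairs))
  expect_equal(rvals, py, tolerance = 1e-6)
})

test_that("fsim identities, symmetry, bounds and degenerate inputs", {
  img <- structuredImage(64, 20)
  expect_equal(viewFSIM(img, img), 1)
  other <- structuredImage(64, 21)
  v <- viewFSIM(img, other)
  expect_true(v > 0 && v < 1)
  expect_equal(viewFSIM(img, other), viewFSIM(other, img))
  expect_error(viewFSIM(matrix(0.5, 16, 16), matrix(0.5, 16, 16)), "32")
  # constant images: identical -> 1
  expect_equal(viewFSIM(matrix(0.5, 40, 40), matrix(0.5, 40, 40)), 1)
})

test_that("fsim agrees with the independent reference implementation", {
  td <- tempfile(); dir.create(td)
  pairs <- file.path(td, "pairs.txt")
  con <- file(pairs, "w")
  rvals <- numeric(0)
  for (i in 1:4) {
    a <- structuredImage(64, 30 + i)
    b <- if (i == 1) a else
      pmin(pmax(a + 0.15 * structuredImage(64, 80 + i) - 0.05, 0), 1)
    fa <- file.path(td, paste0("fa", i, ".txt"))
    fb <- file.path(td, paste0("fb", i, ".txt"))
    write.table(a * 255, fa, row.names = FALSE, col.names = FALSE)
    write.table(b * 255, fb, row.names = FALSE, col.names = FALSE)
    cat(fa, fb, "\n", file = con)
    rvals <- c(rvals, viewFSIM(a, b))
  }
  close(con)
  py <- as.numeric(system2(pythonBin(),
    c(test_path("fsim_reference.py"), pairs), stdout = TRUE))
  expect_equal(rvals, py, tolerance = 1e-3)
})

test_that("metric bounds hold on many random pairs", {
  set.seed(44)
  for (i in 1:60) {
    a <- matrix(runif(40 * 40), 40)
    b <- matrix(runif(40 * 40), 40)
    s <- viewSSIM(a, b)
    f <- viewFSIM(a, b)
    expect_true(s >= -1 && s <= 1)
    expect_true(f >= 0 && f <= 1)
  }
})

test_that("similarity features aggregate per-view metrics over five views", {
  ph <- generatePhantom(phantomSpec(gridSize = 48, seed = 8))
  s <- normalizeScan(ph@scan)
  m <- headMask(s)
  v <- renderAllViews(s, m, 64L)
  idf <- similarityFeatures(v, v)
  expect_equal(unlist(idf),
               c(rmse = 0, psnr = 100, ssim = 1, fsim = 1))
  def <- simulateDefacing(ph, defaceSimSpec(removal = c(
    nose = 1, left_eye = 0, right_eye = 0, mouth = 0)))
  sd2 <- normalizeScan(def)
  vd <- renderAllViews(sd2, headMask(sd2), 64L)
  sf <- similarityFeatures(v, vd)
  # the mean over 5 views equals the mean of per-view values
  per <- vapply(names(viewImages(v)), function(nm)
    viewFSIM(viewImages(v)[[nm]], viewImages(vd)[[nm]]), numeric(1))
  expect_equal(sf$fsim, mean(per))
  # the protruding nose silhouettes against background in the profiles,
  # so those views lose the most similarity when it goes
  expect_true(names(which.min(per)) %in% c("left_profile", "right_profile",
                                           "frontal"))
  expect_true(all(per < 1))
  # a view that cannot see the removed feature is untouched: the right
  # profile is occluded from a left-eye removal
  defEye <- simulateDefacing(ph, defaceSimSpec(removal = c(
    nose = 0, left_eye = 1, right_eye = 0, mouth = 0)))
  se <- normalizeScan(defEye)
  ve <- renderAllViews(se, headMask(se), 64L)
  perEye <- vapply(names(viewImages(v)), function(nm)
    viewFSIM(viewImages(v)[[nm]], viewImages(ve)[[nm]]), numeric(1))
  expect_equal(perEye[["right_profile"]], 1)
  expect_lt(perEye[["left_profile"]], 1)
  expect_lt(perEye[["frontal"]], 1)
  vbad <- renderAllViews(sd2, headMask(sd2), 32L)
  expect_error(similarityFeatures(v, vbad), "resolution")
})
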