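test_that("classification metrics reproduce a hand-computed 2x2 table", {
  # TP=3 FP=1 FN=1 TN=5
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  score <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.1, 0.4)
  m <- classificationMetrics(truth, score)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.8)
  perfect <- classificationMetrics(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, precision = 1, auroc = 1))
})

test_that("auroc uses tie-corrected ranks and matches pROC", {
  expect_equal(aurocScore(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_true(is.na(aurocScore(c(1, 1), c(0.2, 0.3))))
  set.seed(5)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(40), 1)   # plenty of ties
    ours <- aurocScore(y, s)
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
    # invariant under strictly monotone transforms of the scores
    expect_equal(aurocScore(y, qlogis(pmin(pmax(s, 0.01), 0.99))), ours)
  }
})

test_that("group-stratified folds keep subjects together and balance classes", {
  subj <- rep(paste0("s", 1:10), each = 4)
  y <- rep(c(0, 1), 20)
  f <- makeGroupStratifiedFolds(subj, y, 5, seed = 1)
  expect_identical(length(unique(tapply(f, subj, function(x)
    length(unique(x))))), 1L)
  expect_true(all(tapply(f, subj, function(x) length(unique(x))) == 1))
  # leave-one-subject-out
  f10 <- makeGroupStratifiedFolds(subj, y, 10, seed = 1)
  expect_identical(length(unique(f10)), 10L)
  expect_error(makeGroupStratifiedFolds(subj, y, 11), "exceeds")
  # balanced labels stay within 10 percentage points of global over seeds
  glob <- mean(y)
  for (s in 1:50) {
    fs <- makeGroupStratifiedFolds(subj, y, 5, seed = s)
    rates <- tapply(y, fs, mean)
    expect_true(all(abs(rates - glob) <= 0.10))
  }
})

test_that("nested CV tests each sample once with no subject leakage", {
  tab <- selectionFixture(1, n = 120)
  res <- nestedCV(tab, cvConfig(models = "rf", permutationRepeats = 3),
                  seed = 2,
                  featureCols = c("inf1", "inf2", "noise1"))
  f <- res@folds
  expect_identical(sort(unique(f)), 1:5)
  expect_identical(length(f), nrow(tab))
  for (k in 1:5) {
    inside <- unique(tab$subject_id[f == k])
    outside <- unique(tab$subject_id[f != k])
    expect_length(intersect(inside, outside), 0)
  }
  # fold-metric means match recomputation from stored per-fold values
  fm <- foldMetrics(res)
  expect_equal(cvSummary(res)$auroc,
               mean(fm$auroc[fm$model == "rf"], na.rm = TRUE))
  expect_true(all(fm$auroc >= 0 & fm$auroc <= 1, na.rm = TRUE))
})

test_that("nested CV on permuted labels sits at chance", {
  tab <- selectionFixture(3, n = 160)
  set.seed(9)
  tab$label <- sample(tab$label)
  res <- nestedCV(tab, cvConfig(models = "rf", permutationRepeats = 2),
                  seed = 4, featureCols = c("inf1", "inf2", "noise1"))
  expect_gt(cvSummary(res)$auroc, 0.3)
  expect_lt(cvSummary(res)$auroc, 0.7)
})

test_that("permutation importance ranks signal above noise", {
  set.seed(11)
  n <- 600
  y <- rep(0:1, each = n / 2)
  X <- cbind(signal = y * 2 + rnorm(n), noise1 = rnorm(n),
             noise2 = rnorm(n))
  tr <- seq_len(n) %% 2 == 0   # importance on a held-out fold
  fit <- defacingQC:::fitOne("rf", X[tr, ], y[tr],
                             data.frame(mtry = 2, num.trees = 300), seed = 1)
  imp <- permutationImportance(fit, X[!tr, ], y[!tr], repeats = 20, seed = 2)
  expect_identical(names(which.max(imp)), "signal")
  expect_lt(abs(imp[["noise1"]]), 0.02)
  expect_lt(abs(imp[["noise2"]]), 0.02)
  expect_error(permutationImportance(list(), X, y), "trained")
})

test_that("trained bundles predict, round-trip, and reject schema drift", {
  tab <- selectionFixture(5, n = 160)
  cols <- c("inf1", "inf2", "noise1")
  bundle <- trainDefacingClassifier(tab, model = "xgb",
                                    config = cvConfig(innerFolds = 2),
                                    seed = 6, featureCols = cols)
  pred <- predictDefacing(bundle, tab)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_gt(aurocScore(tab$label, pred$score), 0.8)
  f <- tempfile(fileext = ".rds")
  saveModelBundle(bundle, f)
  reloaded <- readModelBundle(f)
  expect_equal(predictDefacing(reloaded, tab), pred)
  bad <- tab
  names(bad)[names(bad) == "inf1"] <- "renamed"
  expect_error(predictDefacing(bundle, bad), "lacks columns|schema")
})

test_that("a phantom-trained model flags intact faces and passes removals", {
  man <- separabilityManifest(nSubjects = 24, seed = 21)
  tab <- cohortFeatureTable(man, gridSize = 48, noiseSd = 0.02,
                            config = qaConfig(resolution = 64L))
  tab$label <- tab$label_strict
  bundle <- trainDefacingClassifier(tab, model = "rf",
                                    config = cvConfig(), seed = 7)
  ph <- generatePhantom(phantomSpec(gridSize = 48, seed = 99,
                                    subjectSeed = 99))
  untouched <- simulateDefacing(ph, defaceSimSpec(removal = c(
    nose = 0, left_eye = 0, right_eye = 0, mouth = 0)))
  fullGone <- simulateDefacing(ph, defaceSimSpec())
  cfg <- qaConfig(resolution = 64L)
  fU <- pairFeatures(ph@scan, untouched, ph@brainMask, cfg)
  fF <- pairFeatures(ph@scan, fullGone, ph@brainMask, cfg)
  fU$method <- "pydeface"; fF$method <- "pydeface"
  expect_identical(predictDefacing(bundle, fU)$label, 1L)  # face intact
  expect_identical(predictDefacing(bundle, fF)$label, 0L)  # face removed
})
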