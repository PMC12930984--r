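# Shared fixtures, built in code at test time.

# smooth structured random field in [0,1] (Gaussian-filtered white noise)
structuredImage <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm((n + 12)^2), n + 12)
  k <- defacingQC:::gaussKernel1d(2.5, 13)
  y <- defacingQC:::gaussFiltValid(x, k)
  (y - min(y)) / (max(y) - min(y))
}

# brute-force triple-loop oracle for the volumetric measures
bruteVolumetrics <- function(o, d, head, brain, eps = 0) {
  dims <- dim(o)
  hi <- ha <- hr <- bi <- ba <- br <- bb <- 0
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      dif <- abs(o[i, j, k] - d[i, j, k])
      rem <- o[i, j, k] != 0 && d[i, j, k] == 0
      if (head[i, j, k]) {
        hi <- hi + 1
        if (dif > eps) ha <- ha + 1
        if (rem) hr <- hr + 1
      }
      if (brain[i, j, k]) {
        bi <- bi + 1
        if (dif > eps) ba <- ba + 1
        if (rem) br <- br + 1
      }
      if (brain[i, j, k]) bb <- bb + 1
    }
  c(head_impacted_pct = 100 * ha / hi, head_removed_pct = 100 * hr / hi,
    brain_impacted_pct = 100 * ba / bi, brain_removed_pct = 100 * br / bi,
    bhr = bb / hi)
}

# random scan pair on a tiny grid with random masks
randomTinyPair <- function(seed, n = 5L) {
  set.seed(seed)
  o <- array(round(runif(n^3), 2), c(n, n, n))
  d <- o
  flip <- sample(n^3, n^3 %/% 3)
  d[flip] <- ifelse(runif(length(flip)) < 0.5, 0, round(runif(length(flip)), 2))
  brain <- array(FALSE, c(n, n, n))
  brain[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- TRUE
  head <- array(TRUE, c(n, n, n))
  list(o = o, d = d, head = head, brain = brain)
}

# tabular cohort with known informative / redundant / noise features
selectionFixture <- function(seed, n = 200L) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  subj <- paste0("s", rep(seq_len(n / 2), each = 2))
  z <- rnorm(n)
  tab <- data.frame(
    inf1 = y * 1.5 + rnorm(n), inf2 = y * 1.2 + rnorm(n),
    red1 = z, red2 = z + rnorm(n, 0, 0.05), red_dup = z,
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
    label = y, subject_id = subj)
  tab[sample(n), ]
}

# separability cohort: full removal vs two residual features
separabilityManifest <- function(nSubjects = 60L, seed = 11L) {
  generateCohortManifest(
    nSubjects = nSubjects, scansPerSubject = c(1L, 2L), classBalance = 0.5,
    rule = groundTruthRule("strict"), methodsPerScan = 1L,
    successScenarios = c(full = 1), failureScenarios = c(multi = 1),
    seed = seed)
}

pythonBin <- function() Sys.which("python")

runPythonLines <- function(lines, args = character()) {
  f <- tempfile(fileext = ".py")
  writeLines(lines, f)
  out <- system2(pythonBin(), c(f, args), stdout = TRUE, stderr = FALSE)
  unlink(f)
  out
}
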