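#' Generate a synthetic defacing cohort
#'
#' `generateCohortManifest()` draws the cohort design: subjects contribute
#' 1-7 scans each, every scan is defaced by each method in `methods`, and
#' per-entry defacing outcomes (per-feature removal extents, global
#' perturbation, brain clip) are sampled so that the realized share of
#' insufficiently defaced entries under `rule` matches `classBalance`.
#' Strict and lenient labels are derived from the sampled outcomes by
#' [labelDefacing()], so re-deriving labels from the manifest reproduces
#' them exactly. `generateCohort()` additionally materializes the volumes
#' on disk as NIfTI files named `<scan_id>.nii.gz`,
#' `<scan_id>_<method>.nii.gz` and `<scan_id>_{head,brain}mask.nii.gz`,
#' plus `manifest.csv`. `cohortFeatureTable()` regenerates each phantom
#' from the seeds recorded in the manifest and computes the full feature
#' table in memory. Everything is reproducible from the master seed.
#'
#' Failure modes emulated per entry: "clean" (all features removed),
#' "single_minimal" (one feature partially left, removal in [0.5, 0.95)),
#' "single_severe" (one feature largely left, removal < 0.5) and "multi"
#' (two residual features). The mrideface tag additionally applies a tiny
#' global intensity perturbation to every voxel; fsldeface occasionally
#' clips a small fraction of brain voxels.
#'
#' @param nSubjects number of subjects.
#' @param scansPerSubject integer range (min, max) of scans per subject.
#' @param methods defacing method tags to apply to every scan.
#' @param classBalance target fraction of insufficiently defaced entries
#'   under `rule`.
#' @param rule the [groundTruthRule()] the balance refers to.
#' @param methodsPerScan if NULL (default), every scan is defaced by every
#'   method in `methods`; an integer k samples k methods per scan instead.
#' @param successScenarios,failureScenarios named probability vectors over
#'   the outcome scenarios ("full" = every feature removed completely,
#'   "clean" = all features essentially removed, "single_minimal",
#'   "single_severe", "multi" = two residual features) used for entries
#'   targeted as successes/failures under `rule`. Defaults depend on the
#'   criterion (a success under strict must be "full"/"clean"; under
#'   lenient it may also be "single_minimal").
#' @param seed master seed.
#' @return a data.frame manifest with one row per original/defaced entry:
#'   ids, method, sim parameters, seeds and both labels.
#' @export
generateCohortManifest <- function(nSubjects = 20L,
                                   scansPerSubject = c(1L, 7L),
                                   methods = c("pydeface", "quickshear",
                                               "fsldeface", "mrideface"),
                                   classBalance = 0.5,
                                   rule = groundTruthRule("lenient"),
                                   methodsPerScan = NULL,
                                   successScenarios = NULL,
                                   failureScenarios = NULL,
                                   seed = 1L) {
  stopifnot(nSubjects >= 1, classBalance >= 0, classBalance <= 1,
            length(scansPerSubject) == 2, scansPerSubject[1] >= 1)
  if (is.null(successScenarios))
    successScenarios <- if (rule$criterion == "strict") c(clean = 1)
                        else c(clean = 0.6, single_minimal = 0.4)
  if (is.null(failureScenarios))
    failureScenarios <- if (rule$criterion == "strict")
      c(single_minimal = 0.4, single_severe = 0.3, multi = 0.3)
    else c(single_severe = 0.5, multi = 0.5)
  if (rule$criterion == "strict" &&
      !all(names(successScenarios) %in% c("full", "clean")))
    stop("under the strict criterion only 'full'/'clean' outcomes are successes")
  set.seed(childSeed(seed, 11L))
  scanRange <- seq(scansPerSubject[1], scansPerSubject[2])
  nScans <- scanRange[sample.int(length(scanRange), nSubjects,
                                 replace = TRUE)]
  rows <- list()
  for (i in seq_len(nSubjects)) {
    subj <- sprintf("subj%03d", i)
    for (s in seq_len(nScans[i])) {
      sid <- sprintf("%s_s%d", subj, s)
      ms <- if (is.null(methodsPerScan)) methods
            else sample(methods, methodsPerScan)
      for (m in ms) {
        rows[[length(rows) + 1L]] <- data.frame(
          scan_id = sid, subject_id = subj, method = m,
          subject_seed = childSeed(seed, 1000L + i),
          scan_seed = childSeed(seed, 5000L + 10L * i + s))
      }
    }
  }
  man <- do.call(rbind, rows)
  n <- nrow(man)
  nPos <- round(classBalance * n)
  if (nPos > n) stop("unsatisfiable class balance request")
  target <- sample(c(rep(1L, nPos), rep(0L, n - nPos)))
  feats <- featureNames4()
  sim <- matrix(NA_real_, n, 4, dimnames = list(NULL, feats))
  scenario <- character(n)
  drawScenario <- function(p) {
    if (length(p) == 1L) names(p) else sample(names(p), 1, prob = p)
  }
  for (j in seq_len(n)) {
    y <- target[j]
    scn <- drawScenario(if (y == 0) successScenarios else failureScenarios)
    r <- runif(4, rule$residualThreshold, 1)
    if (scn == "full") {
      r <- rep(1, 4)
    } else if (scn == "single_minimal") {
      r[sample(4, 1)] <- runif(1, rule$minimalResidual,
                               rule$residualThreshold - 0.001)
    } else if (scn == "single_severe") {
      r[sample(4, 1)] <- runif(1, 0, rule$minimalResidual - 0.001)
    } else if (scn == "multi") {
      r[sample(4, 2)] <- runif(2, 0, rule$residualThreshold - 0.05)
    }
    sim[j, ] <- r
    scenario[j] <- scn
  }
  man$r_nose <- sim[, "nose"]
  man$r_left_eye <- sim[, "left_eye"]
  man$r_right_eye <- sim[, "right_eye"]
  man$r_mouth <- sim[, "mouth"]
  man$scenario <- scenario
  man$global_perturbation <- ifelse(man$method == "mrideface",
                                    runif(n, 0.001, 0.003), 0)
  man$brain_clip <- ifelse(man$method == "fsldeface" & runif(n) < 0.1,
                           runif(n, 0.01, 0.05), 0)
  man$sim_seed <- childSeed(seed, 9000L + seq_len(n))
  man$label_strict <- vapply(seq_len(n), function(j)
    labelDefacing(manifestSim(man[j, ]), groundTruthRule("strict")),
    integer(1))
  man$label_lenient <- vapply(seq_len(n), function(j)
    labelDefacing(manifestSim(man[j, ]), groundTruthRule("lenient")),
    integer(1))
  realized <- if (rule$criterion == "strict") man$label_strict
              else man$label_lenient
  if (!identical(realized, target))
    stop("scenario mix is inconsistent with the requested class balance ",
         "under the '", rule$criterion, "' criterion")
  rownames(man) <- NULL
  man
}

# rebuild the defaceSimSpec encoded in one manifest row
manifestSim <- function(row) {
  defaceSimSpec(
    removal = c(nose = row$r_nose, left_eye = row$r_left_eye,
                right_eye = row$r_right_eye, mouth = row$r_mouth),
    globalPerturbation = row$global_perturbation,
    brainClip = row$brain_clip, method = row$method, seed = row$sim_seed)
}

manifestPhantom <- function(row, gridSize, noiseSd) {
  generatePhantom(phantomSpec(
    gridSize = gridSize, noiseSd = noiseSd,
    subjectId = row$subject_id, scanId = row$scan_id,
    subjectSeed = row$subject_seed, seed = row$scan_seed))
}

#' @rdname generateCohortManifest
#' @param dir output directory for the NIfTI volumes and manifest.
#' @param gridSize,noiseSd phantom grid size and noise level.
#' @param ... arguments passed to `generateCohortManifest()`.
#' @export
generateCohort <- function(dir, gridSize = 96L, noiseSd = 0.02, ...) {
  man <- generateCohortManifest(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(man$scan_id)) {
    sub <- man[man$scan_id == sid, ]
    ph <- manifestPhantom(sub[1, ], gridSize, noiseSd)
    writeScan(ph@scan, file.path(dir, paste0(sid, ".nii.gz")))
    writeScan(ph@headMask, file.path(dir, paste0(sid, "_headmask.nii.gz")))
    writeScan(ph@brainMask, file.path(dir, paste0(sid, "_brainmask.nii.gz")))
    for (j in seq_len(nrow(sub))) {
      defaced <- simulateDefacing(ph, manifestSim(sub[j, ]))
      writeScan(defaced,
                file.path(dir, paste0(sid, "_", sub$method[j], ".nii.gz")))
    }
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' @rdname generateCohortManifest
#' @param manifest a manifest from `generateCohortManifest()`.
#' @param config a [qaConfig()].
#' @return `cohortFeatureTable()` returns the manifest with the feature
#'   columns (fsim, ssim, rmse, psnr, volumetric measures) appended.
#' @export
cohortFeatureTable <- function(manifest, gridSize = 64L, noiseSd = 0.02,
                               config = qaConfig(resolution = 128L)) {
  out <- vector("list", nrow(manifest))
  for (sid in unique(manifest$scan_id)) {
    idx <- which(manifest$scan_id == sid)
    ph <- manifestPhantom(manifest[idx[1], ], gridSize, noiseSd)
    for (j in idx) {
      defaced <- simulateDefacing(ph, manifestSim(manifest[j, ]))
      feat <- pairFeatures(ph@scan, defaced, ph@brainMask, config)
      out[[j]] <- feat[, setdiff(names(feat), c("scan_id", "subject_id"))]
    }
  }
  cbind(manifest, do.call(rbind, out))
}
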