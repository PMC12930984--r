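#' Full feature vector for one original/defaced scan pair
#'
#' Runs the complete per-pair feature extraction: the head mask is derived
#' from the normalized original at the configured threshold; volumetric
#' impact measures are computed on the raw, orientation-aligned intensities
#' (so a global additive perturbation registers as impact); both scans are
#' rendered from the five standardized views using their own head masks;
#' and the four similarity metrics are aggregated across views.
#'
#' @param orig,defaced \code{\linkS4class{MRIScan}}s on the same grid.
#' @param brain the brain \code{\linkS4class{VoxelMask}} for the original.
#' @param config a [qaConfig()].
#' @return one-row data.frame: scan_id, subject_id, fsim, ssim, rmse, psnr,
#'   head_impacted_pct, head_removed_pct, brain_impacted_pct,
#'   brain_removed_pct, bhr.
#' @export
pairFeatures <- function(orig, defaced, brain, config = qaConfig()) {
  stopifnot(is(orig, "MRIScan"), is(defaced, "MRIScan"), is(brain, "VoxelMask"))
  if (!identical(dim(orig@intensities), dim(defaced@intensities)))
    stop("original and defaced scans must share grid shape; resampling is not supported")
  normOrig <- normalizeScan(orig)
  headO <- headMask(normOrig, config$preprocess)
  vol <- volumetricFeatures(orig, defaced, headO, brain, config$preprocess)
  normDef <- normalizeScan(defaced)
  headD <- headMask(normDef, config$preprocess)
  viewsO <- renderAllViews(normOrig, headO, config$resolution)
  viewsD <- renderAllViews(normDef, headD, config$resolution)
  sim <- similarityFeatures(viewsO, viewsD, config$similarity)
  cbind(data.frame(scan_id = orig@scanId, subject_id = orig@subjectId),
        sim[, c("fsim", "ssim", "rmse", "psnr")], vol)
}

#' Feature table for a directory of original/defaced pairs
#'
#' Pairs files by the `<scan_id>_<method>.nii[.gz]` suffix convention over
#' the four known defacing methods. Each original scan `<scan_id>.nii[.gz]`
#' in `origDir` is matched with every defaced counterpart found in
#' `defacedDir`; a brain mask `<scan_id>_brainmask.nii[.gz]` is read from
#' `maskDir`. Defaced files with unknown suffixes are skipped with a
#' warning; it is an error if no pair is found at all.
#'
#' @param origDir,defacedDir,maskDir input directories.
#' @param config a [qaConfig()].
#' @param subjectMap optional named character vector mapping scan_id to
#'   subject_id (defaults to scan_id, i.e. one scan per subject).
#' @return data.frame with one row per pair, including a `method` column.
#' @export
extractFeatures <- function(origDir, defacedDir, maskDir = defacedDir,
                            config = qaConfig(), subjectMap = NULL) {
  methods4 <- c("pydeface", "quickshear", "fsldeface", "mrideface")
  origs <- list.files(origDir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  origs <- origs[!grepl("_(headmask|brainmask)\\.nii", origs)]
  defs <- list.files(defacedDir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  rows <- list()
  for (of in origs) {
    sid <- sub("\\.nii(\\.gz)?$", "", basename(of))
    cand <- defs[grepl(paste0("^", sid, "_"), basename(defs))]
    cand <- cand[!grepl("_(headmask|brainmask)\\.nii", cand)]
    if (!length(cand)) next
    maskPath <- findNifti(maskDir, paste0(sid, "_brainmask"))
    if (is.na(maskPath)) {
      warning("no brain mask for ", sid, "; skipped")
      next
    }
    subj <- if (!is.null(subjectMap) && sid %in% names(subjectMap))
      subjectMap[[sid]] else sid
    orig <- readScan(of, scanId = sid, subjectId = subj)
    brain <- readMask(maskPath, kind = "brain", scanId = sid)
    for (df in cand) {
      method <- sub(paste0("^", sid, "_"), "",
                    sub("\\.nii(\\.gz)?$", "", basename(df)))
      if (!method %in% methods4) {
        warning("unknown method suffix '", method, "' for ", basename(df),
                "; skipped")
        next
      }
      defaced <- readScan(df, scanId = sid, subjectId = subj)
      feat <- pairFeatures(orig, defaced, brain, config)
      feat$method <- method
      rows[[length(rows) + 1L]] <- feat
    }
  }
  if (!length(rows)) stop("no original/defaced pairs found")
  do.call(rbind, rows)
}

findNifti <- function(dir, stem) {
  for (ext in c(".nii.gz", ".nii")) {
    p <- file.path(dir, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  NA_character_
}
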