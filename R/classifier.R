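#' Train a deployable defacing classifier
#'
#' Tunes one model type by group-stratified k-fold AUROC over its
#' hyperparameter grid, refits the winner on the full data and packages it
#' with its feature schema, scaling parameters and configuration snapshot.
#' Predictions on data whose schema does not match the bundle fail loudly.
#'
#' @param featureTable feature table with label and group columns.
#' @param model model type ("lr", "mlp", "rf" or "xgb"). Default "rf".
#' @param config a [cvConfig()]; `innerFolds` controls the tuning folds.
#' @param seed training seed.
#' @param featureCols,labelCol,groupCol table layout
#'   (see [defaultFeatureColumns()]).
#' @param threshold score threshold for the hard label.
#' @param grids hyperparameter grids.
#' @return a \code{\linkS4class{DefacingModel}}.
#' @export
trainDefacingClassifier <- function(featureTable, model = "rf",
                                    config = cvConfig(), seed = 1L,
                                    featureCols = defaultFeatureColumns(),
                                    labelCol = "label",
                                    groupCol = "subject_id",
                                    threshold = 0.5,
                                    grids = defaultGrids()) {
  X <- buildDesignMatrix(featureTable, featureCols)
  y <- as.integer(featureTable[[labelCol]])
  groups <- as.character(featureTable[[groupCol]])
  best <- tuneInner(model, X, y, groups, grids[[model]],
                    config$innerFolds, childSeed(seed, 3L))
  fit <- fitOne(model, X, y, best, childSeed(seed, 5L))
  new("DefacingModel", fit = fit$fit, modelType = model,
      featureNames = colnames(X),
      scaling = list(center = fit$center, scale = fit$scale),
      threshold = threshold,
      config = list(cv = config, featureCols = featureCols,
                    params = as.list(best)),
      seed = as.integer(seed))
}

#' @rdname trainDefacingClassifier
#' @param object a trained \code{\linkS4class{DefacingModel}}.
#' @param newdata a feature table (or design matrix) with the columns the
#'   model was trained on.
#' @return `predictDefacing()` returns a data.frame with `score` in [0,1]
#'   and the thresholded `label` (1 = insufficiently defaced).
#' @export
predictDefacing <- function(object, newdata) {
  stopifnot(is(object, "DefacingModel"))
  X <- if (is.matrix(newdata)) newdata
       else buildDesignMatrix(newdata, object@config$featureCols)
  if (!identical(colnames(X), object@featureNames))
    stop("feature schema mismatch: model expects [",
         paste(object@featureNames, collapse = ", "), "]")
  inner <- list(type = object@modelType, fit = object@fit,
                center = object@scaling$center,
                scale = object@scaling$scale,
                features = object@featureNames)
  score <- scoreOne(inner, X)
  data.frame(score = score,
             label = as.integer(score >= object@threshold))
}

#' @rdname trainDefacingClassifier
#' @param path file path for the serialized bundle (.rds).
#' @export
saveModelBundle <- function(object, path) {
  stopifnot(is(object, "DefacingModel"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname trainDefacingClassifier
#' @export
readModelBundle <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "DefacingModel")) stop("not a DefacingModel bundle: ", path)
  obj
}
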