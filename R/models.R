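# Uniform wrappers around the four classifier families. Each fit is a list
# (type, fit, params, center, scale, features); linear and neural models are
# standardized with statistics from their own training data, tree models use
# raw features. All stochastic fits are seeded.

defaultGrids <- function() {
  list(
    lr = expand.grid(lambda = c(0.001, 0.01, 0.1)),
    mlp = expand.grid(size = c(3L, 6L), decay = c(0.01, 0.1)),
    rf = expand.grid(mtry = c(2L, 3L), num.trees = 300L),
    xgb = expand.grid(max_depth = c(2L, 3L), nrounds = 60L)
  )
}

fitOne <- function(type, X, y, params, seed) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% 0:1))
  center <- NULL; scl <- NULL
  if (type %in% c("lr", "mlp")) {
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    X <- scale(X, center, scl)
  }
  set.seed(childSeed(seed, 17L))
  fit <- switch(type,
    lr = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = params$lambda, standardize = FALSE),
    mlp = nnet::nnet(x = X, y = y, size = params$size, decay = params$decay,
                     maxit = 250, trace = FALSE, entropy = TRUE),
    rf = ranger::ranger(x = X, y = factor(y, levels = 0:1),
                        num.trees = params$num.trees,
                        mtry = min(params$mtry, ncol(X)),
                        probability = TRUE, seed = childSeed(seed, 19L),
                        num.threads = 1),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = 0.3, nthread = 1, seed = childSeed(seed, 23L)),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    stop("unknown model type: ", type)
  )
  list(type = type, fit = fit, params = params, center = center,
       scale = scl, features = colnames(X))
}

scoreOne <- function(model, X) {
  stopifnot(is.list(model), !is.null(model$type), !is.null(model$fit))
  if (!identical(colnames(X), model$features))
    stop("feature schema mismatch: model expects [",
         paste(model$features, collapse = ", "), "]")
  if (!is.null(model$center)) X <- scale(X, model$center, model$scale)
  as.vector(switch(model$type,
    lr = predict(model$fit, X, type = "response"),
    mlp = predict(model$fit, X),
    rf = predict(model$fit, data = X, num.threads = 1)$predictions[, "1"],
    xgb = predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1))
  ))
}

#' Default modeling feature columns
#'
#' The standard 11-feature layout: the four similarity metrics, three
#' volumetric measures (head loss, brain loss and the brain-to-head ratio),
#' and — when `includeMethods` — four one-hot defacing-method indicators
#' appended by [buildDesignMatrix()].
#'
#' @param includeMethods include the defacing-method one-hot block.
#' @return character vector of feature-table column names.
#' @export
defaultFeatureColumns <- function(includeMethods = TRUE) {
  base <- c("fsim", "ssim", "rmse", "psnr",
            "head_removed_pct", "brain_removed_pct", "bhr")
  if (includeMethods) c(base, "method") else base
}

#' Build the numeric design matrix from a feature table
#'
#' Numeric columns are used as-is; a `method` column expands into one-hot
#' indicators `method_pydeface`, `method_quickshear`, `method_fsldeface`,
#' `method_mrideface` (exactly one indicator is 1 per row).
#'
#' @param featureTable data.frame of per-pair features.
#' @param featureCols columns to use; see [defaultFeatureColumns()].
#' @return numeric matrix with named columns.
#' @export
buildDesignMatrix <- function(featureTable,
                              featureCols = defaultFeatureColumns()) {
  missing <- setdiff(featureCols, names(featureTable))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  numCols <- setdiff(featureCols, "method")
  X <- as.matrix(featureTable[, numCols, drop = FALSE])
  storage.mode(X) <- "double"
  if ("method" %in% featureCols) {
    methods4 <- c("pydeface", "quickshear", "fsldeface", "mrideface")
    onehot <- vapply(methods4, function(m)
      as.double(featureTable$method == m), numeric(nrow(featureTable)))
    onehot <- matrix(onehot, nrow = nrow(featureTable),
                     dimnames = list(NULL, paste0("method_", methods4)))
    X <- cbind(X, onehot)
  }
  if (!all(is.finite(X))) stop("non-finite values in the design matrix")
  X
}
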