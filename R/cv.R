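#' Binary classification metrics
#'
#' Computes accuracy, sensitivity, specificity, precision and AUROC from
#' ground-truth labels and scores. The positive class is y = 1
#' (insufficiently defaced): a privacy failure is the event of interest, so
#' sensitivity is the rate at which residual faces are caught. AUROC uses
#' the rank (Mann-Whitney) statistic with average ranks, which applies the
#' standard tie correction; with single-class truth it is undefined and
#' returned as NA.
#'
#' @param truth 0/1 vector.
#' @param scores numeric scores, higher = more likely insufficient.
#' @param threshold score threshold for the hard label. Default 0.5.
#' @return one-row data.frame of the five metrics.
#' @examples
#' classificationMetrics(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.9))
#' @export
classificationMetrics <- function(truth, scores, threshold = 0.5) {
  stopifnot(length(truth) == length(scores), all(truth %in% 0:1))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  data.frame(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    auroc = aurocScore(truth, scores)
  )
}

#' @rdname classificationMetrics
#' @export
aurocScore <- function(truth, scores) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)   # average ranks: tie-corrected Mann-Whitney
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified group k-fold assignment
#'
#' Partitions samples into k folds such that no subject spans folds and
#' per-fold class proportions stay as close to the global proportion as the
#' group constraint permits. Subjects are assigned greedily, largest first
#' (random tie order from the seed), each to the fold that minimizes the
#' resulting class-balance deviation with a mild size-balance penalty.
#'
#' @param subjects group key per sample.
#' @param y 0/1 label per sample.
#' @param k number of folds; must not exceed the number of subjects.
#' @param seed seed for tie-breaking.
#' @return integer fold assignment (1..k) per sample.
#' @export
makeGroupStratifiedFolds <- function(subjects, y, k, seed = 1L) {
  stopifnot(length(subjects) == length(y), all(y %in% 0:1), k >= 2)
  us <- unique(as.character(subjects))
  if (k > length(us))
    stop("k = ", k, " exceeds the number of subjects (", length(us), ")")
  n <- tapply(rep(1L, length(y)), as.character(subjects), sum)[us]
  pos <- tapply(y, as.character(subjects), sum)[us]
  set.seed(childSeed(seed, 77L))
  ord <- order(-n, sample(length(us)))
  globalRate <- sum(y) / length(y)
  targetSize <- length(y) / k
  foldN <- numeric(k)
  foldPos <- numeric(k)
  assign <- integer(length(us))
  for (i in ord) {
    obj <- vapply(seq_len(k), function(f) {
      nn <- foldN[f] + n[i]
      pp <- foldPos[f] + pos[i]
      abs(pp / nn - globalRate) + 0.5 * nn / targetSize
    }, numeric(1))
    f <- which.min(obj)
    assign[i] <- f
    foldN[f] <- foldN[f] + n[i]
    foldPos[f] <- foldPos[f] + pos[i]
  }
  assign[match(as.character(subjects), us)]
}

#' Nested stratified group k-fold cross-validation
#'
#' The outer loop estimates generalization: each sample is tested exactly
#' once, and all scans of one subject stay in one fold. Within each outer
#' training set, an inner group-stratified loop tunes each model's
#' hyperparameters by mean inner AUROC; the winning configuration is
#' refitted on the full outer-training set and evaluated on the held-out
#' outer fold. Metrics are averaged (with sd) over outer folds; outer folds
#' where AUROC is undefined (single-class truth) are excluded from the
#' AUROC mean with a warning. Permutation feature importances (mean AUROC
#' drop on the outer test fold) are computed for the tree-ensemble models
#' and averaged across folds.
#'
#' @param featureTable data.frame with the feature columns plus `labelCol`
#'   and `groupCol`.
#' @param config a [cvConfig()].
#' @param seed master seed; folds, model fits and permutations derive from
#'   it.
#' @param featureCols feature columns ([defaultFeatureColumns()]).
#' @param labelCol,groupCol label (0/1) and subject-id column names.
#' @param grids named list of hyperparameter grids per model.
#' @param importanceModels models for which permutation importance is
#'   computed.
#' @return a \code{\linkS4class{NestedCVResult}}.
#' @export
nestedCV <- function(featureTable, config = cvConfig(), seed = 1L,
                     featureCols = defaultFeatureColumns(),
                     labelCol = "label", groupCol = "subject_id",
                     grids = defaultGrids(),
                     importanceModels = c("rf", "xgb")) {
  X <- buildDesignMatrix(featureTable, featureCols)
  y <- as.integer(featureTable[[labelCol]])
  groups <- as.character(featureTable[[groupCol]])
  stopifnot(all(y %in% 0:1))
  if (length(unique(groups[y == 1])) < 2 || length(unique(groups[y == 0])) < 2)
    stop("need at least 2 subjects per class for nested CV")
  kOut <- config$outerFolds
  outer <- makeGroupStratifiedFolds(groups, y, kOut, seed)
  foldRows <- list()
  impRows <- list()
  for (m in config$models) {
    grid <- grids[[m]]
    if (is.null(grid) || !nrow(grid)) stop("empty hyperparameter grid for ", m)
    for (f in seq_len(kOut)) {
      tr <- which(outer != f)
      te <- which(outer == f)
      best <- tuneInner(m, X[tr, , drop = FALSE], y[tr], groups[tr],
                        grid, config$innerFolds, childSeed(seed, 100L * f))
      fit <- fitOne(m, X[tr, , drop = FALSE], y[tr], best,
                    childSeed(seed, 100L * f + 1L))
      sc <- scoreOne(fit, X[te, , drop = FALSE])
      met <- classificationMetrics(y[te], sc)
      foldRows[[length(foldRows) + 1L]] <-
        cbind(data.frame(model = m, fold = f), met)
      if (m %in% importanceModels) {
        imp <- permutationImportance(fit, X[te, , drop = FALSE], y[te],
                                     repeats = config$permutationRepeats,
                                     seed = childSeed(seed, 100L * f + 2L))
        impRows[[length(impRows) + 1L]] <-
          data.frame(model = m, fold = f, feature = names(imp),
                     importance = unname(imp))
      }
    }
  }
  foldMetrics <- do.call(rbind, foldRows)
  if (anyNA(foldMetrics$auroc))
    warning("AUROC undefined in ", sum(is.na(foldMetrics$auroc)),
            " outer fold(s); excluded from the mean")
  metricCols <- c("accuracy", "sensitivity", "specificity", "precision",
                  "auroc")
  summ <- do.call(rbind, lapply(split(foldMetrics, foldMetrics$model),
    function(d) {
      means <- colMeans(d[metricCols], na.rm = TRUE)
      sds <- apply(d[metricCols], 2, sd, na.rm = TRUE)
      cbind(data.frame(model = d$model[1]),
            as.data.frame(as.list(means)),
            setNames(as.data.frame(as.list(sds)),
                     paste0(metricCols, "_sd")))
    }))
  summ <- summ[match(config$models, summ$model), ]
  rownames(summ) <- NULL
  importance <- if (length(impRows)) {
    allImp <- do.call(rbind, impRows)
    agg <- aggregate(importance ~ model + feature, allImp, mean)
    agg[order(agg$model, -agg$importance), ]
  } else data.frame(model = character(), feature = character(),
                    importance = numeric())
  rownames(importance) <- NULL
  new("NestedCVResult", foldMetrics = foldMetrics, summary = summ,
      importance = importance, folds = as.integer(outer),
      config = config, seed = as.integer(seed))
}

tuneInner <- function(type, X, y, groups, grid, kIn, seed) {
  kIn <- min(kIn, length(unique(groups)))
  if (nrow(grid) == 1L || kIn < 2) return(grid[1, , drop = FALSE])
  inner <- makeGroupStratifiedFolds(groups, y, kIn, seed)
  perf <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(kIn), function(f) {
      tr <- which(inner != f)
      va <- which(inner == f)
      if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2)
        return(NA_real_)
      fit <- fitOne(type, X[tr, , drop = FALSE], y[tr],
                    grid[g, , drop = FALSE], childSeed(seed, g))
      aurocScore(y[va], scoreOne(fit, X[va, , drop = FALSE]))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  perf[is.nan(perf)] <- -Inf
  grid[which.max(perf), , drop = FALSE]
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean drop in test-fold AUROC when that
#' feature's column is shuffled, over `repeats` seeded shuffles. A feature
#' the model ignores scores near 0.
#'
#' @param model a fitted model as produced inside [nestedCV()] or by
#'   [trainDefacingClassifier()].
#' @param X design matrix of the evaluation fold (schema must match).
#' @param y 0/1 truth for the fold.
#' @param repeats shuffles per feature.
#' @param seed shuffle seed.
#' @return named numeric vector of mean AUROC drops per feature.
#' @export
permutationImportance <- function(model, X, y, repeats = 10L, seed = 1L) {
  if (is(model, "DefacingModel"))
    model <- list(type = model@modelType, fit = model@fit,
                  center = model@scaling$center, scale = model@scaling$scale,
                  features = model@featureNames)
  if (!is.list(model) || is.null(model$fit))
    stop("permutationImportance requires a trained model")
  base <- aurocScore(y, scoreOne(model, X))
  set.seed(childSeed(seed, 55L))
  drops <- vapply(colnames(X), function(j) {
    mean(vapply(seq_len(repeats), function(r) {
      Xp <- X
      Xp[, j] <- Xp[sample(nrow(X)), j]
      base - aurocScore(y, scoreOne(model, Xp))
    }, numeric(1)))
  }, numeric(1))
  drops
}
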