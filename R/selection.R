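#' Spearman correlation structure of a feature set
#'
#' Computes the Spearman rank-order correlation matrix (average ranks for
#' ties) over the design-matrix columns and an average-linkage hierarchical
#' clustering on the distance 1 - |rho|. Features merging below the cluster
#' threshold (default 0.2, i.e. |rho| > 0.8) form redundancy clusters.
#' Pairs involving a constant feature have undefined rank correlation;
#' these entries are recorded as 0 with a warning.
#'
#' @param X numeric matrix or a feature table plus `featureCols`.
#' @param featureCols columns to use when `X` is a data.frame.
#' @param threshold dendrogram height below which features cluster.
#' @return list with `rho` (correlation matrix), `hclust` (merge tree) and
#'   `clusters` (integer cluster id per feature at the threshold).
#' @examples
#' X <- cbind(a = rnorm(30), b = rnorm(30))
#' X <- cbind(X, a2 = X[, "a"])   # exact duplicate
#' cs <- correlationStructure(X)
#' cs$clusters                    # a and a2 share a cluster
#' @export
correlationStructure <- function(X, featureCols = defaultFeatureColumns(),
                                 threshold = 0.2) {
  if (is.data.frame(X)) X <- buildDesignMatrix(X, featureCols)
  stopifnot(is.matrix(X), ncol(X) >= 2)
  suppressWarnings(rho <- cor(X, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant feature(s): undefined Spearman correlations recorded as 0")
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
  }
  d <- as.dist(1 - abs(rho))
  hc <- hclust(d, method = "average")
  clusters <- cutree(hc, h = threshold)
  list(rho = rho, hclust = hc, clusters = clusters, threshold = threshold)
}

#' Iterative redundancy-aware feature selection
#'
#' Alternates between (i) nested-CV permutation importances averaged over
#' outer folds and (ii) Spearman redundancy clusters. Each iteration drops
#' features for one of the two reasons, redundancy first: while clusters of
#' highly correlated features exist, every cluster keeps only its
#' highest-importance member; once no cluster remains, features below the
#' importance floor are dropped. The model is retrained on the reduced set. A reduction is kept
#' when the mean outer AUROC does not decrease (ties accepted, judged at
#' `tieTolerance` because the fold-mean AUROC of a stochastic learner is
#' itself noisy); otherwise it is reverted and the loop stops. All
#' iterations are evaluated on the same outer folds. Deterministic given
#' the seed; the full history is returned.
#'
#' @param featureTable feature table with label and group columns.
#' @param config a [cvConfig()]; `corThreshold`, `importanceFloor` and
#'   `maxIterations` control the loop.
#' @param seed master seed.
#' @param model single model type driving importances and AUROC (a
#'   tree ensemble; default "rf").
#' @param featureCols starting feature columns.
#' @param labelCol,groupCol label and subject-id columns.
#' @param grids hyperparameter grids (see [nestedCV()]).
#' @param tieTolerance AUROC decrease still accepted as a tie.
#' @return list with `selected` (design-matrix column names retained),
#'   `history` (per-iteration data.frame: iteration, nFeatures, auroc,
#'   dropped) and `finalAUROC`.
#' @export
iterativeFeatureSelection <- function(featureTable, config = cvConfig(),
                                      seed = 1L, model = "rf",
                                      featureCols = defaultFeatureColumns(),
                                      labelCol = "label",
                                      groupCol = "subject_id",
                                      grids = defaultGrids(),
                                      tieTolerance = 0.01) {
  X <- buildDesignMatrix(featureTable, featureCols)
  y <- as.integer(featureTable[[labelCol]])
  groups <- as.character(featureTable[[groupCol]])
  cfg1 <- config
  cfg1$models <- model
  evalSet <- function(cols) {
    tab <- cbind(as.data.frame(X[, cols, drop = FALSE]),
                 setNames(data.frame(y, groups, stringsAsFactors = FALSE),
                          c(labelCol, groupCol)))
    res <- nestedCV(tab, cfg1, seed = childSeed(seed, 7L),
                    featureCols = cols, labelCol = labelCol,
                    groupCol = groupCol, grids = grids,
                    importanceModels = model)
    imp <- res@importance
    list(auroc = res@summary$auroc[1],
         importance = setNames(imp$importance, imp$feature)[cols])
  }
  current <- colnames(X)
  cur <- evalSet(current)
  history <- data.frame(iteration = 0L, nFeatures = length(current),
                        auroc = cur$auroc, dropped = "")
  for (it in seq_len(config$maxIterations)) {
    drop <- character()
    if (length(current) >= 2) {
      cs <- correlationStructure(X[, current, drop = FALSE],
                                 threshold = 1 - config$corThreshold)
      for (cl in unique(cs$clusters)) {
        members <- names(cs$clusters)[cs$clusters == cl]
        if (length(members) > 1) {
          keep <- members[which.max(cur$importance[members])]
          drop <- c(drop, setdiff(members, keep))
        }
      }
    }
    if (!length(drop)) {
      # no redundancy clusters left: prune uninformative features
      drop <- names(cur$importance)[cur$importance < config$importanceFloor]
    }
    drop <- intersect(drop, current)
    # never eliminate the whole feature set
    if (length(drop) >= length(current))
      drop <- setdiff(drop, names(which.max(cur$importance)))
    if (!length(drop)) break
    candidate <- setdiff(current, drop)
    if (!length(candidate)) stop("feature selection eliminated all features")
    cand <- evalSet(candidate)
    if (cand$auroc >= cur$auroc - tieTolerance) {
      current <- candidate
      cur <- cand
      history <- rbind(history,
        data.frame(iteration = it, nFeatures = length(current),
                   auroc = cand$auroc,
                   dropped = paste(drop, collapse = ";")))
    } else {
      history <- rbind(history,
        data.frame(iteration = it, nFeatures = length(current),
                   auroc = cur$auroc,
                   dropped = paste0("reverted:", paste(drop, collapse = ";"))))
      break
    }
  }
  list(selected = current, history = history, finalAUROC = cur$auroc)
}
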