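#' @importFrom ranger ranger
NULL

#' Random-forest configuration
#'
#' Settings for the classification harness: 1000 trees, minimum leaf size 5,
#' unlimited depth, square-root of the feature count sampled per split, 10
#' stratified cross-validation folds and 10 random repetitions. The split
#' impurity criterion is Gini.
#'
#' @param nTrees number of trees per forest.
#' @param minNodeSize minimum samples per leaf.
#' @param cvFolds folds for within-dataset cross-validation.
#' @param nRepeats random repetitions per experiment.
#' @param seed integer master seed; all ensemble/fold seeds derive from it.
#' @param ciDf degrees of freedom for the t-based AUC confidence interval;
#'   \code{NULL} uses (number of AUC values - 1). The original matrices used
#'   the literal product (datasets x randomizations) - 1, which can be
#'   passed here explicitly.
#' @return a list of class \code{"RfConfig"}.
#' @export
rfConfig <- function(nTrees = 1000, minNodeSize = 5, cvFolds = 10,
                     nRepeats = 10, seed = 1, ciDf = NULL) {
  stopifnot(nTrees > 0, minNodeSize > 0, cvFolds > 1, nRepeats > 0)
  structure(list(nTrees = nTrees, minNodeSize = minNodeSize,
                 cvFolds = cvFolds, nRepeats = nRepeats,
                 seed = as.integer(seed), ciDf = ciDf),
            class = "RfConfig")
}

# deterministic child seeds, kept within 32-bit integer range
.childSeed <- function(seed, ...) {
  off <- sum(unlist(list(...)) * (31L^seq_along(unlist(list(...)))))
  as.integer((as.double(seed) * 7919 + off) %% 2147483629)
}

# rank-sum (Mann-Whitney) AUC of scores for the positive class; ties averaged
.wilcoxAUC <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class test set")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.fitForest <- function(x, y, config, seed) {
  df <- data.frame(t(x))
  df$.class <- factor(ifelse(y, "high_fat", "low_fat"),
                      levels = c("low_fat", "high_fat"))
  ranger(dependent.variable.name = ".class", data = df,
         num.trees = config$nTrees, min.node.size = config$minNodeSize,
         mtry = max(1L, floor(sqrt(nrow(x)))), probability = TRUE,
         importance = "impurity", seed = seed, num.threads = 1)
}

.scoreForest <- function(fit, x) {
  stats::predict(fit, data = data.frame(t(x)), num.threads = 1)$predictions[, "high_fat"]
}

.aucCI <- function(aucs, ciDf = NULL) {
  m <- mean(aucs)
  if (length(aucs) < 2 || sd(aucs) == 0) return(c(m, m, m))
  df <- if (is.null(ciDf)) length(aucs) - 1 else ciDf
  half <- qt(0.975, df) * sd(aucs) / sqrt(length(aucs))
  c(m, m - half, m + half)
}

# stratified fold assignment: each class split as evenly as possible
.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select ML-eligible samples and datasets
#'
#' Keeps the baseline timepoint per mouse (earliest; missing timepoints are
#' treated as baseline), optionally drops antibiotic-treated samples, and
#' retains datasets with at least \code{minPerClass} samples in each diet
#' class (or in total, with \code{perClass = FALSE}).
#'
#' @param meta per-sample metadata (\code{data.frame}/\code{DataFrame}).
#' @param excludeAntibiotics drop samples under antibiotic treatment.
#' @param minPerClass sample-count threshold (default 20).
#' @param perClass interpret the threshold per diet class (default) or on
#'   the dataset total.
#' @return \code{list(samples = , datasets = )} of retained IDs.
#' @export
selectEligible <- function(meta, excludeAntibiotics = TRUE, minPerClass = 20,
                           perClass = TRUE) {
  md <- as.data.frame(meta)
  if (is.null(md$sample_id)) md$sample_id <- rownames(md)
  if (!is.null(md$timepoint) && !is.null(md$mouse_id)) {
    tp <- md$timepoint
    tp[is.na(tp)] <- -Inf
    baseline <- unlist(lapply(split(seq_len(nrow(md)), md$mouse_id),
                              function(i) i[which.min(tp[i])]))
    md <- md[sort(baseline), , drop = FALSE]
  }
  if (excludeAntibiotics && !is.null(md$antibiotics))
    md <- md[!md$antibiotics %in% TRUE, , drop = FALSE]
  keep <- vapply(split(md$diet_class, md$dataset_id), function(cl) {
    if (perClass)
      sum(cl == "high_fat") >= minPerClass && sum(cl == "low_fat") >= minPerClass
    else length(cl) >= minPerClass
  }, logical(1))
  datasets <- names(keep)[keep]
  list(samples = md$sample_id[md$dataset_id %in% datasets],
       datasets = datasets)
}

#' Within-dataset cross-validated AUC
#'
#' Stratified \code{cvFolds}-fold cross-validation repeated
#' \code{nRepeats} times (default 10 x 10 = 100 held-out AUC values) with a
#' random-forest classifier on transformed abundances. If a class has fewer
#' samples than \code{cvFolds}, the fold count is reduced with a warning.
#'
#' @param x transformed features-x-samples matrix.
#' @param labels \code{"high_fat"}/\code{"low_fat"} per sample (or logical,
#'   TRUE = high fat).
#' @param config an \code{\link{rfConfig}}.
#' @return \code{list(auc, ci_low, ci_high, aucs)}.
#' @export
runCV <- function(x, labels, config = rfConfig()) {
  y <- if (is.logical(labels)) labels else labels == "high_fat"
  k <- config$cvFolds
  minClass <- min(sum(y), sum(!y))
  if (minClass < 2) stop("both classes need >= 2 samples")
  if (minClass < k) {
    warning("class with fewer samples than folds; reducing folds to ", minClass)
    k <- minClass
  }
  aucs <- numeric(0)
  for (r in seq_len(config$nRepeats)) {
    fold <- .stratifiedFolds(y, k, .childSeed(config$seed, r, 1))
    for (f in seq_len(k)) {
      te <- fold == f
      fit <- .fitForest(x[, !te, drop = FALSE], y[!te], config,
                        .childSeed(config$seed, r, f, 2))
      aucs <- c(aucs, .wilcoxAUC(.scoreForest(fit, x[, te, drop = FALSE]), y[te]))
    }
  }
  ci <- .aucCI(aucs, config$ciDf)
  list(auc = ci[1], ci_low = ci[2], ci_high = ci[3], aucs = aucs)
}

#' Align two feature spaces by feature-ID union
#'
#' Missing features are filled with 0 (a genuine absence on the
#' relative-abundance scale).
#'
#' @param a,b features-x-samples matrices with feature IDs as row names.
#' @return list of the two matrices on the union feature space.
#' @export
alignFeatures <- function(a, b) {
  feats <- union(rownames(a), rownames(b))
  pad <- function(m) {
    out <- matrix(0, length(feats), ncol(m), dimnames = list(feats, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  list(pad(a), pad(b))
}

#' Cross-dataset transfer AUC
#'
#' Trains on one cohort and tests on another, repeated
#' \code{config$nRepeats} times with different ensemble seeds; the feature
#' spaces are aligned by union with zero fill.
#'
#' @param trainX,testX transformed features-x-samples matrices.
#' @param trainY,testY diet labels.
#' @param config an \code{\link{rfConfig}}.
#' @return \code{list(auc, ci_low, ci_high, aucs)}.
#' @export
runTransfer <- function(trainX, trainY, testX, testY, config = rfConfig()) {
  yTr <- if (is.logical(trainY)) trainY else trainY == "high_fat"
  yTe <- if (is.logical(testY)) testY else testY == "high_fat"
  if (length(unique(yTe)) < 2) stop("AUC undefined: test set has one class")
  al <- alignFeatures(trainX, testX)
  aucs <- vapply(seq_len(config$nRepeats), function(r) {
    fit <- .fitForest(al[[1]], yTr, config, .childSeed(config$seed, r, 3))
    .wilcoxAUC(.scoreForest(fit, al[[2]]), yTe)
  }, numeric(1))
  ci <- .aucCI(aucs, config$ciDf)
  list(auc = ci[1], ci_low = ci[2], ci_high = ci[3], aucs = aucs)
}

#' Leave-one-dataset-out AUC and averaged feature ranking
#'
#' Each cohort is iteratively held out while a forest is trained on the
#' pooled remaining cohorts (10 repeats per left-out cohort). The feature
#' ranking averages, over all training runs, the rank of each feature's
#' impurity importance (rank 1 = most important); it is computed from
#' training data only, so the held-out cohort never influences it.
#'
#' @param x transformed features-x-samples matrix.
#' @param labels diet labels per sample.
#' @param datasets dataset ID per sample (>= 2 datasets).
#' @param config an \code{\link{rfConfig}}.
#' @return \code{list(auc = data.frame(dataset, auc, ci_low, ci_high),
#'   ranking = named numeric of average ranks, aucs = per-dataset list)}.
#' @export
runLODO <- function(x, labels, datasets, config = rfConfig()) {
  y <- if (is.logical(labels)) labels else labels == "high_fat"
  datasets <- as.character(datasets)
  ds <- unique(datasets)
  if (length(ds) < 2) stop("need >= 2 datasets for LODO")
  rankSum <- numeric(nrow(x))
  nModels <- 0L
  rows <- list(); aucsAll <- list()
  for (d in ds) {
    te <- datasets == d
    aucs <- numeric(config$nRepeats)
    for (r in seq_len(config$nRepeats)) {
      fit <- .fitForest(x[, !te, drop = FALSE], y[!te], config,
                        .childSeed(config$seed, r, match(d, ds), 4))
      aucs[r] <- .wilcoxAUC(.scoreForest(fit, x[, te, drop = FALSE]), y[te])
      imp <- fit$variable.importance[rownames(x)]
      rankSum <- rankSum + rank(-imp, ties.method = "average")
      nModels <- nModels + 1L
    }
    ci <- .aucCI(aucs, config$ciDf)
    rows[[d]] <- data.frame(dataset = d, auc = ci[1],
                            ci_low = ci[2], ci_high = ci[3])
    aucsAll[[d]] <- aucs
  }
  ranking <- rankSum / nModels
  names(ranking) <- rownames(x)
  list(auc = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       ranking = ranking, aucs = aucsAll)
}

#' PredictionGrid: train-by-test AUC matrix with LODO row
#'
#' Holds the cross-prediction AUC grid: one row per training cohort plus a
#' final \code{"LODO"} row, one column per test cohort; the diagonal holds
#' within-cohort cross-validation values. Per-cell t-based confidence
#' bounds are stored alongside.
#'
#' @aliases PredictionGrid-class aucMatrix
#' @exportClass PredictionGrid
setClass("PredictionGrid",
         representation(auc = "matrix", ciLow = "matrix", ciHigh = "matrix",
                        datasets = "character"))

setValidity("PredictionGrid", function(object) {
  d <- length(object@datasets)
  if (!all(dim(object@auc) == c(d + 1L, d)))
    return("AUC grid must be (D+1) x D with the LODO row last")
  ok <- is.na(object@auc) | (object@auc >= 0 & object@auc <= 1)
  if (!all(ok)) return("AUC values must lie in [0, 1]")
  TRUE
})

#' @describeIn PredictionGrid the AUC matrix ((D+1) x D, LODO row last).
#' @param x a \code{PredictionGrid}.
#' @export
aucMatrix <- function(x) x@auc

setMethod("show", "PredictionGrid", function(object) {
  cat("PredictionGrid:", length(object@datasets),
      "cohorts (+ LODO row); mean AUC",
      round(mean(object@auc, na.rm = TRUE), 3), "\n")
  print(round(object@auc, 3))
})

#' Assemble the full cross-prediction matrix
#'
#' Diagonal cells from \code{\link{runCV}}, off-diagonal cells from
#' \code{\link{runTransfer}}, bottom row from \code{\link{runLODO}}.
#'
#' @inheritParams runLODO
#' @return a \code{\linkS4class{PredictionGrid}}; the LODO feature ranking
#'   is attached as attribute \code{"ranking"}.
#' @export
crossPredictionMatrix <- function(x, labels, datasets, config = rfConfig()) {
  datasets <- as.character(datasets)
  ds <- unique(datasets)
  if (length(ds) < 2) stop("need >= 2 datasets")
  d <- length(ds)
  auc <- ciL <- ciH <- matrix(NA_real_, d + 1, d,
                              dimnames = list(c(ds, "LODO"), ds))
  y <- if (is.logical(labels)) labels else labels == "high_fat"
  for (i in seq_len(d)) for (j in seq_len(d)) {
    tr <- datasets == ds[i]; te <- datasets == ds[j]
    res <- if (i == j) runCV(x[, tr, drop = FALSE], y[tr], config)
           else runTransfer(x[, tr, drop = FALSE], y[tr],
                            x[, te, drop = FALSE], y[te], config)
    auc[i, j] <- res$auc; ciL[i, j] <- res$ci_low; ciH[i, j] <- res$ci_high
  }
  lodo <- runLODO(x, y, datasets, config)
  auc[d + 1, lodo$auc$dataset] <- lodo$auc$auc
  ciL[d + 1, lodo$auc$dataset] <- lodo$auc$ci_low
  ciH[d + 1, lodo$auc$dataset] <- lodo$auc$ci_high
  out <- new("PredictionGrid", auc = auc, ciLow = ciL, ciHigh = ciH,
             datasets = ds)
  attr(out, "ranking") <- lodo$ranking
  out
}
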