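# small config keeps forests cheap; properties do not depend on tree count
testCfg <- function(seed = 1, ...) rfConfig(nTrees = 60, nRepeats = 2, seed = seed, ...)

# separable two-cohort toy: biomarkers shifted by `shift` under high fat
makeMLData <- function(nDatasets = 2, nPerArm = 12, nFeatures = 30,
                       nBio = 5, shift = 0.12, seed = 1) {
  set.seed(seed)
  n <- nDatasets * 2 * nPerArm
  datasets <- rep(sprintf("D%d", seq_len(nDatasets)), each = 2 * nPerArm)
  diet <- rep(rep(c("high_fat", "low_fat"), each = nPerArm), nDatasets)
  x <- matrix(rnorm(nFeatures * n, 0.3, 0.03), nFeatures, n,
              dimnames = list(sprintf("SGB%03d", seq_len(nFeatures)),
                              sprintf("s%03d", seq_len(n))))
  x[seq_len(nBio), diet == "high_fat"] <-
    x[seq_len(nBio), diet == "high_fat"] + shift
  list(x = pmax(x, 0), datasets = datasets, diet = diet)
}

test_that("eligibility selection applies baseline, antibiotic and size rules", {
  md <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    dataset_id = c(rep("A", 8), rep("B", 4)),
    diet_class = c(rep(c("high_fat", "low_fat"), 4), rep("high_fat", 3), "low_fat"),
    antibiotics = c(rep(FALSE, 7), TRUE, rep(FALSE, 4)),
    mouse_id = c(paste0("m", 1:6), "m1", "m7", rep("m8", 3), "m9"),
    timepoint = c(rep(1L, 6), 2L, 1L, 1:3, 1L))
  sel1 <- selectEligible(md, excludeAntibiotics = TRUE, minPerClass = 1)
  # s07 is mouse m1 at timepoint 2 -> dropped; s08 on antibiotics -> dropped
  expect_false("s07" %in% sel1$samples)
  expect_false("s08" %in% sel1$samples)
  # mouse m8 has 3 timepoints; only the earliest (s09) is retained
  expect_true("s09" %in% sel1$samples)
  expect_false(any(c("s10", "s11") %in% sel1$samples))
  # B retains 1 high_fat + 1 low_fat baseline -> ineligible at 2 per class
  sel <- selectEligible(md, excludeAntibiotics = TRUE, minPerClass = 2)
  expect_identical(sel$datasets, "A")
  expect_false(any(c("s09", "s12") %in% sel$samples))

  # threshold boundary: 19 high-fat samples fails a 20-per-class rule
  md2 <- data.frame(sample_id = sprintf("t%02d", 1:49),
                    dataset_id = "C",
                    diet_class = rep(c("high_fat", "low_fat"), c(19, 30)))
  expect_length(selectEligible(md2, minPerClass = 20)$datasets, 0)
  expect_identical(selectEligible(md2, minPerClass = 19)$datasets, "C")
  expect_identical(selectEligible(md2, minPerClass = 20, perClass = FALSE)$datasets, "C")
})

test_that("cross-validation separates signal from null and is deterministic", {
  d <- makeMLData(nDatasets = 1, nPerArm = 15, shift = 0.15, seed = 2)
  cv <- runCV(d$x, d$diet, testCfg(seed = 3))
  expect_gt(cv$auc, 0.9)
  expect_length(cv$aucs, 20)             # folds x repeats
  # same seed twice -> identical result
  cv2 <- runCV(d$x, d$diet, testCfg(seed = 3))
  expect_identical(cv$aucs, cv2$aucs)
  # featureless null: labels independent of every feature
  d0 <- makeMLData(nDatasets = 1, nPerArm = 15, shift = 0, seed = 4)
  nullAuc <- runCV(d0$x, d0$diet, testCfg(seed = 5))$auc
  expect_lt(abs(nullAuc - 0.5), 0.15)
})

test_that("AUC is rank-based: invariant to monotone transforms, flipped by label swap", {
  set.seed(6)
  scores <- rnorm(40)
  pos <- rep(c(TRUE, FALSE), 20)
  a <- sgbMeta:::.wilcoxAUC(scores, pos)
  expect_equal(sgbMeta:::.wilcoxAUC(exp(scores), pos), a)
  expect_equal(sgbMeta:::.wilcoxAUC(scores, !pos), 1 - a)
  # agreement with pROC on tied and untied data
  scores2 <- round(rnorm(60), 1)
  pos2 <- rbinom(60, 1, 0.5) == 1
  expect_equal(sgbMeta:::.wilcoxAUC(scores2, pos2),
               as.numeric(pROC::auc(pROC::roc(pos2, scores2, quiet = TRUE,
                                              direction = "<"))))
  expect_error(sgbMeta:::.wilcoxAUC(scores, rep(TRUE, 40)), "single-class")
})

test_that("transfer learning works across aligned feature spaces", {
  d <- makeMLData(nDatasets = 2, nPerArm = 12, shift = 0.15, seed = 7)
  tr <- d$datasets == "D1"
  r <- runTransfer(d$x[, tr], d$diet[tr], d$x[, !tr], d$diet[!tr],
                   testCfg(seed = 8))
  expect_gt(r$auc, 0.9)
  # resubstitution bound: testing on the training set is at least as good as CV
  cv <- runCV(d$x[, tr], d$diet[tr], testCfg(seed = 8))
  resub <- runTransfer(d$x[, tr], d$diet[tr], d$x[, tr], d$diet[tr],
                       testCfg(seed = 8))
  expect_gte(resub$auc, cv$auc - 0.02)
  # zero-fill alignment: features missing from the test cohort
  xTest <- d$x[6:30, !tr]
  r2 <- runTransfer(d$x[, tr], d$diet[tr], xTest, d$diet[!tr], testCfg(seed = 9))
  expect_true(r2$auc >= 0 && r2$auc <= 1)
  al <- alignFeatures(d$x[, tr], xTest)
  expect_identical(rownames(al[[1]]), rownames(al[[2]]))
  expect_true(all(al[[2]][1:5, ] == 0))
  # orthogonal train signal gives chance performance
  d2 <- makeMLData(nDatasets = 2, nPerArm = 12, shift = 0, seed = 10)
  d2$x[26:30, d2$datasets == "D2" & d2$diet == "high_fat"] <-
    d2$x[26:30, d2$datasets == "D2" & d2$diet == "high_fat"] + 0.15
  tr2 <- d2$datasets == "D1"
  rNull <- runTransfer(d2$x[1:25, tr2], d2$diet[tr2],
                       d2$x[1:25, !tr2], d2$diet[!tr2], testCfg(seed = 11))
  expect_lt(abs(rNull$auc - 0.5), 0.2)
  expect_error(runTransfer(d$x[, tr], d$diet[tr], d$x[, !tr],
                           rep("high_fat", sum(!tr)), testCfg()),
               "single|one class")
})

test_that("LODO ranks true biomarkers first and never sees the test cohort", {
  d <- makeMLData(nDatasets = 3, nPerArm = 10, nFeatures = 40, nBio = 5,
                  shift = 0.15, seed = 12)
  lodo <- runLODO(d$x, d$diet, d$datasets, testCfg(seed = 13))
  expect_equal(nrow(lodo$auc), 3)
  expect_true(all(lodo$auc$auc > 0.8))
  top5 <- names(sort(lodo$ranking))[1:5]
  expect_setequal(top5, sprintf("SGB%03d", 1:5))
  # determinism
  lodo2 <- runLODO(d$x, d$diet, d$datasets, testCfg(seed = 13))
  expect_identical(lodo$ranking, lodo2$ranking)
  # no leakage: the ranking must be reproducible from forests fit on the
  # training cohorts alone (the held-out cohort contributes no importance)
  d2 <- makeMLData(nDatasets = 2, nPerArm = 10, nFeatures = 20, nBio = 4,
                   shift = 0.15, seed = 14)
  cfg <- rfConfig(nTrees = 40, nRepeats = 1, seed = 17)
  lodoSmall <- runLODO(d2$x, d2$diet, d2$datasets, cfg)
  rankSum <- numeric(nrow(d2$x))
  for (i in 1:2) {
    te <- d2$datasets == sprintf("D%d", i)
    fit <- sgbMeta:::.fitForest(d2$x[, !te], d2$diet[!te] == "high_fat", cfg,
                                sgbMeta:::.childSeed(cfg$seed, 1, i, 4))
    imp <- fit$variable.importance[rownames(d2$x)]
    rankSum <- rankSum + rank(-imp, ties.method = "average")
  }
  expect_equal(unname(lodoSmall$ranking), unname(rankSum / 2))
  expect_error(runLODO(d$x, d$diet, rep("D1", length(d$datasets)), testCfg()),
               ">= 2 datasets")
})

test_that("the cross-prediction grid assembles CV, transfer and LODO cells", {
  d <- makeMLData(nDatasets = 3, nPerArm = 8, nFeatures = 25, nBio = 4,
                  shift = 0.15, seed = 15)
  cfg <- rfConfig(nTrees = 50, nRepeats = 2, cvFolds = 8, seed = 16)
  grid <- crossPredictionMatrix(d$x, d$diet, d$datasets, cfg)
  m <- aucMatrix(grid)
  expect_identical(dim(m), c(4L, 3L))    # D+1 rows x D columns
  expect_identical(rownames(m)[4], "LODO")
  expect_true(all(m >= 0 & m <= 1))
  # shared strong signal -> high off-diagonal transfer
  offDiag <- m[1:3, ][row(m[1:3, ]) != col(m[1:3, ])]
  expect_gt(min(offDiag), 0.8)
  expect_named(attr(grid, "ranking"))
  expect_output(show(grid), "PredictionGrid")
})
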