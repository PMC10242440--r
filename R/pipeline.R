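#' @importFrom stats wilcox.test aggregate median
NULL

.logMsg <- function(...) message("[sgbMeta] ", ...)

#' Cross-cohort binary diet-association meta-analysis
#'
#' End-to-end standardized-mean-difference analysis: arcsine-square-root
#' transform, per-dataset covariate-adjusted linear models
#' (\code{\link{fitDatasetLM}}), t-to-SMD conversion, random-effects pooling
#' with Paule-Mandel heterogeneity, Benjamini-Yekutieli FDR over the
#' retained feature family, and a fold-change meta-analysis
#' (\code{\link{lfcMeta}}) oriented by the pooled SMD sign. Features must
#' exceed \code{minPrevalence} overall prevalence (strict) and be detected
#' in at least \code{minDatasets} datasets \emph{before} the FDR step, so
#' the correction family equals the reported feature set. Datasets lacking
#' both diet classes are skipped with a warning; every exclusion is logged.
#'
#' @param profiles an \code{\link{SGBProfiles}} with full \code{colData}.
#' @param covariates covariate columns for the per-dataset models.
#' @param minPrevalence overall-prevalence threshold (default 0.2).
#' @param minDatasets minimum datasets with detection (default 5).
#' @param fdrLevel FDR significance level used for the \code{significant}
#'   flag (default 0.2).
#' @param baselineOnly restrict to the baseline timepoint per mouse
#'   (default \code{FALSE}: all timepoints enter the meta-analysis).
#' @param computeLfc also run the fold-change meta-analysis (default TRUE;
#'   disable in simulation studies that only assess the SMD path).
#' @return list with \code{smd} (per-feature \code{MetaResult} table, sorted
#'   by |pooled| descending, with \code{q} and \code{significant}),
#'   \code{lfc} (fold-change meta table) and \code{effects} (per
#'   feature x dataset effect records).
#' @export
runBinaryMeta <- function(profiles, covariates = .DEFAULT_COVARIATES,
                          minPrevalence = 0.2, minDatasets = 5,
                          fdrLevel = 0.2, baselineOnly = FALSE,
                          computeLfc = TRUE) {
  md <- as.data.frame(colData(profiles))
  if (is.null(md$sample_id)) md$sample_id <- rownames(md)
  if (baselineOnly) {
    keep <- selectEligible(md, excludeAntibiotics = FALSE, minPerClass = 0)$samples
    profiles <- profiles[, keep]
    md <- md[keep, , drop = FALSE]
  }
  prev <- computePrevalence(profiles)
  feats <- filterFeatures(prev, minPrevalence, minDatasets)
  if (!length(feats)) {
    warning("no feature passes the prevalence/dataset filters")
    return(list(smd = NULL, lfc = NULL, effects = NULL))
  }
  .logMsg(length(feats), "/", nrow(profiles), " features pass filters")
  tx <- arcsinSqrt(abundances(profiles)[feats, , drop = FALSE])

  effects <- list()
  for (d in unique(md$dataset_id)) {
    fit <- withCallingHandlers(
      fitDatasetLM(tx, md, d, covariates = covariates),
      warning = function(w) { .logMsg("dataset ", d, ": ", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    if (!is.null(fit)) effects[[d]] <- fit
  }
  if (length(effects) < 2) stop("fewer than 2 datasets usable for pooling")
  eff <- do.call(rbind, c(effects, list(make.row.names = FALSE)))

  ab <- abundances(profiles)
  rows <- list(); lfcRows <- list()
  for (f in feats) {
    e <- eff[eff$feature_id == f & !is.na(eff$d), , drop = FALSE]
    if (!nrow(e)) next
    pooled <- randomEffectsPool(e$d, e$se_d^2,
                                tau2 = if (nrow(e) >= 2) NULL else 0)
    pooled$feature_id <- f
    rows[[f]] <- pooled
    if (!computeLfc) next
    sgn <- if (pooled$pooled >= 0) 1 else -1
    grp <- lapply(e$dataset_id, function(d) {
      sel <- md$dataset_id == d
      list(high = ab[f, md$sample_id[sel & md$diet_class == "high_fat"]],
           low = ab[f, md$sample_id[sel & md$diet_class == "low_fat"]])
    })
    lf <- lfcMeta(grp, smdSign = sgn)
    lf$feature_id <- f
    lfcRows[[f]] <- lf
  }
  smd <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  smd$q <- byFDR(smd$p)
  smd$significant <- smd$q < fdrLevel
  ord <- order(-abs(smd$pooled))
  smd <- smd[ord, c("feature_id", setdiff(colnames(smd), "feature_id"))]
  lfc <- NULL
  if (length(lfcRows)) {
    lfc <- do.call(rbind, c(lfcRows, list(make.row.names = FALSE)))
    lfc <- lfc[match(smd$feature_id, lfc$feature_id),
               c("feature_id", setdiff(colnames(lfc), "feature_id"))]
    rownames(lfc) <- NULL
  }
  list(smd = smd, lfc = lfc, effects = eff)
}

#' Partial-correlation meta-analysis against a continuous exposure
#'
#' Per dataset and feature, the partial Spearman correlation between the
#' transformed abundance and the exposure (\code{fat_pct} or
#' \code{duration_days}) is computed controlling for the covariate set plus
#' the respective other exposure; per-feature records are pooled on the
#' Fisher-Z scale (\code{\link{poolCorrelations}}) and BY-adjusted.
#' Datasets in which the exposure does not vary are skipped with a warning.
#' Features must be detected in at least \code{minDatasets} datasets
#' (4 for fat, 3 for duration).
#'
#' @param profiles an \code{\link{SGBProfiles}}.
#' @param exposure \code{"fat_pct"} or \code{"duration_days"}.
#' @param covariates adjustment covariates (the other exposure is added
#'   automatically).
#' @param minDatasets minimum datasets with detection; default 4 when
#'   \code{exposure = "fat_pct"}, 3 for duration.
#' @param minPrevalence optional strict overall-prevalence threshold
#'   (default 0: detection filter only).
#' @param fdrLevel FDR level for the \code{significant} flag.
#' @return list with \code{meta} (per-feature pooled correlation table) and
#'   \code{records} (per feature x dataset partial correlations).
#' @export
runCorrelationMeta <- function(profiles, exposure = c("fat_pct", "duration_days"),
                               covariates = .DEFAULT_COVARIATES,
                               minDatasets = NULL, minPrevalence = 0,
                               fdrLevel = 0.2) {
  exposure <- match.arg(exposure)
  if (is.null(minDatasets))
    minDatasets <- if (exposure == "fat_pct") 4 else 3
  other <- setdiff(c("fat_pct", "duration_days"), exposure)
  md <- as.data.frame(colData(profiles))
  if (is.null(md$sample_id)) md$sample_id <- rownames(md)
  prev <- computePrevalence(profiles)
  feats <- filterFeatures(prev, minPrevalence, minDatasets)
  if (!length(feats)) {
    warning("no feature passes the detection filter")
    return(list(meta = NULL, records = NULL))
  }
  tx <- arcsinSqrt(abundances(profiles)[feats, , drop = FALSE])

  recs <- list()
  for (d in unique(md$dataset_id)) {
    sel <- md$dataset_id == d
    x <- md[[exposure]][sel]
    if (length(unique(x)) < 2) {
      warning("exposure constant within dataset ", d, "; skipped")
      next
    }
    covs <- md[sel, c(covariates, other), drop = FALSE]
    covs <- covs[, vapply(covs, function(v) length(unique(v)) > 1, logical(1)),
                 drop = FALSE]
    for (f in feats) {
      y <- tx[f, md$sample_id[sel]]
      r <- suppressWarnings(
        partialSpearman(y, x, if (ncol(covs)) covs else NULL))
      r$feature_id <- f
      r$dataset_id <- d
      recs[[paste(f, d)]] <- r
    }
  }
  if (!length(recs)) stop("no dataset with a varying exposure")
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))

  rows <- list()
  for (f in feats) {
    rf <- records[records$feature_id == f & !is.na(records$rho), , drop = FALSE]
    if (nrow(rf) < 2) next
    pooled <- suppressWarnings(poolCorrelations(rf))
    pooled$feature_id <- f
    rows[[f]] <- pooled
  }
  if (!length(rows)) return(list(meta = NULL, records = records))
  meta <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  meta$q <- byFDR(meta$p)
  meta$significant <- meta$q < fdrLevel
  meta <- meta[order(-abs(meta$pooled)),
               c("feature_id", setdiff(colnames(meta), "feature_id"))]
  rownames(meta) <- NULL
  list(meta = meta, records = records)
}

#' Cross-prediction machine-learning experiment
#'
#' Applies the eligibility rules (baseline timepoints, antibiotic
#' exclusion, at-least-\code{minPerClass}-per-arm datasets), then builds the
#' full cross-prediction AUC matrix (CV diagonal, transfer off-diagonals,
#' LODO bottom row) and the averaged LODO feature ranking for each
#' requested feature set (\code{"all"} SGBs and/or the \code{"known_only"}
#' kSGB subset).
#'
#' @param profiles an \code{\link{SGBProfiles}}.
#' @param config an \code{\link{rfConfig}}.
#' @param featureSets subset of \code{c("all", "known_only")}.
#' @param excludeAntibiotics drop antibiotic-treated samples (default TRUE).
#' @param minPerClass per-arm dataset size threshold (default 20).
#' @return named list per feature set:
#'   \code{list(grid = PredictionGrid, ranking = named numeric)}.
#' @export
runML <- function(profiles, config = rfConfig(),
                  featureSets = c("all", "known_only"),
                  excludeAntibiotics = TRUE, minPerClass = 20) {
  featureSets <- match.arg(featureSets, several.ok = TRUE)
  md <- as.data.frame(colData(profiles))
  if (is.null(md$sample_id)) md$sample_id <- rownames(md)
  elig <- selectEligible(md, excludeAntibiotics = excludeAntibiotics,
                         minPerClass = minPerClass)
  if (length(elig$datasets) < 2)
    stop("fewer than 2 eligible datasets for the ML experiment")
  .logMsg("eligible: ", length(elig$datasets), " datasets, ",
          length(elig$samples), " samples")
  md <- md[elig$samples, , drop = FALSE]
  tx <- arcsinSqrt(abundances(profiles)[, elig$samples, drop = FALSE])

  out <- list()
  for (fs in featureSets) {
    x <- if (fs == "known_only") tx[isKnown(profiles), , drop = FALSE] else tx
    grid <- crossPredictionMatrix(x, md$diet_class, md$dataset_id, config)
    out[[fs]] <- list(grid = grid, ranking = attr(grid, "ranking"))
  }
  out
}

#' Select the top-ranked significant features
#'
#' Among features significant in the pooled analysis, returns the \code{k}
#' with the best (lowest) average LODO rank.
#'
#' @param smd the \code{smd} table from \code{\link{runBinaryMeta}}.
#' @param ranking named average-rank vector from the LODO harness.
#' @param k number of features (default 8).
#' @param fdrLevel significance cutoff on \code{q}.
#' @return character vector of feature IDs, best rank first.
#' @export
selectTopFeatures <- function(smd, ranking, k = 8, fdrLevel = 0.2) {
  sig <- smd$feature_id[smd$q < fdrLevel]
  sig <- sig[sig %in% names(ranking)]
  head(sig[order(ranking[sig])], k)
}

#' Evaluate longitudinal diet-shift trajectories
#'
#' Summarizes, per mouse and phase, the mean square-root-scale relative
#' abundance of a selected feature panel, and tests each consecutive phase
#' pair with a paired two-sided Wilcoxon signed-rank test across mice.
#' Phase pairs without samples are skipped; an all-zero difference vector
#' yields a missing p-value.
#'
#' @param profiles a longitudinal \code{\link{SGBProfiles}} (colData must
#'   carry \code{mouse_id}, \code{timepoint} and \code{phase}).
#' @param features feature IDs to aggregate (e.g. from
#'   \code{\link{selectTopFeatures}}).
#' @return list with \code{summary} (mouse x phase mean levels) and
#'   \code{shifts} (per consecutive phase pair: n mice, median paired
#'   difference, p).
#' @export
evaluateTrajectories <- function(profiles, features) {
  md <- as.data.frame(colData(profiles))
  stopifnot(all(c("mouse_id", "timepoint", "phase") %in% colnames(md)))
  stopifnot(all(features %in% rownames(profiles)))
  sq <- sqrt(abundances(profiles)[features, , drop = FALSE] / 100)
  lvl <- colMeans(sq)

  agg <- aggregate(lvl ~ mouse_id + phase,
                   data = data.frame(mouse_id = md$mouse_id,
                                     phase = md$phase, lvl = lvl),
                   FUN = mean)
  phaseOrder <- unique(md$phase[order(md$mouse_id, md$timepoint)])
  shifts <- list()
  for (i in seq_len(length(phaseOrder) - 1)) {
    a <- phaseOrder[i]; b <- phaseOrder[i + 1]
    mice <- intersect(agg$mouse_id[agg$phase == a], agg$mouse_id[agg$phase == b])
    if (!length(mice)) next
    va <- agg$lvl[match(paste(mice, a), paste(agg$mouse_id, agg$phase))]
    vb <- agg$lvl[match(paste(mice, b), paste(agg$mouse_id, agg$phase))]
    dd <- vb - va
    p <- if (all(dd == 0)) NA_real_ else
      suppressWarnings(wilcox.test(vb, va, paired = TRUE)$p.value)
    shifts[[paste(a, b, sep = "->")]] <-
      data.frame(phase_from = a, phase_to = b, n_mice = length(mice),
                 median_diff = median(dd), p = p)
  }
  list(summary = agg,
       shifts = if (length(shifts))
         do.call(rbind, c(shifts, list(make.row.names = FALSE))) else NULL)
}
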