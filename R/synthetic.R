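#' @importFrom stats rnorm runif rbinom rlnorm
NULL

#' Specification of a synthetic multi-cohort study
#'
#' Declares the generative conditions for a multi-cohort mouse-diet study:
#' number of cohorts and arm sizes, feature count, the biomarker subset with
#' true standardized mean differences on the arcsine-square-root scale,
#' study-effect and residual scales, covariate effects, per-feature
#' detection probabilities, and the per-cohort fat-percentage distributions
#' of the two diet arms. Defaults emulate the pooled public cohorts: study
#' identity dominates variance, roughly two thirds of features are uSGBs,
#' high-fat arms draw ~40-60% of calories from fat versus ~5-17% in low-fat
#' arms, and a small biomarker panel (three quarters of it high-fat
#' associated) carries a true effect of 1 residual standard deviation.
#'
#' Diet effects are injected on the arcsine-square-root scale so that the
#' true SMD is exactly the quantity the estimation pipeline targets;
#' biomarkers are fully prevalent, moderate-abundance features (baseline
#' 0.5%), keeping the compositional renormalization perturbation negligible.
#'
#' @param nDatasets number of cohorts.
#' @param samplesPerArm samples per diet arm per cohort.
#' @param nFeatures number of SGB features.
#' @param nBiomarkers number of diet-responsive features.
#' @param biomarkerSMD true standardized mean difference (scalar or
#'   per-biomarker vector) on the transformed scale.
#' @param biomarkerSigns +1/-1 per biomarker; default three quarters +1.
#' @param fractionUnknown fraction of features flagged uSGB.
#' @param studyEffectSD sd of per-feature-per-cohort baseline shifts
#'   (arcsine scale).
#' @param noiseSD residual sd (arcsine scale).
#' @param covariateEffects named vector of covariate effect scales
#'   (arcsine scale) for \code{age_days} (per day), \code{sex},
#'   \code{body_site}, \code{antibiotics}; each covariate perturbs a random
#'   30\% of features with random sign.
#' @param prevalenceRange detection-probability interval for non-biomarker
#'   features; biomarkers are fully prevalent.
#' @param fatHigh,fatLow fat-percentage ranges; one value is drawn per
#'   cohort arm (diet formulations differ between studies, not mice).
#' @param durationRange diet duration range in days (one draw per cohort).
#' @param biomarkerBasePct baseline percent abundance assigned to
#'   biomarkers.
#' @param seed integer seed making the draw fully reproducible.
#' @return list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nDatasets = 6, samplesPerArm = 20, nFeatures = 200,
                          nBiomarkers = 8, biomarkerSMD = 1.0,
                          biomarkerSigns = NULL,
                          fractionUnknown = 2 / 3,
                          studyEffectSD = 0.05, noiseSD = 0.03,
                          covariateEffects = c(age_days = 0.0004, sex = 0.02,
                                               body_site = 0.03,
                                               antibiotics = 0.03),
                          prevalenceRange = c(0.35, 1),
                          fatHigh = c(40, 60), fatLow = c(5, 17),
                          durationRange = c(14, 112),
                          biomarkerBasePct = 0.5,
                          seed = 1) {
  if (is.null(biomarkerSigns))
    biomarkerSigns <- rep(c(1, -1),
                          c(ceiling(nBiomarkers * 0.75),
                            nBiomarkers - ceiling(nBiomarkers * 0.75)))
  stopifnot(length(biomarkerSigns) == nBiomarkers,
            all(biomarkerSigns %in% c(-1, 1)),
            fractionUnknown >= 0, fractionUnknown <= 1,
            studyEffectSD >= 0, noiseSD > 0,
            all(prevalenceRange >= 0), all(prevalenceRange <= 1),
            nBiomarkers <= nFeatures)
  smd <- rep_len(biomarkerSMD, nBiomarkers)
  baseLatent <- asin(sqrt(biomarkerBasePct / 100))
  if (nBiomarkers > 0 &&
      (any(baseLatent + abs(smd) * noiseSD > pi / 2 - 0.1) ||
       baseLatent - max(abs(smd)) * noiseSD < -10 * noiseSD))
    stop("infeasible spec: biomarker effect too large for the arcsine scale")
  structure(list(nDatasets = nDatasets, samplesPerArm = samplesPerArm,
                 nFeatures = nFeatures, nBiomarkers = nBiomarkers,
                 biomarkerSMD = smd, biomarkerSigns = biomarkerSigns,
                 fractionUnknown = fractionUnknown,
                 studyEffectSD = studyEffectSD, noiseSD = noiseSD,
                 covariateEffects = covariateEffects,
                 prevalenceRange = prevalenceRange,
                 fatHigh = fatHigh, fatLow = fatLow,
                 durationRange = durationRange,
                 biomarkerBasePct = biomarkerBasePct,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.syntheticFeatureFrame <- function(spec) {
  nF <- spec$nFeatures
  ids <- sprintf("SGB%04d", seq_len(nF))
  unknown <- seq_len(nF) <= round(nF * spec$fractionUnknown)
  clade <- ifelse(unknown,
    sprintf("k__Bacteria|p__Firmicutes|c__Clostridia|o__Oscillospirales|f__Ruminococcaceae|g__GGB%04d|s__GGB%04d_SGB%04d|t__%s",
            seq_len(nF), seq_len(nF), seq_len(nF), ids),
    sprintf("k__Bacteria|p__Firmicutes|c__Clostridia|o__Lachnospirales|f__Lachnospiraceae|g__Genus%04d|s__Genus%04d_species%04d|t__%s",
            seq_len(nF), seq_len(nF), seq_len(nF), ids))
  DataFrame(feature_id = ids, clade_name = clade, known = !unknown,
            genus_level_assigned = !unknown, row.names = ids)
}

# baseline composition on the percent scale; biomarkers pinned to a fixed
# moderate abundance, remaining mass spread log-normally
.syntheticBase <- function(spec, biomarkerIdx) {
  raw <- rlnorm(spec$nFeatures, meanlog = 0, sdlog = 1.2)
  raw[biomarkerIdx] <- 0
  base <- raw / sum(raw) * (100 - spec$nBiomarkers * spec$biomarkerBasePct)
  base[biomarkerIdx] <- spec$biomarkerBasePct
  base
}

.syntheticMetadata <- function(spec) {
  nD <- spec$nDatasets
  nArm <- spec$samplesPerArm
  rows <- list()
  strains <- c("C57BL/6J", "BALB/c", "CD1")
  sites <- c("feces", "feces", "feces", "cecum", "ileum")
  for (d in seq_len(nD)) {
    fatHi <- runif(1, spec$fatHigh[1], spec$fatHigh[2])
    fatLo <- runif(1, spec$fatLow[1], spec$fatLow[2])
    # mice are sampled at varying diet durations around a per-cohort center,
    # so duration-abundance correlations are estimable within a cohort
    durCenter <- runif(1, spec$durationRange[1], spec$durationRange[2])
    strain <- sample(strains, 1)
    site <- sample(sites, 1)
    n <- 2 * nArm
    ids <- sprintf("D%02d_S%03d", d, seq_len(n))
    rows[[d]] <- data.frame(
      sample_id = ids,
      dataset_id = sprintf("D%02d", d),
      diet_class = rep(c("high_fat", "low_fat"), each = nArm),
      fat_pct = rep(c(fatHi, fatLo), each = nArm),
      duration_days = pmax(7, round(durCenter + runif(n, -14, 14))),
      age_days = round(runif(n, 42, 120)),
      sex = sample(c("female", "male"), n, replace = TRUE),
      strain = strain,
      body_site = site,
      antibiotics = FALSE,
      mouse_id = paste0("M_", ids),
      timepoint = 1L)
  }
  md <- do.call(rbind, rows)
  rownames(md) <- md$sample_id
  md
}

#' Generate a synthetic multi-cohort dataset with known ground truth
#'
#' Draws, for every feature, cohort and sample, a latent value on the
#' arcsine-square-root scale:
#' baseline + per-cohort study shift + covariate effects + diet effect
#' (biomarkers only) + Gaussian noise; clamps it to \eqn{[0, \pi/2]}, zeroes
#' it with probability one minus the feature's detection probability, maps
#' it back through the inverse transform and renormalizes each sample to a
#' 100\% composition. Metadata fields are drawn from the spec distributions.
#' The output is byte-identical for a given spec (the seed lives in the
#' spec).
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return \code{list(profiles = SGBProfiles, truth = list(...))}; the truth
#'   carries biomarker indices/IDs, the true per-feature SMD and sign, the
#'   realized study effects and the per-feature detection probabilities.
#' @export
generateCohorts <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  nF <- spec$nFeatures
  fi <- .syntheticFeatureFrame(spec)
  # biomarkers drawn among uSGB-heavy tail by default: last nBiomarkers of
  # the unknown block, so known-only feature sets exclude them
  nUnknown <- round(nF * spec$fractionUnknown)
  biomarkerIdx <- seq_len(spec$nBiomarkers) +
    max(0L, nUnknown - spec$nBiomarkers)
  base <- .syntheticBase(spec, biomarkerIdx)
  baseLatent <- asin(sqrt(base / 100))
  prevalence <- runif(nF, spec$prevalenceRange[1], spec$prevalenceRange[2])
  prevalence[biomarkerIdx] <- 1

  md <- .syntheticMetadata(spec)
  n <- nrow(md)
  studyEffects <- matrix(rnorm(nF * spec$nDatasets, 0, spec$studyEffectSD),
                         nF, spec$nDatasets,
                         dimnames = list(fi$feature_id,
                                         unique(md$dataset_id)))
  # covariate loading: each covariate perturbs a random 30% of features
  covNames <- c("age_days", "sex", "body_site", "antibiotics")
  covEff <- setNames(numeric(length(covNames)), covNames)
  covEff[names(spec$covariateEffects)] <- spec$covariateEffects
  loading <- sapply(covNames, function(cv)
    rbinom(nF, 1, 0.3) * sample(c(-1, 1), nF, replace = TRUE) * covEff[[cv]])
  delta <- numeric(nF)
  delta[biomarkerIdx] <- spec$biomarkerSigns * spec$biomarkerSMD * spec$noiseSD

  latent <- matrix(baseLatent, nF, n) +
    studyEffects[, md$dataset_id] +
    outer(loading[, "age_days"], md$age_days - mean(md$age_days)) +
    outer(loading[, "sex"], as.numeric(md$sex == "male")) +
    outer(loading[, "body_site"], as.numeric(md$body_site != "feces")) +
    outer(loading[, "antibiotics"], as.numeric(md$antibiotics)) +
    outer(delta, as.numeric(md$diet_class == "high_fat")) +
    matrix(rnorm(nF * n, 0, spec$noiseSD), nF, n)
  latent <- pmin(pmax(latent, 0), pi / 2)
  detected <- matrix(rbinom(nF * n, 1, prevalence), nF, n)
  ab <- 100 * sin(latent)^2 * detected
  cs <- colSums(ab)
  cs[cs == 0] <- 1
  ab <- sweep(ab, 2, cs / 100, "/")
  dimnames(ab) <- list(fi$feature_id, md$sample_id)

  trueSMD <- numeric(nF)
  trueSMD[biomarkerIdx] <- spec$biomarkerSigns * spec$biomarkerSMD
  truth <- list(biomarkerIdx = biomarkerIdx,
                biomarkerIds = fi$feature_id[biomarkerIdx],
                trueSMD = setNames(trueSMD, fi$feature_id),
                fatCorrSign = setNames(sign(trueSMD), fi$feature_id),
                studyEffects = studyEffects,
                prevalence = setNames(prevalence, fi$feature_id))
  list(profiles = SGBProfiles(ab, featureInfo = fi, sampleData = md),
       truth = truth)
}

#' Generate longitudinal per-mouse trajectories across diet phases
#'
#' Each mouse passes through an ordered schedule of dietary phases
#' (\code{N} nursing, \code{LFD}/\code{LLFD} low fat, \code{HFD} high fat).
#' Biomarker abundances approach the phase-appropriate mean (baseline +
#' diet effect under \code{HFD}, baseline otherwise) with a first-order lag
#' per timepoint; non-biomarker features have no systematic phase trend.
#'
#' @param spec a \code{\link{syntheticSpec}} (its biomarker panel, scales
#'   and seed are reused).
#' @param phases character vector, the ordered phase schedule, each entry
#'   one timepoint, from \code{c("N", "LFD", "HFD", "LLFD")}; repeats allowed
#'   (e.g. \code{rep(c("LFD","HFD"), each = 4)}).
#' @param nMice number of mice.
#' @param approachRate fraction of the gap to the phase target closed per
#'   timepoint (1 = immediate shift).
#' @return an \code{SGBProfiles} whose \code{colData} carries
#'   \code{mouse_id}, \code{timepoint}, \code{phase} and the mapped
#'   \code{diet_class}.
#' @export
generateLongitudinal <- function(spec, phases = rep(c("LFD", "HFD"), each = 4),
                                 nMice = 8, approachRate = 0.7) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (!length(phases)) stop("empty phase schedule")
  if (!all(phases %in% c("N", "LFD", "HFD", "LLFD")))
    stop("phases must be from {N, LFD, HFD, LLFD}")
  set.seed(spec$seed + 1L)
  nF <- spec$nFeatures
  fi <- .syntheticFeatureFrame(spec)
  nUnknown <- round(nF * spec$fractionUnknown)
  biomarkerIdx <- seq_len(spec$nBiomarkers) +
    max(0L, nUnknown - spec$nBiomarkers)
  base <- .syntheticBase(spec, biomarkerIdx)
  baseLatent <- asin(sqrt(base / 100))
  delta <- numeric(nF)
  delta[biomarkerIdx] <- spec$biomarkerSigns * spec$biomarkerSMD * spec$noiseSD

  nT <- length(phases)
  cols <- list(); mats <- list()
  for (m in seq_len(nMice)) {
    cur <- baseLatent + rnorm(nF, 0, spec$noiseSD)
    traj <- matrix(0, nF, nT)
    for (t in seq_len(nT)) {
      target <- baseLatent + delta * (phases[t] == "HFD")
      cur <- cur + approachRate * (target - cur) + rnorm(nF, 0, spec$noiseSD)
      traj[, t] <- pmin(pmax(cur, 0), pi / 2)
    }
    ab <- 100 * sin(traj)^2
    ab <- sweep(ab, 2, colSums(ab) / 100, "/")
    ids <- sprintf("M%02d_T%02d", m, seq_len(nT))
    colnames(ab) <- ids
    mats[[m]] <- ab
    cols[[m]] <- data.frame(
      sample_id = ids, dataset_id = "longitudinal",
      diet_class = ifelse(phases == "HFD", "high_fat", "low_fat"),
      fat_pct = ifelse(phases == "HFD", 45, ifelse(phases == "LLFD", 6.2, 10)),
      duration_days = seq_len(nT) * 7, age_days = 21 + seq_len(nT) * 7,
      sex = "female", strain = "C57BL/6J", body_site = "feces",
      antibiotics = FALSE, mouse_id = sprintf("M%02d", m),
      timepoint = seq_len(nT), phase = phases)
  }
  ab <- do.call(cbind, mats)
  rownames(ab) <- fi$feature_id
  md <- do.call(rbind, cols)
  rownames(md) <- md$sample_id
  out <- SGBProfiles(ab, featureInfo = fi, sampleData = md)
  attr(out, "biomarkerIds") <- fi$feature_id[biomarkerIdx]
  out
}
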