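#' @importFrom stats pnorm qnorm qt p.adjust var sd
NULL

#' Paule-Mandel between-study variance
#'
#' Iterative moment estimator of the between-study variance \eqn{\tau^2} in
#' a random-effects meta-analysis: solves
#' \deqn{\sum_i w_i(\tau^2)\,(y_i - \hat\mu(\tau^2))^2 = k - 1, \qquad
#'   w_i = 1/(v_i + \tau^2),}
#' by Newton-type iteration, truncating at 0 (if the generalized Q at
#' \eqn{\tau^2 = 0} does not exceed \eqn{k-1}, the estimate is 0).
#' If the iteration fails to converge within \code{maxIter} steps, the
#' DerSimonian-Laird estimate is returned with a warning.
#'
#' @param effects per-study effect estimates (length \eqn{k \ge 2}).
#' @param variances per-study sampling variances (all positive).
#' @param tol convergence tolerance (default 1e-10).
#' @param maxIter maximum iterations (default 100).
#' @return non-negative scalar \eqn{\tau^2}.
#' @export
pauleMandelTau2 <- function(effects, variances, tol = 1e-10, maxIter = 100) {
  k <- length(effects)
  if (k < 2) stop("need at least 2 studies")
  stopifnot(length(variances) == k, all(variances > 0))

  genQ <- function(tau2) {
    w <- 1 / (variances + tau2)
    mu <- sum(w * effects) / sum(w)
    list(q = sum(w * (effects - mu)^2), w = w, mu = mu)
  }
  if (genQ(0)$q <= k - 1) return(0)

  tau2 <- max(0, var(effects) - mean(variances))   # moment start
  for (i in seq_len(maxIter)) {
    gq <- genQ(tau2)
    step <- (gq$q - (k - 1)) / sum(gq$w^2 * (effects - gq$mu)^2)
    tau2New <- max(0, tau2 + step)
    if (abs(tau2New - tau2) < tol) return(tau2New)
    tau2 <- tau2New
  }
  warning("Paule-Mandel iteration did not converge; DerSimonian-Laird fallback")
  .dlTau2(effects, variances)
}

.dlTau2 <- function(effects, variances) {
  w <- 1 / variances
  mu <- sum(w * effects) / sum(w)
  q <- sum(w * (effects - mu)^2)
  k <- length(effects)
  max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' Random-effects pooling of per-study effects
#'
#' Inverse-variance pooling with random-effects weights
#' \eqn{w_i = 1/(v_i + \tau^2)}: pooled effect \eqn{\sum w_i y_i / \sum w_i},
#' standard error \eqn{1/\sqrt{\sum w_i}}, normal 95\% confidence interval
#' (\eqn{\pm 1.96\, se}), two-sided normal p-value, and Cochran's Q computed
#' with fixed-effect weights. \eqn{\tau^2} defaults to the Paule-Mandel
#' estimate (0 for a single study).
#'
#' @param effects per-study effects (length \eqn{k \ge 1}).
#' @param variances per-study sampling variances.
#' @param tau2 between-study variance; \code{NULL} to estimate.
#' @param ciLevel confidence level (default 0.95).
#' @return one-row \code{data.frame}: \code{k}, \code{pooled}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{z}, \code{p}, \code{tau2},
#'   \code{Q_het}.
#' @export
randomEffectsPool <- function(effects, variances, tau2 = NULL, ciLevel = 0.95) {
  k <- length(effects)
  if (k == 0) stop("no studies to pool")
  stopifnot(length(variances) == k, all(variances > 0))
  if (is.null(tau2))
    tau2 <- if (k >= 2) pauleMandelTau2(effects, variances) else 0
  w <- 1 / (variances + tau2)
  pooled <- sum(w * effects) / sum(w)
  se <- 1 / sqrt(sum(w))
  zq <- qnorm(1 - (1 - ciLevel) / 2)
  wf <- 1 / variances
  muF <- sum(wf * effects) / sum(wf)
  data.frame(k = k, pooled = pooled, se = se,
             ci_low = pooled - zq * se, ci_high = pooled + zq * se,
             z = pooled / se, p = 2 * pnorm(-abs(pooled / se)),
             tau2 = tau2, Q_het = sum(wf * (effects - muF)^2))
}

#' Fixed-effect (inverse-variance) pooling
#'
#' @inheritParams randomEffectsPool
#' @return one-row \code{data.frame}: \code{k}, \code{pooled}, \code{se}.
#' @export
fixedEffectsPool <- function(effects, variances) {
  k <- length(effects)
  if (k == 0) stop("no studies to pool")
  stopifnot(length(variances) == k, all(variances > 0))
  w <- 1 / variances
  data.frame(k = k, pooled = sum(w * effects) / sum(w), se = 1 / sqrt(sum(w)))
}

#' Log2 fold-change meta-analysis between diet groups
#'
#' Per dataset: zeros are replaced by \code{epsilon} (0.0001), every value is
#' log2-transformed, group means are taken, and the difference is formed
#' with the SMD-favored group first (the high-fat group when the pooled
#' standardized mean difference is positive, the low-fat group otherwise),
#' so the fold change describes the increase in the diet arm the SMD
#' analysis associated the feature with. Each dataset effect's variance is
#' the sum of the two group-mean variances. Datasets are pooled by fixed
#' effect; the reported meta standard error is the standard deviation of the
#' per-dataset effects over \eqn{\sqrt{k}}, with the 95\% interval using the
#' t quantile with \eqn{k-1} degrees of freedom. Set
#' \code{standardSE = TRUE} for the conventional fixed-effect standard
#' error instead. Linear-scale values are \eqn{2^{x}}.
#'
#' @param groups list, one element per dataset, each a
#'   \code{list(high = , low = )} of abundance vectors.
#' @param smdSign +1/-1 direction from the SMD meta-analysis.
#' @param epsilon zero replacement value (default 0.0001).
#' @param standardSE use the fixed-effect standard error for the CI.
#' @return one-row \code{data.frame}: \code{k}, \code{pooled_log2fc},
#'   \code{se}, \code{ci_low}, \code{ci_high}, \code{fold_change},
#'   \code{fc_ci_low}, \code{fc_ci_high}, \code{direction_sign}.
#' @export
lfcMeta <- function(groups, smdSign = 1, epsilon = 1e-4, standardSE = FALSE) {
  stopifnot(smdSign %in% c(-1, 1))
  eff <- numeric(0); v <- numeric(0)
  for (g in groups) {
    if (!length(g$high) || !length(g$low)) {
      warning("dataset with an empty diet group excluded from fold-change meta")
      next
    }
    lhi <- log2(replace(g$high, g$high == 0, epsilon))
    llo <- log2(replace(g$low, g$low == 0, epsilon))
    first <- if (smdSign > 0) lhi else llo
    second <- if (smdSign > 0) llo else lhi
    eff <- c(eff, mean(first) - mean(second))
    vHigh <- if (length(lhi) > 1) var(lhi) / length(lhi) else 0
    vLow <- if (length(llo) > 1) var(llo) / length(llo) else 0
    v <- c(v, vHigh + vLow)
  }
  k <- length(eff)
  if (k == 0) stop("no dataset with both diet groups")
  v[v <= 0] <- min(v[v > 0], 1e-8)
  fe <- fixedEffectsPool(eff, v)
  se <- if (standardSE) fe$se
        else if (k > 1) sd(eff) / sqrt(k) else NA_real_
  tq <- if (k > 1) qt(0.975, k - 1) else NA_real_
  lo <- fe$pooled - tq * se
  hi <- fe$pooled + tq * se
  data.frame(k = k, pooled_log2fc = fe$pooled, se = se,
             ci_low = lo, ci_high = hi,
             fold_change = 2^fe$pooled,
             fc_ci_low = 2^lo, fc_ci_high = 2^hi,
             direction_sign = smdSign)
}

#' Fisher-Z transform and its inverse
#'
#' \code{fisherZ} is \eqn{\mathrm{atanh}(r)}, variance-stabilizing for
#' correlation coefficients; \code{inverseFisherZ} is \eqn{\tanh(z)}.
#'
#' @param r correlation in (-1, 1).
#' @param z Fisher-Z value.
#' @return transformed numeric vector.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("domain error: |r| must be < 1")
  atanh(r)
}

#' @rdname fisherZ
#' @export
inverseFisherZ <- function(z) tanh(z)

#' Random-effects pooling of partial correlations
#'
#' Correlations are Fisher-Z transformed with sampling variance
#' \eqn{1/(n - n_{cov} - 3)} (the classic \eqn{1/(n-3)} adjusted for the
#' covariates partialled out), pooled on the z scale by
#' \code{\link{randomEffectsPool}} (Paule-Mandel \eqn{\tau^2}), and the
#' pooled estimate and confidence bounds are back-transformed to the r
#' scale. Records with \eqn{n - n_{cov} - 3 \le 0} are excluded with a
#' warning.
#'
#' @param records \code{data.frame} with columns \code{rho}, \code{n},
#'   \code{n_covariates} (one row per study).
#' @param tau2 between-study variance on the z scale; \code{NULL} to
#'   estimate.
#' @return one-row \code{data.frame}: \code{k}, \code{pooled} (r scale),
#'   \code{ci_low}, \code{ci_high} (r scale), \code{se} (z scale),
#'   \code{z}, \code{p}, \code{tau2}, \code{Q_het}.
#' @export
poolCorrelations <- function(records, tau2 = NULL) {
  records <- records[!is.na(records$rho), , drop = FALSE]
  ok <- records$n - records$n_covariates - 3 > 0
  if (any(!ok)) warning(sum(!ok), " record(s) with insufficient n excluded")
  records <- records[ok, , drop = FALSE]
  if (!nrow(records)) stop("no poolable correlation records")
  z <- fisherZ(records$rho)
  v <- 1 / (records$n - records$n_covariates - 3)
  pz <- randomEffectsPool(z, v, tau2 = tau2)
  data.frame(k = pz$k, pooled = inverseFisherZ(pz$pooled),
             ci_low = inverseFisherZ(pz$ci_low),
             ci_high = inverseFisherZ(pz$ci_high),
             se = pz$se, z = pz$z, p = pz$p,
             tau2 = pz$tau2, Q_het = pz$Q_het)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' False-discovery-rate control valid under arbitrary dependence, via the
#' harmonic-sum inflation factor \eqn{c(m) = \sum_{h=1}^m 1/h}; delegates to
#' \code{stats::p.adjust(method = "BY")}. Input order is preserved.
#'
#' @param p p-values in [0, 1].
#' @return adjusted q-values, \code{q >= p} elementwise.
#' @export
byFDR <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("domain error: p-values must lie in [0, 1]")
  p.adjust(p, method = "BY")
}
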