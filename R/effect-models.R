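#' @importFrom stats pt cor complete.cases as.formula
NULL

.DEFAULT_COVARIATES <- c("age_days", "sex", "strain", "body_site", "antibiotics")

# build the per-dataset design matrix: intercept + covariates (one-hot,
# first-level reference) + diet indicator (high_fat = 1) as last column.
# covariates constant within the dataset are dropped.
.buildDesign <- function(md, covariates) {
  dropped <- character(0)
  usable <- character(0)
  for (cv in covariates) {
    v <- md[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv)
    if (length(unique(v[!is.na(v)])) < 2) dropped <- c(dropped, cv)
    else usable <- c(usable, cv)
  }
  diet <- as.numeric(md$diet_class == "high_fat")
  if (length(usable)) {
    f <- as.formula(paste("~", paste(usable, collapse = "+")))
    X <- model.matrix(f, data = as.data.frame(md))
  } else {
    X <- matrix(1, nrow = nrow(md), dimnames = list(NULL, "(Intercept)"))
  }
  X <- cbind(X, diet_high_fat = diet)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  list(X = X, dropped = dropped, qr = qrX)
}

#' Per-dataset covariate-adjusted linear models for every feature
#'
#' Fits, within one dataset, an ordinary least squares model
#' \code{feature ~ covariates + diet} for every feature of an
#' arcsine-square-root transformed abundance matrix, and converts the Wald t
#' statistic of the diet indicator (coded \code{high_fat = 1}, so positive
#' effects mean higher abundance under a high-fat diet) into a standardized
#' mean difference via \code{\link{tToSMD}}. Categorical covariates are
#' one-hot encoded against a first-level reference; covariates constant
#' within the dataset are dropped before fitting. All features share one QR
#' decomposition of the design, so the fit is a single multiresponse OLS.
#'
#' Features with zero residual variance in the dataset yield a missing
#' record (\code{NA}) rather than a spurious t = 0.
#'
#' @param features transformed features-x-samples matrix (see
#'   \code{\link{arcsinSqrt}}); columns must be samples of one dataset or a
#'   superset keyed by \code{meta}.
#' @param meta per-sample metadata \code{data.frame} (or \code{DataFrame})
#'   with at least \code{sample_id}/rownames, \code{dataset_id},
#'   \code{diet_class} and the requested covariates.
#' @param datasetId which dataset to fit.
#' @param covariates covariate column names to adjust for. Sex is included
#'   by default; pass a reduced set to reproduce a formula without it.
#' @return \code{data.frame} with one row per feature: \code{feature_id},
#'   \code{dataset_id}, \code{t}, \code{df}, \code{n1} (high fat),
#'   \code{n2} (low fat), \code{d}, \code{se_d}, \code{p_wald}.
#' @export
fitDatasetLM <- function(features, meta, datasetId,
                         covariates = .DEFAULT_COVARIATES) {
  meta <- as.data.frame(meta)
  if (is.null(meta$sample_id)) meta$sample_id <- rownames(meta)
  md <- meta[meta$dataset_id == datasetId, , drop = FALSE]
  if (!nrow(md)) stop("unknown dataset: ", datasetId)
  missing <- setdiff(md$sample_id, colnames(features))
  if (length(missing)) stop("samples without profiles: ",
                            paste(head(missing, 5), collapse = ", "))
  Y <- t(features[, md$sample_id, drop = FALSE])

  n1 <- sum(md$diet_class == "high_fat")
  n2 <- sum(md$diet_class == "low_fat")
  if (n1 < 2 || n2 < 2) {
    warning("dataset ", datasetId, " lacks both diet classes (>=2 each); skipped")
    return(NULL)
  }
  des <- .buildDesign(md, covariates)
  qrX <- des$qr
  p <- ncol(des$X)
  df <- nrow(Y) - p
  if (df < 1) stop("not enough residual degrees of freedom in ", datasetId)

  coefs <- qr.coef(qrX, Y)
  resid <- qr.resid(qrX, Y)
  sigma2 <- colSums(resid^2) / df
  xtxInv <- chol2inv(qr.R(qrX))
  jj <- which(colnames(des$X) == "diet_high_fat")
  se <- sqrt(sigma2 * xtxInv[jj, jj])
  tval <- coefs[jj, ] / se
  degenerate <- sigma2 <= .Machine$double.eps * 100
  tval[degenerate] <- NA_real_

  smd <- tToSMD(tval, n1 = n1, n2 = n2, df = df)
  data.frame(feature_id = rownames(features),
             dataset_id = datasetId,
             t = unname(tval), df = df, n1 = n1, n2 = n2,
             d = smd$d, se_d = smd$se_d,
             p_wald = unname(2 * pt(-abs(tval), df)),
             row.names = NULL)
}

#' Standardized mean difference from a regression t statistic
#'
#' Converts the t statistic of a group contrast from a covariate-adjusted
#' linear model into a Cohen's-d-type standardized mean difference,
#' \deqn{d = \frac{t (n_1 + n_2)}{\sqrt{n_1 n_2}\,\sqrt{df}},}
#' with adjusted standard error
#' \deqn{se_d = \sqrt{\frac{n_1+n_2-1}{n_1+n_2-3}\cdot\frac{4}{n_1+n_2}
#'   \left(1 + \frac{d^2}{8}\right)}.}
#' The conversion is odd in \code{t}: flipping the sign of \code{t} flips
#' \code{d} and leaves \code{se_d} unchanged.
#'
#' @param t t statistic(s) of the group indicator.
#' @param n1,n2 group sizes (both at least 2; \code{n1 + n2 > 3}).
#' @param df residual degrees of freedom of the model.
#' @return \code{list(d =, se_d =)}, vectorized over \code{t}.
#' @export
tToSMD <- function(t, n1, n2, df) {
  stopifnot(n1 >= 2, n2 >= 2, df >= 1)
  if (n1 + n2 <= 3) stop("SE undefined for n1 + n2 <= 3")
  d <- t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
  se <- sqrt(((n1 + n2 - 1) / (n1 + n2 - 3)) * (4 / (n1 + n2)) * (1 + d^2 / 8))
  list(d = unname(d), se_d = unname(se))
}

#' Partial Spearman correlation
#'
#' All variables are rank-transformed (average ranks for ties); the partial
#' correlation is the Pearson correlation of the OLS residuals of ranked
#' \code{y} and ranked \code{x} on the ranked covariates (plus intercept).
#' With an empty covariate set this reduces to ordinary Spearman's rho.
#' Significance uses the t transform with \code{n - n_covariates - 2}
#' degrees of freedom.
#'
#' @param y,x numeric vectors of equal length.
#' @param covariates optional matrix/data.frame of covariates; categorical
#'   columns are one-hot encoded.
#' @return one-row \code{data.frame}: \code{rho}, \code{n},
#'   \code{n_covariates}, \code{p}. Constant \code{y} or \code{x} yields a
#'   missing record with a warning.
#' @export
partialSpearman <- function(y, x, covariates = NULL) {
  stopifnot(length(y) == length(x))
  n <- length(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    Z <- model.matrix(~ ., data = covariates)
    Z <- Z[, -1, drop = FALSE]              # intercept re-added below
    Z <- Z[, apply(Z, 2, function(v) length(unique(v)) > 1), drop = FALSE]
  } else {
    Z <- matrix(nrow = n, ncol = 0)
  }
  nc <- ncol(Z)
  dfree <- n - nc - 2
  if (dfree < 1) stop("n - n_covariates - 2 must be >= 1")
  if (length(unique(y)) < 2 || length(unique(x)) < 2) {
    warning("constant y or x: partial Spearman undefined")
    return(data.frame(rho = NA_real_, n = n, n_covariates = nc, p = NA_real_))
  }
  ry <- rank(y); rx <- rank(x)
  Zr <- if (nc) cbind(1, apply(Z, 2, rank)) else matrix(1, n, 1)
  resY <- qr.resid(qr(Zr), ry)
  resX <- qr.resid(qr(Zr), rx)
  rho <- suppressWarnings(cor(resY, resX))
  if (is.na(rho)) {
    warning("covariates fully explain y or x: partial Spearman undefined")
    return(data.frame(rho = NA_real_, n = n, n_covariates = nc, p = NA_real_))
  }
  rho <- max(-1, min(1, rho))
  tt <- rho * sqrt(dfree / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(tt), dfree)
  data.frame(rho = rho, n = n, n_covariates = nc, p = p)
}
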