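#' @importFrom vegan vegdist diversity
#' @importFrom stats model.matrix as.dist
NULL

#' Alpha diversity of a sample
#'
#' Proportions are renormalized to sum to one over detected taxa before the
#' index is computed. Shannon entropy uses the natural logarithm;
#' Gini-Simpson is \eqn{1 - \sum p_i^2}; richness counts strictly positive
#' entries.
#'
#' @param x non-negative abundance vector, or a features-x-samples matrix /
#'   \code{SGBProfiles} (one value per sample is returned).
#' @param index one of \code{"shannon"}, \code{"gini_simpson"},
#'   \code{"richness"}.
#' @return numeric scalar (vector input) or named vector (matrix input).
#' @export
alphaDiversity <- function(x, index = c("shannon", "gini_simpson", "richness")) {
  index <- match.arg(index)
  if (is(x, "SummarizedExperiment")) x <- abundances(x)
  if (is.matrix(x))
    return(vapply(seq_len(ncol(x)),
                  function(j) alphaDiversity(x[, j], index), numeric(1)) |>
             setNames(colnames(x)))
  if (any(x < 0)) stop("domain error: negative abundance")
  if (index == "richness") return(sum(x > 0))
  s <- sum(x)
  if (s <= 0) stop("domain error: zero-sum sample has no defined ", index)
  p <- x[x > 0] / s
  switch(index,
         shannon = unname(vegan::diversity(p, index = "shannon")),
         gini_simpson = unname(vegan::diversity(p, index = "simpson")))
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(i,j) = \sum_f |x_{fi} - x_{fj}| / \sum_f (x_{fi} + x_{fj})},
#' computed on the relative abundances. The distance between two all-zero
#' samples is undefined (0/0) and is set to 0 with a warning.
#'
#' @param x an \code{SGBProfiles} or a features-x-samples matrix.
#' @return a \code{dist} object labelled by sample ID.
#' @export
brayCurtis <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- abundances(x)
  if (ncol(x) < 2) stop("need at least 2 samples")
  d <- suppressWarnings(vegan::vegdist(t(x), method = "bray"))
  if (anyNA(d)) {
    warning("distance between all-zero samples is undefined; set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Write / read a distance matrix as square TSV
#'
#' @param d a \code{dist} or square matrix with sample IDs.
#' @param path TSV path (header row and first column are sample IDs).
#' @return \code{readDistanceTSV} returns a \code{dist}.
#' @export
writeDistanceTSV <- function(d, path) {
  m <- as.matrix(d)
  write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceTSV
#' @export
readDistanceTSV <- function(path) {
  m <- read.delim(path, check.names = FALSE)
  ids <- m[[1]]
  m <- as.matrix(m[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(rownames(m), colnames(m)))
    stop("format error: header and first column must list the same samples")
  as.dist(m)
}

# among/within sums of squared distances for a grouping
.permanovaSS <- function(dm2, labels) {
  n <- nrow(dm2)
  sst <- sum(dm2) / (2 * n)
  ssw <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ssw <- ssw + sum(dm2[idx, idx]) / (2 * length(idx))
  }
  c(sst = sst, ssw = ssw)
}

.permanovaF <- function(dm2, labels, nGroups, n) {
  ss <- .permanovaSS(dm2, labels)
  ((ss["sst"] - ss["ssw"]) / (nGroups - 1)) / (ss["ssw"] / (n - nGroups))
}

# all distinct arrangements of a label multiset, as a matrix (rows = labelings);
# callers guarantee the count is small
.enumerateLabelings <- function(counts) {
  labs <- names(counts)
  rec <- function(remaining, slots) {
    if (slots == 0L) return(matrix(character(0), nrow = 1L, ncol = 0L))
    out <- NULL
    for (l in labs[remaining > 0L]) {
      r2 <- remaining
      r2[l] <- r2[l] - 1L
      sub <- rec(r2, slots - 1L)
      out <- rbind(out, cbind(l, sub, deparse.level = 0))
    }
    out
  }
  rec(counts, sum(counts))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix. The pseudo-F statistic is formed
#' from among- and within-group sums of squared distances; significance is
#' assessed by permuting group labels. When the number of distinct label
#' arrangements does not exceed \code{nPermutations}, the exact permutation
#' distribution is enumerated exhaustively and
#' \eqn{p = \#\{F^* \ge F\} / N}; otherwise \code{nPermutations} random
#' permutations are drawn and \eqn{p = (1 + \#\{F^* \ge F\}) /
#' (1 + n_{perm})}.
#'
#' @param d a \code{dist} or square distance matrix.
#' @param labels group label per sample (at least 2 groups, each with at
#'   least 2 samples).
#' @param nPermutations number of random permutations (default 999).
#' @param seed integer seed for the permutation RNG.
#' @return one-row \code{data.frame}: \code{pseudo_F}, \code{R2},
#'   \code{adjusted_R2}, \code{p_perm}, \code{n_permutations},
#'   \code{exhaustive}.
#' @export
permanova <- function(d, labels, nPermutations = 999, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  counts <- table(labels)
  if (length(counts) < 2) stop("contract error: need at least 2 groups")
  if (any(counts < 2)) stop("contract error: each group needs >= 2 samples")
  g <- length(counts)
  dm2 <- dm^2
  fObs <- .permanovaF(dm2, labels, g, n)
  ss <- .permanovaSS(dm2, labels)
  r2 <- unname((ss["sst"] - ss["ssw"]) / ss["sst"])

  nDistinct <- round(exp(lfactorial(n) - sum(lfactorial(counts))))
  exhaustive <- is.finite(nDistinct) && nDistinct <= nPermutations
  if (exhaustive) {
    cnt <- as.integer(counts)
    names(cnt) <- names(counts)
    all <- .enumerateLabelings(cnt)
    fAll <- apply(all, 1L, function(l) .permanovaF(dm2, l, g, n))
    p <- mean(fAll >= fObs - 1e-12)
    nUsed <- nrow(all)
  } else {
    if (!is.null(seed)) set.seed(seed)
    fPerm <- vapply(seq_len(nPermutations), function(i)
      .permanovaF(dm2, sample(labels), g, n), numeric(1))
    p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + nPermutations)
    nUsed <- nPermutations
  }
  data.frame(pseudo_F = unname(fObs), R2 = r2,
             adjusted_R2 = 1 - (1 - r2) * (n - 1) / (n - g),
             p_perm = p, n_permutations = nUsed, exhaustive = exhaustive)
}

# doubly-centered Gower matrix from squared distances
.gowerG <- function(dm2) {
  n <- nrow(dm2)
  a <- -0.5 * dm2
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

# explained SS of the (column-space of) design X on Gower matrix G
.hatSS <- function(G, X) {
  q <- qr.Q(qr(X))
  sum(q * (G %*% q))
}

#' Sequential variance partitioning of a distance matrix
#'
#' Distance-based redundancy partitioning: terms are added in the given
#' order and each term's contribution is its increment in explained sum of
#' squares (McArdle-Anderson trace formulation), expressed as an
#' \eqn{R^2} fraction of the total. Each term additionally carries an
#' Ezekiel-adjusted \eqn{R^2},
#' \eqn{1 - (1 - R^2)(n-1)/(n-k-1)} with \eqn{k} the cumulative model
#' degrees of freedom after the term enters, a pseudo-F against the full
#' model residual, and a permutation p-value (sample relabeling).
#' Covariates constant across all samples are skipped with a warning.
#'
#' @param d a \code{dist} or square distance matrix.
#' @param covariates \code{data.frame} of covariates (rows aligned with
#'   samples of \code{d}).
#' @param termOrder character vector ordering the covariate terms.
#' @param nPermutations permutations for per-term p-values (default 999).
#' @param seed integer seed.
#' @return \code{data.frame}, one row per fitted term: \code{term},
#'   \code{df}, \code{R2}, \code{adjusted_R2}, \code{pseudo_F},
#'   \code{p_perm}; the full-model \eqn{R^2} is attached as attribute
#'   \code{"full_R2"}.
#' @export
variancePartition <- function(d, covariates, termOrder = colnames(covariates),
                              nPermutations = 999, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(nrow(covariates) == n)
  if (!all(termOrder %in% colnames(covariates)))
    stop("termOrder must name columns of covariates")
  keep <- vapply(termOrder, function(tm) {
    v <- covariates[[tm]]
    if (anyNA(v)) stop("missing values in covariate '", tm, "'")
    length(unique(v)) > 1
  }, logical(1))
  if (any(!keep))
    warning("constant covariate(s) skipped: ",
            paste(termOrder[!keep], collapse = ", "))
  terms <- termOrder[keep]
  if (!length(terms)) stop("no usable covariate terms")

  G <- .gowerG(dm^2)
  sst <- sum(diag(G))

  seqSS <- function(Gm) {
    ssPrev <- 0
    dfPrev <- 0L
    out <- matrix(0, nrow = length(terms), ncol = 2,
                  dimnames = list(terms, c("ss", "df")))
    for (i in seq_along(terms)) {
      f <- as.formula(paste("~", paste(terms[seq_len(i)], collapse = "+")))
      X <- model.matrix(f, data = covariates)
      ssCum <- .hatSS(Gm, X)
      dfCum <- qr(X)$rank - 1L
      out[i, ] <- c(ssCum - ssPrev, dfCum - dfPrev)
      ssPrev <- ssCum
      dfPrev <- dfCum
    }
    attr(out, "ss_full") <- ssPrev
    attr(out, "df_full") <- dfPrev
    out
  }

  obs <- seqSS(G)
  ssFull <- attr(obs, "ss_full"); dfFull <- attr(obs, "df_full")
  dfRes <- n - 1L - dfFull
  msRes <- (sst - ssFull) / dfRes
  fObs <- (obs[, "ss"] / obs[, "df"]) / msRes

  if (!is.null(seed)) set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(nPermutations)) {
    idx <- sample.int(n)
    pm <- seqSS(G[idx, idx])
    fP <- (pm[, "ss"] / pm[, "df"]) /
      ((sst - attr(pm, "ss_full")) / dfRes)
    exceed <- exceed + (fP >= fObs - 1e-12)
  }

  r2 <- obs[, "ss"] / sst
  kCum <- cumsum(obs[, "df"])
  res <- data.frame(term = terms,
                    df = obs[, "df"],
                    R2 = unname(r2),
                    adjusted_R2 = unname(1 - (1 - r2) * (n - 1) / (n - kCum - 1)),
                    pseudo_F = unname(fObs),
                    p_perm = unname((1 + exceed) / (1 + nPermutations)),
                    row.names = NULL)
  attr(res, "full_R2") <- ssFull / sst
  res
}
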