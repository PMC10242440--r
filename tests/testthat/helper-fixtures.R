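# Small in-code fixtures shared across test files.

# write a 3-row merged-profile TSV: two terminal SGB rows (one kSGB, one
# uSGB) plus one non-terminal species row that must be filtered out
writeProfileFixture <- function(path, values = c(40, 60, 30, 40),
                                samples = c("s1", "s2")) {
  lines <- c(
    paste(c("clade_name", samples), collapse = "\t"),
    paste(c("k__Bacteria|f__Lachnospiraceae|g__Lachnospira|s__Lachnospiraceae_bacterium_28_4|t__SGB7272",
            values[1], values[2]), collapse = "\t"),
    paste(c("k__Bacteria|f__Ruminococcaceae|g__GGB4563|s__GGB4563_SGB43546|t__SGB43546",
            values[3], values[4]), collapse = "\t"),
    paste(c("k__Bacteria|f__Lachnospiraceae|g__Lachnospira|s__Lachnospiraceae_bacterium_28_4",
            10, 10), collapse = "\t"))
  writeLines(lines, path)
  path
}

# minimal SGBProfiles: abundance matrix + dataset/diet metadata
makeProfiles <- function(ab, datasets, diet = NULL, known = NULL, ...) {
  if (is.null(colnames(ab))) colnames(ab) <- sprintf("s%02d", seq_len(ncol(ab)))
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("SGB%03d", seq_len(nrow(ab)))
  md <- data.frame(sample_id = colnames(ab), dataset_id = datasets,
                   diet_class = if (is.null(diet)) "high_fat" else diet,
                   ...)
  rownames(md) <- md$sample_id
  fi <- data.frame(feature_id = rownames(ab),
                   clade_name = rownames(ab),
                   known = if (is.null(known)) TRUE else known)
  SGBProfiles(ab, featureInfo = fi, sampleData = md)
}

# two-cluster compositional matrix giving a clean PERMANOVA signal
twoClusterMatrix <- function(nPerGroup = 3, sep = 50, seed = 42) {
  set.seed(seed)
  m <- cbind(matrix(rep(c(sep, 100 - sep), nPerGroup), 2) +
               matrix(abs(rnorm(2 * nPerGroup, 0, 1)), 2),
             matrix(rep(c(100 - sep, sep), nPerGroup), 2) +
               matrix(abs(rnorm(2 * nPerGroup, 0, 1)), 2))
  rownames(m) <- c("SGB001", "SGB002")
  colnames(m) <- sprintf("s%02d", seq_len(2 * nPerGroup))
  m
}

# brute-force partial Spearman by explicit rank residualization
oraclePartialSpearman <- function(y, x, Z) {
  ry <- rank(y); rx <- rank(x)
  Zr <- cbind(1, apply(as.matrix(Z), 2, rank))
  P <- Zr %*% solve(t(Zr) %*% Zr) %*% t(Zr)
  ey <- ry - P %*% ry
  ex <- rx - P %*% rx
  sum(ey * ex) / sqrt(sum(ey^2) * sum(ex^2))
}

# grid-search oracle for the Paule-Mandel generalized Q equation
oracleGridTau2 <- function(effects, variances, upper = 10, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  gq <- vapply(grid, function(t2) {
    w <- 1 / (variances + t2)
    mu <- sum(w * effects) / sum(w)
    sum(w * (effects - mu)^2)
  }, numeric(1))
  k <- length(effects)
  if (gq[1] <= k - 1) return(0)
  grid[which.min(abs(gq - (k - 1)))]
}
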