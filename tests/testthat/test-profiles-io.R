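test_that("merged-profile parsing keeps terminal SGB rows and infers known flags", {
  f <- writeProfileFixture(withr::local_tempfile(fileext = ".tsv"))
  p <- readMergedProfiles(f)
  expect_s4_class(p, "SGBProfiles")
  expect_equal(nrow(p), 2L)          # non-terminal species row dropped
  expect_setequal(rownames(p), c("SGB7272", "SGB43546"))
  expect_true(featureInfo(p)["SGB7272", "known"])
  expect_false(featureInfo(p)["SGB43546", "known"])
  expect_true(featureInfo(p)["SGB7272", "genus_level_assigned"])
  expect_false(featureInfo(p)["SGB43546", "genus_level_assigned"])
})

test_that("a column summing to exactly 100 is accepted unchanged", {
  f <- writeProfileFixture(withr::local_tempfile(fileext = ".tsv"),
                           values = c(40, 60, 60, 40))
  p <- readMergedProfiles(f)
  expect_equal(unname(colSums(abundances(p))), c(100, 100))
  expect_equal(abundances(p)["SGB7272", "s1"], 40)
})

test_that("malformed tables are rejected", {
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeProfileFixture(neg, values = c(-1, 60, 30, 70))
  expect_error(readMergedProfiles(neg), "negative")

  noheader <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\ts1", "k__X|t__SGB1\t5"), noheader)
  expect_error(readMergedProfiles(noheader), "format error")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clade_name\ts1\ts1", "k__X|t__SGB1\t5\t6"), dup)
  expect_error(readMergedProfiles(dup), "duplicate sample")
})

test_that("a sidecar file overrides the naming-based known flag", {
  f <- writeProfileFixture(withr::local_tempfile(fileext = ".tsv"))
  sc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tknown", "SGB43546\tTRUE"), sc)
  p <- readMergedProfiles(f, sidecar = sc)
  expect_true(featureInfo(p)["SGB43546", "known"])
})

test_that("arcsine-square-root transform hits its closed forms and is monotone", {
  expect_equal(arcsinSqrt(0), 0)
  expect_equal(arcsinSqrt(100), pi / 2)
  expect_equal(arcsinSqrt(25), pi / 6)
  expect_error(arcsinSqrt(101), "domain")
  expect_error(arcsinSqrt(-0.1), "domain")
  # strict monotonicity => rank preservation within any sample
  set.seed(11)
  x <- matrix(runif(60, 0, 100), 6)
  tx <- arcsinSqrt(x)
  expect_identical(dim(tx), dim(x))
  for (j in seq_len(ncol(x)))
    expect_identical(rank(tx[, j]), rank(x[, j]))
})

test_that("prevalence averages per-dataset fractions over a fixed denominator", {
  ab <- rbind(SGB001 = c(1, 1, 1, 1, 1, 1),   # everywhere
              SGB002 = c(1, 1, 0, 0, 0, 0),   # dataset A only
              SGB003 = c(1, 0, 1, 1, 0, 0))   # A: 1/2, B: 2/2, C: 0
  p <- makeProfiles(ab, datasets = rep(c("A", "B", "C"), each = 2))
  prev <- computePrevalence(p)
  expect_equal(prev["SGB001", "overall"], 1)
  expect_equal(prev["SGB002", "overall"], 1 / 3)  # absent datasets count as 0
  expect_equal(prev["SGB003", "overall"], (0.5 + 1 + 0) / 3)
  expect_equal(prev$n_datasets_detected, c(3, 1, 2))
  expect_error(computePrevalence(abundances(p)), "key error")
})

test_that("feature filtering uses a strict prevalence bound and inclusive dataset count", {
  prev <- S4Vectors::DataFrame(
    feature_id = c("a", "b", "c"),
    overall = c(0.25, 0.25, 0.20),
    n_datasets_detected = c(5, 4, 6))
  expect_identical(filterFeatures(prev, 0.20, 5), "a")
  expect_identical(filterFeatures(prev, 0.20, 4), c("a", "b"))
  # prevalence exactly at the bound is excluded (">20%")
  expect_false("c" %in% filterFeatures(prev, 0.20, 5))
  # idempotence under re-application with the same thresholds
  kept <- filterFeatures(prev, 0.20, 4)
  expect_identical(filterFeatures(prev[match(kept, prev$feature_id), ], 0.20, 4),
                   kept)
})

test_that("cohort summaries count and sum k/uSGBs with conservation", {
  ab <- matrix(c(20, 20, 20, 20, 20,
                 0, 0, 0, 0, 0), ncol = 2,
               dimnames = list(sprintf("SGB%03d", 1:5), c("s1", "s2")))
  p <- makeProfiles(ab, datasets = "A", known = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  cs <- cohortSummaries(p)
  expect_equal(unlist(cs["s1", c("n_ksgb", "n_usgb")]), c(n_ksgb = 2, n_usgb = 3))
  expect_equal(unlist(cs["s1", c("ksgb_pct", "usgb_pct")]),
               c(ksgb_pct = 40, usgb_pct = 60))
  expect_equal(unlist(cs["s2", c("n_ksgb", "n_usgb", "ksgb_pct", "usgb_pct")]),
               c(n_ksgb = 0, n_usgb = 0, ksgb_pct = 0, usgb_pct = 0))
  # conservation: ksgb% + usgb% equals the column sum
  set.seed(3)
  ab2 <- matrix(runif(50, 0, 2), 10,
                dimnames = list(sprintf("SGB%03d", 1:10), sprintf("s%d", 1:5)))
  p2 <- makeProfiles(ab2, datasets = "A", known = rep(c(TRUE, FALSE), 5))
  cs2 <- cohortSummaries(p2)
  expect_equal(cs2$ksgb_pct + cs2$usgb_pct, unname(colSums(ab2)))
})

test_that("uSGB-dominated synthetic cohorts show ~2x uSGB per-sample counts", {
  g <- generateCohorts(syntheticSpec(nDatasets = 2, samplesPerArm = 10,
                                     nFeatures = 150, nBiomarkers = 4,
                                     fractionUnknown = 2 / 3,
                                     prevalenceRange = c(0.8, 1), seed = 4))
  cs <- cohortSummaries(g$profiles)
  ratio <- mean(cs$n_usgb) / mean(cs$n_ksgb)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("profile and metadata writers round-trip through the readers", {
  g <- generateCohorts(syntheticSpec(nDatasets = 2, samplesPerArm = 4,
                                     nFeatures = 30, nBiomarkers = 2, seed = 9))
  pf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  writeMergedProfiles(g$profiles, pf)
  writeSampleMetadata(g$profiles, mf)
  md <- readSampleMetadata(mf)
  p2 <- readMergedProfiles(pf, metadata = md)
  expect_equal(abundances(p2), abundances(g$profiles), tolerance = 1e-8)
  expect_identical(featureInfo(p2)$known, featureInfo(g$profiles)$known)
  expect_identical(SummarizedExperiment::colData(p2)$diet_class,
                   SummarizedExperiment::colData(g$profiles)$diet_class)
})
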