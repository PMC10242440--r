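makeDatasetMeta <- function(n1 = 10, n2 = 10, seed = 1, dataset = "D1") {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%02d", seq_len(n1 + n2)),
             dataset_id = dataset,
             diet_class = rep(c("high_fat", "low_fat"), c(n1, n2)),
             age_days = round(runif(n1 + n2, 40, 120)),
             sex = sample(c("female", "male"), n1 + n2, replace = TRUE),
             strain = "C57BL/6J", body_site = "feces", antibiotics = FALSE)
}

test_that("t-to-SMD conversion matches its closed forms and is odd in t", {
  # engineered symmetric case: t = 2.1213, n1 = n2 = 10, df = 18 -> d = 1
  r <- tToSMD(2.1213, 10, 10, 18)
  expect_equal(r$d, 2.1213 * 20 / (10 * sqrt(18)), tolerance = 1e-12)
  expect_equal(r$d, 1.0, tolerance = 1e-4)
  # SE at d = 1, n1 = n2 = 10: sqrt((19/17)*(4/20)*1.125) ~ 0.5015
  tUnit <- sqrt(18) / 2                  # t giving exactly d = 1
  rr <- tToSMD(tUnit, 10, 10, 18)
  expect_equal(rr$d, 1.0, tolerance = 1e-12)
  expect_equal(rr$se_d, sqrt((19 / 17) * (4 / 20) * (1 + 1 / 8)), tolerance = 1e-12)
  expect_equal(rr$se_d, 0.5015, tolerance = 1e-4)
  # zero case
  r0 <- tToSMD(0, 6, 8, 12)
  expect_equal(r0$d, 0)
  expect_equal(r0$se_d, sqrt(((6 + 8 - 1) / (6 + 8 - 3)) * 4 / (6 + 8)))
  # odd symmetry
  rp <- tToSMD(1.7, 9, 12, 17); rn <- tToSMD(-1.7, 9, 12, 17)
  expect_equal(rp$d, -rn$d)
  expect_equal(rp$se_d, rn$se_d)
  expect_error(tToSMD(1, 2, 1, 10))     # group size below the contract
})

test_that("per-dataset model with no covariates reproduces the pooled-variance t test", {
  md <- makeDatasetMeta(12, 9, seed = 2)
  set.seed(3)
  y <- rnorm(21, 0.3, 0.05) + 0.04 * (md$diet_class == "high_fat")
  feats <- rbind(SGB001 = y, SGB002 = rnorm(21, 0.2, 0.05))
  colnames(feats) <- md$sample_id
  fit <- fitDatasetLM(feats, md, "D1", covariates = character(0))
  tt <- t.test(y[md$diet_class == "high_fat"], y[md$diet_class == "low_fat"],
               var.equal = TRUE)
  expect_equal(fit$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(fit$p_wald[1], tt$p.value, tolerance = 1e-12)
  expect_equal(fit$df[1], 19)
  expect_equal(fit$n1[1], 12)
  expect_equal(fit$n2[1], 9)
  expect_equal(sign(fit$d), sign(fit$t))
})

test_that("per-dataset model agrees with lm() under covariate adjustment", {
  md <- makeDatasetMeta(10, 10, seed = 4)
  set.seed(5)
  y <- 0.3 + 0.002 * md$age_days + 0.03 * (md$sex == "male") +
    0.05 * (md$diet_class == "high_fat") + rnorm(20, 0, 0.03)
  feats <- rbind(SGB001 = y)
  colnames(feats) <- md$sample_id
  fit <- fitDatasetLM(feats, md, "D1", covariates = c("age_days", "sex"))
  ref <- summary(lm(y ~ age_days + sex + I(diet_class == "high_fat"), data = md))
  expect_equal(fit$t[1], ref$coefficients[4, "t value"], tolerance = 1e-10)
  expect_equal(fit$p_wald[1], ref$coefficients[4, "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(fit$df[1], 16)
})

test_that("null features give t ~ 0 and constant covariates are dropped", {
  md <- makeDatasetMeta(15, 15, seed = 6)
  md$sex <- "female"                      # single-sex dataset
  set.seed(7)
  feats <- rbind(SGB001 = rnorm(30, 0.3, 0.02))
  colnames(feats) <- md$sample_id
  fit <- fitDatasetLM(feats, md, "D1",
                      covariates = c("age_days", "sex", "strain"))
  # sex and strain constant -> dropped; design = intercept + age + diet
  expect_equal(fit$df[1], 30 - 3)
  expect_lt(abs(fit$t[1]), 3)
  expect_gt(fit$p_wald[1], 0.001)
})

test_that("covariate adjustment removes a body-site confounder", {
  set.seed(8)
  reps <- replicate(30, {
    n <- 40
    md <- data.frame(sample_id = sprintf("s%02d", 1:n), dataset_id = "D1",
                     diet_class = rep(c("high_fat", "low_fat"), each = n / 2),
                     body_site = c(rep("cecum", 15), rep("feces", 5),
                                   rep("cecum", 5), rep("feces", 15)))
    dietEff <- 0.05
    y <- 0.3 + dietEff * (md$diet_class == "high_fat") +
      0.08 * (md$body_site == "cecum") + rnorm(n, 0, 0.04)
    feats <- rbind(SGB001 = y); colnames(feats) <- md$sample_id
    adj <- fitDatasetLM(feats, md, "D1", covariates = "body_site")$t
    raw <- fitDatasetLM(feats, md, "D1", covariates = character(0))$t
    c(adj = adj, raw = raw)
  })
  # true adjusted t is ~ dietEff / (sigma * sqrt(4/n)) = 0.05/(0.04*0.316) ~ 3.95
  expect_lt(abs(mean(reps["adj", ]) - 3.95), 1.0)
  # the unadjusted estimate is biased upward by the confounded body-site effect
  expect_gt(mean(reps["raw", ]), mean(reps["adj", ]) + 1)
})

test_that("degenerate and one-class datasets are guarded", {
  md <- makeDatasetMeta(5, 5, seed = 9)
  feats <- rbind(SGB001 = rep(0.5, 10), SGB002 = rnorm(10, 0.4, 0.01))
  colnames(feats) <- md$sample_id
  fit <- fitDatasetLM(feats, md, "D1", covariates = character(0))
  expect_true(is.na(fit$t[1]))            # zero-variance feature -> missing
  expect_false(is.na(fit$t[2]))

  mdOne <- md; mdOne$diet_class <- "high_fat"
  expect_warning(r <- fitDatasetLM(feats, mdOne, "D1", covariates = character(0)),
                 "diet classes")
  expect_null(r)
})

test_that("partial Spearman reduces to ordinary Spearman and matches the oracle", {
  set.seed(10)
  x <- rnorm(25); y <- x + rnorm(25, 0, 0.5)
  r <- partialSpearman(y, x)
  expect_equal(r$rho, cor(y, x, method = "spearman"), tolerance = 1e-12)
  expect_identical(r$n_covariates, 0L)
  # strictly monotone -> rho = 1
  expect_equal(partialSpearman(exp(seq(1, 3, length = 12)),
                               seq(1, 3, length = 12))$rho, 1)
  # 8-point (and larger) fixtures vs explicit rank-residualization oracle
  for (i in 1:10) {
    set.seed(100 + i)
    n <- sample(8:20, 1)
    z <- matrix(rnorm(2 * n), n)
    yy <- rnorm(n) + z[, 1]
    xx <- rnorm(n) + z[, 2]
    expect_equal(partialSpearman(yy, xx, z)$rho,
                 oraclePartialSpearman(yy, xx, z), tolerance = 1e-10)
  }
})

test_that("conditioning removes a shared-driver correlation", {
  set.seed(12)
  rhos <- replicate(200, {
    z <- rnorm(100)
    y <- z + rnorm(100)
    x <- z + rnorm(100)
    partialSpearman(y, x, data.frame(z = z))$rho
  })
  expect_lt(mean(abs(rhos)), 0.1)
  # constant input yields a missing record
  expect_warning(r <- partialSpearman(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(r$rho))
})
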