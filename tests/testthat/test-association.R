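make_cohort_geno <- function(counts, chrom = "1") {
  m <- ncol(counts)
  genotype_matrix(counts,
                  data.frame(chrom = chrom, id = paste0("v", seq_len(m)),
                             pos = seq_len(m) * 1000, a1 = "A", a2 = "B"),
                  data.frame(fid = "0",
                             iid = sprintf("i%04d", seq_len(nrow(counts)))))
}

test_that("single-variant scan matches a hand-computed least-squares oracle", {
  # 8 individuals, one variant, one covariate, hand-typed values
  g <- c(0, 1, 2, 0, 1, 2, 1, 0)
  x <- c(1.2, -0.4, 0.3, 2.1, -1.0, 0.5, 0.0, -0.7)
  y <- c(0.5, 1.1, 2.3, -0.2, 0.8, 2.9, 1.4, 0.1)
  geno <- make_cohort_geno(matrix(as.integer(g), 8))
  covar <- covariate_table(data.frame(fid = "0",
                                      iid = sprintf("i%04d", 1:8), x = x))
  res <- dn_scan(geno, y, covar)

  gs <- standardize_genotypes(geno)
  oracle <- joint_ols_oracle(gs$values, y, cbind(1, x))
  expect_equal(res$BETA[1], unname(oracle[1, "beta"]), tolerance = 1e-10)
  expect_equal(res$SE[1], unname(oracle[1, "se"]), tolerance = 1e-10)
  expect_equal(res$CHISQ[1], (res$BETA[1] / res$SE[1])^2, tolerance = 1e-10)
  expect_equal(res$P[1],
               pchisq(res$CHISQ[1], 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("residualize-both equals the joint fit on random systems", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(20:40, 1)
    m <- sample(2:5, 1)
    counts <- matrix(rbinom(n * m, 2, 0.3), n, m)
    Z <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    y <- rnorm(n)
    geno <- make_cohort_geno(counts)
    covar <- covariate_table(data.frame(fid = "0",
                                        iid = sprintf("i%04d", 1:n),
                                        c1 = Z[, 1], c2 = Z[, 2]))
    res <- dn_scan(geno, y, covar)
    gs <- standardize_genotypes(geno)
    keep <- !gs$excluded
    oracle <- joint_ols_oracle(gs$values[, keep, drop = FALSE], y,
                               cbind(1, Z))
    expect_equal(res$BETA[keep], unname(oracle[, "beta"]), tolerance = 1e-8)
    expect_equal(res$SE[keep], unname(oracle[, "se"]), tolerance = 1e-8)
  }
})

test_that("null scans are calibrated: mean chi-square near 1, uniform p", {
  set.seed(12)
  n <- 2000; m <- 500
  counts <- matrix(rbinom(n * m, 2, runif(m, 0.05, 0.5)[col(matrix(0, n, m))]),
                   n, m)
  geno <- make_cohort_geno(counts)
  covar <- covariate_table(data.frame(fid = "0", iid = sprintf("i%04d", 1:n),
                                      age = rnorm(n)))
  y <- rnorm(n) + 0.3 * covar$age
  res <- dn_scan(geno, y, covar)
  ok <- !res$EXCLUDED
  mc_se <- sd(res$CHISQ[ok]) / sqrt(sum(ok))
  expect_lt(abs(mean(res$CHISQ[ok]) - 1), 3 * mc_se)
  ks <- suppressWarnings(ks.test(res$P[ok], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("residualize projects onto the orthogonal complement", {
  set.seed(13)
  Z <- cbind(1, rnorm(30), rnorm(30))
  M <- matrix(rnorm(90), 30, 3)
  R <- residualize(M, Z)
  expect_lt(max(abs(crossprod(Z, R))) / max(abs(M)), 1e-8)
  # idempotence and fixed point
  expect_equal(residualize(R, Z), R, tolerance = 1e-10)
  expect_error(residualize(M, cbind(Z, Z[, 2])), "rank deficient")
})

test_that("rank-deficient designs are rejected with the offending column", {
  set.seed(14)
  n <- 50
  counts <- matrix(rbinom(n * 2, 2, 0.4), n, 2)
  geno <- make_cohort_geno(counts)
  covar <- covariate_table(data.frame(fid = "0", iid = sprintf("i%04d", 1:n),
                                      age = rnorm(n), sex = rbinom(n, 1, .5)))
  y <- rnorm(n)
  # prediction that is an exact linear function of the covariates
  pred <- setNames(2 * covar$age - covar$sex + 1, dn_key(covar$fid, covar$iid))
  expect_error(dn_scan(geno, y, covar, prediction = pred), "deepnull_pred")
})

test_that("zero-variance variants are flagged, not fatal", {
  n <- 40
  counts <- cbind(rbinom(n, 2, 0.4), rep(1L, n))
  geno <- make_cohort_geno(counts)
  res <- dn_scan(geno, rnorm(n))
  expect_true(res$EXCLUDED[2])
  expect_true(is.na(res$BETA[2]))
  expect_false(res$EXCLUDED[1])
})

test_that("doubling the phenotype doubles beta and se, chi-square invariant", {
  set.seed(15)
  n <- 100
  counts <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  geno <- make_cohort_geno(counts)
  covar <- covariate_table(data.frame(fid = "0", iid = sprintf("i%04d", 1:n),
                                      age = rnorm(n)))
  y <- rnorm(n)
  r1 <- dn_scan(geno, y, covar)
  r2 <- dn_scan(geno, 2 * y, covar)
  ok <- !r1$EXCLUDED
  expect_equal(r2$BETA[ok], 2 * r1$BETA[ok])
  expect_equal(r2$SE[ok], 2 * r1$SE[ok])
  expect_equal(r2$CHISQ[ok], r1$CHISQ[ok], tolerance = 1e-10)
})

test_that("summary statistics round-trip through the tab-separated format", {
  set.seed(16)
  n <- 30
  counts <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  res <- dn_scan(make_cohort_geno(counts), rnorm(n))
  path <- withr::local_tempfile()
  write_sumstats(res, path, stamp = list(seed = 16))
  res2 <- read_sumstats(path)
  expect_equal(res2$BETA, res$BETA, tolerance = 1e-12)
  expect_equal(res2$P, res$P, tolerance = 1e-12)
  expect_identical(res2$ID, res$ID)
})

test_that("bias estimators: independence kills the bias, correlation biases
          only the unadjusted model", {
  dat0 <- simulate_bias_demo(n = 800, rho = 0, beta = 1, replicates = 400,
                             seed = 21)
  for (mode in c("unadjusted", "adjusted", "generative")) {
    est <- bias_demo_estimates(dat0, mode)
    expect_lt(abs(est$z), 3)
  }
  dat5 <- simulate_bias_demo(n = 800, rho = 0.5, beta = 1, replicates = 400,
                             seed = 22)
  expect_gt(abs(bias_demo_estimates(dat5, "unadjusted")$z), 3)
  expect_lt(abs(bias_demo_estimates(dat5, "adjusted")$z), 3)
  expect_lt(abs(bias_demo_estimates(dat5, "generative")$z), 3)

  expect_error(bias_demo_estimates(
    simulate_bias_demo(n = 50, beta = 0, replicates = 2, seed = 1),
    "unadjusted"), "beta = 0")
})

test_that("unadjusted bias matches its large-sample population value", {
  # finite-replicate mean of the unadjusted estimator vs a single huge-n fit
  dat <- simulate_bias_demo(n = 1000, rho = 0.5, beta = 1, replicates = 400,
                            seed = 23)
  est <- bias_demo_estimates(dat, "unadjusted")
  big <- simulate_bias_demo(n = 5e5, rho = 0.5, beta = 1, replicates = 1,
                            seed = 24)
  bigest <- bias_demo_estimates(big, "unadjusted")
  expect_lt(abs(est$relative_bias - bigest$relative_bias), 3 * est$se + 0.01)
})
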