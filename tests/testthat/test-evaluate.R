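fake_assoc <- function(chisq, p = NULL, chrom = "1", pos = NULL,
                       id = NULL, beta = NULL) {
  m <- length(chisq)
  p <- p %||% pchisq(chisq, 1, lower.tail = FALSE)
  out <- data.frame(CHR = chrom, POS = pos %||% seq_len(m) * 1000,
                    ID = id %||% paste0("v", seq_len(m)), A1 = "A",
                    BETA = beta %||% sqrt(chisq), SE = 1, CHISQ = chisq,
                    P = p, N = 100, EXCLUDED = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("dn_assoc", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("scan evaluation computes stratified rates and means", {
  res <- fake_assoc(c(0, 1, 2, 3, 8, 9), p = c(1, 1, 1, 1, 1, 1))
  ev <- eval_scan(res, causal = c("v5", "v6"), alpha = 0.05)
  expect_equal(ev$power, 0)
  expect_equal(ev$type_I, 0)
  # injected chi-squares for four nulls average exactly
  expect_equal(ev$expected_chi2_null, 1.5)
  expect_equal(ev$expected_chi2_causal, 8.5)
  expect_equal(ev$n_causal, 2)

  # empty stratum reported absent
  ev2 <- eval_scan(res, causal = character(0))
  expect_true(is.na(ev2$power))
  expect_error(eval_scan(res, causal = "nope"), "missing")

  # lowering alpha never increases power or type-I error
  set.seed(1)
  res3 <- fake_assoc(rchisq(200, 1, ncp = 2))
  caus <- paste0("v", 1:100)
  alphas <- c(0.2, 0.05, 0.01, 1e-4)
  evs <- lapply(alphas, function(a) eval_scan(res3, caus, a))
  expect_true(all(diff(sapply(evs, `[[`, "power")) <= 0))
  expect_true(all(diff(sapply(evs, `[[`, "type_I")) <= 0))
})

test_that("greedy clumping matches a brute-force oracle on a toy instance", {
  # 5 variants: v1 and v2 perfectly correlated, v4 = noisy copy of v3,
  # v5 independent
  set.seed(2)
  n <- 400
  base <- rbinom(n, 2, 0.4)
  other <- rbinom(n, 2, 0.4)
  flip <- function(g, k) { i <- sample(n, k); g[i] <- 2 - g[i]; g }
  counts <- cbind(v1 = base, v2 = base, v3 = other, v4 = flip(other, 30),
                  v5 = rbinom(n, 2, 0.4))
  panel <- genotype_matrix(counts,
                           data.frame(chrom = "1", id = colnames(counts),
                                      pos = c(100, 200, 5000, 5100, 9000),
                                      a1 = "A", a2 = "B"),
                           data.frame(fid = "0", iid = sprintf("i%04d", 1:n)))
  pvals <- c(1e-10, 1e-12, 1e-9, 1e-8, 0.5)
  res <- fake_assoc(rep(50, 5), p = pvals, pos = panel$variants$pos,
                    id = colnames(counts))

  hits <- clump(res, panel, p_thresh = 5e-8, r2_thresh = 0.1)

  # brute-force greedy oracle by explicit enumeration
  oracle_leads <- local({
    cc <- cor(counts)^2
    sig <- order(pvals)[pvals[order(pvals)] <= 5e-8]
    leads <- integer(0)
    while (length(sig)) {
      lead <- sig[1]
      leads <- c(leads, lead)
      sig <- sig[cc[lead, sig] < 0.1]
    }
    colnames(counts)[leads]
  })
  expect_identical(hits$ID, oracle_leads)
  expect_identical(hits$ID[1], "v2")       # smallest p leads
  expect_false("v5" %in% hits$ID)          # not significant

  # spans cover the correlated partners
  expect_equal(hits$SPAN_START[hits$ID == "v2"], 100)
  expect_equal(hits$SPAN_END[hits$ID == "v2"], 200)

  # pairwise independence of the output at the threshold
  idx <- match(hits$ID, colnames(counts))
  if (length(idx) > 1) {
    cc <- cor(counts[, idx])^2
    expect_lt(max(cc[upper.tri(cc)]), 0.1)
  }

  # nothing significant -> empty result
  res_ns <- fake_assoc(rep(1, 5), id = colnames(counts),
                       pos = panel$variants$pos)
  expect_equal(nrow(clump(res_ns, panel)), 0)
})

test_that("locus merging is single-linkage within 250 kb", {
  mk_hits <- function(pos, chrom = "1") {
    h <- data.frame(ID = paste0("h", seq_along(pos)), CHR = chrom, POS = pos,
                    P = 1e-9, BETA = 1, SPAN_START = pos - 10,
                    SPAN_END = pos + 10, stringsAsFactors = FALSE)
    class(h) <- c("dn_hits", "data.frame")
    h
  }
  expect_equal(nrow(merge_loci(mk_hits(c(100000, 500000)))), 2)
  expect_equal(nrow(merge_loci(mk_hits(c(100000, 300000)))), 1)
  # transitive chain: 0 / 200k / 400k merges into one locus even though the
  # endpoints are 400 kb apart (checked against explicit pairwise distances)
  chain <- mk_hits(c(0, 200000, 400000))
  expect_true(diff(range(chain$POS)) > 250000)
  loci <- merge_loci(chain)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$N_HITS, 3)

  # different chromosomes never merge
  h2 <- mk_hits(c(100000, 150000))
  h2$CHR <- c("1", "2")
  expect_equal(nrow(merge_loci(h2)), 2)

  # locus count <= hit count, and surviving loci are separated by > window
  set.seed(3)
  hr <- mk_hits(sort(sample.int(5e6, 40)))
  lr <- merge_loci(hr)
  expect_lte(nrow(lr), nrow(hr))
  gap <- lr$START[-1] - lr$END[-nrow(lr)]
  expect_true(all(diff(sort(tapply(hr$POS, cumsum(
    c(TRUE, diff(hr$POS) > 250000)), min))) > 250000))

  expect_equal(nrow(merge_loci(mk_hits(100)[0, ])), 0)
})

test_that("scan comparison classifies hits by span overlap", {
  mk <- function(chrom, start, end) {
    h <- data.frame(ID = paste0("h", seq_along(chrom)), CHR = chrom,
                    POS = (start + end) %/% 2, P = 1e-9, BETA = 1,
                    SPAN_START = start, SPAN_END = end,
                    stringsAsFactors = FALSE)
    class(h) <- c("dn_hits", "data.frame")
    h
  }
  a <- mk(c("1", "1", "2"), c(100, 5000, 100), c(200, 6000, 200))
  expect_true(all(compare_scans(a, a)$SHARED))

  b <- mk(c("3", "3", "3"), c(100, 5000, 100), c(200, 6000, 200))
  expect_false(any(compare_scans(a, b)$SHARED))

  # exactly one overlapping pair in a 3 vs 3 toy
  c3 <- mk(c("1", "2", "2"), c(150, 300, 900), c(180, 400, 950))
  got <- compare_scans(a, c3)
  expect_equal(got$SHARED, c(TRUE, FALSE, FALSE))

  a_nospan <- a; a_nospan$SPAN_START <- NA
  expect_error(compare_scans(a_nospan, b), "spans")
})

test_that("prediction R-squared is squared Pearson correlation with bootstrap SE", {
  set.seed(4)
  y <- rnorm(100)
  expect_equal(prediction_r2(y, y, bootstrap_trials = 10)$r2, 1)
  expect_equal(prediction_r2(y, -y, bootstrap_trials = 10)$r2, 1)

  n <- 10000
  x <- rnorm(n)
  yh <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  pr <- prediction_r2(x, yh, bootstrap_trials = 200, seed = 5)
  expect_lt(abs(pr$r2 - 0.36), 3 * pr$se)
  expect_gt(pr$se, 0)

  expect_warning(out <- prediction_r2(y, rep(1, 100)), "zero variance")
  expect_equal(out$r2, 0)
  expect_error(prediction_r2(1:2, 1:2), "lengths")
})

test_that("polygenic scores are clump-and-sum over standardized genotypes", {
  set.seed(6)
  n <- 50
  counts <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  geno <- genotype_matrix(counts,
                          data.frame(chrom = "1", id = c("a", "b", "c"),
                                     pos = 1:3, a1 = "A", a2 = "B"),
                          data.frame(fid = "0", iid = sprintf("i%03d", 1:n)))
  gs <- standardize_genotypes(geno)
  mk_hits <- function(ids, betas) {
    h <- data.frame(ID = ids, CHR = "1", POS = 1, P = 1e-9, BETA = betas,
                    SPAN_START = 1, SPAN_END = 2, stringsAsFactors = FALSE)
    class(h) <- c("dn_hits", "data.frame")
    h
  }
  s1 <- prs_score(gs, mk_hits("b", 1))
  expect_equal(unname(s1), unname(gs$values[, 2]))

  expect_equal(unname(prs_score(gs, mk_hits(c("a", "c"), c(0, 0)))),
               rep(0, n))

  s2 <- prs_score(gs, mk_hits(c("a", "c"), c(0.5, -2)))
  expect_equal(unname(s2),
               unname(0.5 * gs$values[, 1] - 2 * gs$values[, 3]))

  expect_warning(s0 <- prs_score(gs, mk_hits("a", 1)[0, ]),
                 "empty")
  expect_equal(unname(s0), rep(0, n))
})

test_that("hit and locus intervals export as BED-like tables", {
  h <- data.frame(ID = "h1", CHR = "1", POS = 500, P = 1e-9, BETA = 1,
                  SPAN_START = 400, SPAN_END = 600, stringsAsFactors = FALSE)
  class(h) <- c("dn_hits", "data.frame")
  path <- withr::local_tempfile()
  write_intervals(h, path)
  got <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(got$start, 400)
  write_intervals(merge_loci(h), path)
  expect_equal(read.table(path, header = TRUE, sep = "\t")$lead_id, "h1")
})
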