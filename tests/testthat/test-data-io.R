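test_that("text genotype format round-trips counts, metadata and missing", {
  g <- toy_geno()
  path <- withr::local_tempfile(fileext = ".txt")
  write_genotypes(g, path, format = "text")
  g2 <- read_genotypes(path, format = "text")
  expect_identical(unname(g$counts), unname(g2$counts))
  expect_identical(g$variants$chrom, g2$variants$chrom)
  expect_identical(g$variants$pos, g2$variants$pos)
  expect_identical(g$variants$a1, g2$variants$a1)
  expect_identical(g$samples, g2$samples)

  # hand-written file with stated counts
  hand <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("FID IID v1 v2", "f1 i1 0 2", "f2 i2 1 NA", "f3 i3 2 0"), hand)
  gh <- read_genotypes(hand, format = "text")
  expect_equal(unname(gh$counts),
               matrix(c(0L, 1L, 2L, 2L, NA, 0L), nrow = 3))
  expect_identical(gh$variants$id, c("v1", "v2"))
})

test_that("plink bed round-trips and matches a hand-decoded byte fixture", {
  set.seed(9)
  for (n in c(4L, 7L)) {   # exercises both full and padded final byte groups
    m <- 3L
    counts <- matrix(sample(c(0:2, NA), n * m, replace = TRUE), n, m)
    g <- genotype_matrix(
      counts,
      data.frame(chrom = "1", id = paste0("v", 1:m), pos = 1:m * 100,
                 a1 = c("A", "T", "C"), a2 = c("G", "A", "T")),
      data.frame(fid = paste0("f", 1:n), iid = paste0("i", 1:n)))
    stem <- withr::local_tempfile()
    write_genotypes(g, stem)
    g2 <- read_genotypes(paste0(stem, ".bed"))
    expect_identical(unname(g$counts), unname(g2$counts))
    expect_identical(g$variants$a1, g2$variants$a1)
  }

  # independent fixture: bytes assembled by hand for a 4 x 3 matrix.
  # two-bit codes per sample (low bits first): 00 -> 2, 10 -> 1, 11 -> 0,
  # 01 -> missing. Variant columns below are (2,1,0,NA), (0,0,2,2), (1,1,1,1).
  stem <- withr::local_tempfile()
  bytes <- as.raw(c(0x6c, 0x1b, 0x01,
                    0x78,   # codes 0,2,3,1 (samples 1..4 in low-to-high bits)
                    0x0f,   # codes 3,3,0,0
                    0xaa))  # codes 2,2,2,2
  writeBin(bytes, paste0(stem, ".bed"))
  writeLines(c("1\tva\t0\t100\tA\tG", "1\tvb\t0\t200\tC\tT",
               "2\tvc\t0\t300\tG\tA"), paste0(stem, ".bim"))
  writeLines(paste(paste0("f", 1:4), paste0("i", 1:4), "0 0 0 -9"),
             paste0(stem, ".fam"))
  g3 <- read_genotypes(paste0(stem, ".bed"))
  expect_identical(unname(g3$counts),
                   matrix(c(2L, 1L, 0L, NA, 0L, 0L, 2L, 2L, 1L, 1L, 1L, 1L),
                          nrow = 4))

  # cross-check against a second, independently coded decoder based on
  # integer arithmetic rather than a lookup table
  decode2 <- function(bed, n, m) {
    raw <- readBin(bed, "raw", n = file.size(bed))[-(1:3)]
    bpv <- ceiling(n / 4)
    out <- matrix(NA_integer_, n, m)
    for (j in seq_len(m)) for (i in seq_len(n)) {
      byte <- as.integer(raw[(j - 1) * bpv + ((i - 1) %/% 4) + 1])
      code <- (byte %/% 4^((i - 1) %% 4)) %% 4
      out[i, j] <- c(2L, NA, 1L, 0L)[code + 1]
    }
    out
  }
  expect_identical(unname(g3$counts), decode2(paste0(stem, ".bed"), 4, 3))

  # malformed magic bytes are reported with the file name
  bad <- withr::local_tempfile(fileext = ".bed")
  writeBin(as.raw(c(0x00, 0x1b, 0x01)), bad)
  writeLines("1\tv\t0\t1\tA\tG", sub("bed$", "bim", bad))
  writeLines("f i 0 0 0 -9", sub("bed$", "fam", bad))
  expect_error(read_genotypes(bad), "magic")
})

test_that("table reader enforces the FID/IID dialect and locates bad cells", {
  path <- withr::local_tempfile()
  writeLines(c("FID IID age sex", "f1 i1 30 1", "f2 i2 NA 0"), path)
  tab <- read_table(path, "covariate")
  expect_s3_class(tab, "covariate_table")
  expect_equal(tab$age, c(30, NA))
  expect_equal(nrow(tab), 2)

  # round trip
  out <- withr::local_tempfile()
  write_table(tab, out, stamp = list(seed = 1))
  tab2 <- read_table(out, "covariate")
  expect_equal(as.data.frame(tab), as.data.frame(tab2))

  writeLines(c("FID name age", "f1 i1 30"), path)
  expect_error(read_table(path, "covariate"), "FID and IID")

  writeLines(c("FID IID age", "f1 i1 thirty"), path)
  expect_error(read_table(path, "covariate"), "row 1 column age")

  writeLines(c("FID IID y extra", "f1 i1 1 2"), path)
  expect_error(read_table(path, "phenotype"), "exactly one value column")
})

test_that("covariate tables validate keys and keep PCs out of the DNN set", {
  df <- data.frame(fid = c("a", "a"), iid = c("1", "2"),
                   age = c(1, 2), PC1 = c(0.1, 0.2))
  ct <- covariate_table(df)
  expect_identical(attr(ct, "non_genetic"), "age")
  expect_identical(attr(ct, "adjustment"), c("age", "PC1"))
  expect_error(covariate_table(df, non_genetic = c("age", "PC1")), "PC-like")
  expect_error(covariate_table(df[c(1, 1), ]), "duplicated")
})

test_that("column standardization is exact, excludes constants, idempotent", {
  s <- standardize_columns(cbind(a = c(0, 0, 2, 2), b = c(1, 1, 1, 1)))
  expect_equal(unname(s$values[, 1]), c(-1, -1, 1, 1))
  expect_true(s$excluded["b"])
  expect_false(s$excluded["a"])
  expect_error(standardize_columns(matrix(1, 4, 2)), "no usable columns")

  set.seed(4)
  M <- matrix(rnorm(500, mean = 3, sd = 7), 100, 5)
  s <- standardize_columns(M)
  expect_lt(max(abs(colMeans(s$values))), 1e-8)
  expect_lt(max(abs(colMeans(s$values^2) - 1)), 1e-8)
  # idempotence
  s2 <- standardize_columns(s$values)
  expect_lt(max(abs(s2$values - s$values)), 1e-8)
  # the input is never modified
  expect_gt(abs(mean(M)), 1)
})

test_that("stored standardization applies to held-out rows without leakage", {
  set.seed(5)
  M <- matrix(rnorm(200), 40, 5)
  tr <- 1:30; ho <- 31:40
  s <- standardize_columns(M[tr, ])
  got <- apply_standardization(M[ho, ], s)
  want <- sweep(sweep(M[ho, ], 2, s$center, "-"), 2, s$scale, "/")
  expect_equal(got, want)
  # held-out rows keep nonzero means under the training-fold transform
  expect_gt(max(abs(colMeans(got))), 0.01)
})

test_that("genotype standardization mean-imputes missing and flags monomorphs", {
  g <- toy_geno()
  gs <- standardize_genotypes(g)
  expect_lt(max(abs(colMeans(gs$values))), 1e-12)
  expect_equal(unname(colMeans(gs$values^2)), c(1, 1))
  # imputed entry sits at the column mean, i.e. exactly 0 after centering
  expect_equal(unname(gs$values[2, 2]), 0)

  mono <- genotype_matrix(matrix(1L, 4, 1),
                          data.frame(chrom = "1", id = "v", pos = 1,
                                     a1 = "A", a2 = "G"),
                          data.frame(fid = as.character(1:4),
                                     iid = as.character(1:4)))
  expect_true(standardize_genotypes(mono)$excluded[1])
})
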