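# Shared fixtures, all built in code at test time.

# small hand-typed genotype matrix with a missing entry and both homozygote
# classes represented
toy_geno <- function() {
  counts <- matrix(c(0L, 1L, 2L,
                     2L, NA, 0L), nrow = 3)
  genotype_matrix(
    counts,
    variants = data.frame(chrom = c("1", "2"), id = c("rs1", "rs2"),
                          pos = c(1000L, 2000L), a1 = c("A", "C"),
                          a2 = c("G", "T"), stringsAsFactors = FALSE),
    samples = data.frame(fid = c("f1", "f2", "f3"),
                         iid = c("i1", "i2", "i3"),
                         stringsAsFactors = FALSE))
}

# fast training configuration for unit tests
test_config <- function(epochs = 60, batch_size = 256, checkpoint_every = 10,
                        seed = 42, ...) {
  dn_desk_config(epochs = epochs, batch_size = batch_size,
                 checkpoint_every = checkpoint_every, seed = seed, ...)
}

# joint per-variant OLS oracle: fit y ~ [Z | g_j] by normal equations and
# return beta_j, se_j (unbiased residual variance). Independent of dn_scan.
joint_ols_oracle <- function(gmat, y, Z) {
  t(vapply(seq_len(ncol(gmat)), function(j) {
    X <- cbind(Z, g = gmat[, j])
    XtX <- crossprod(X)
    co <- solve(XtX, crossprod(X, y))
    res <- y - X %*% co
    s2 <- sum(res^2) / (length(y) - ncol(X))
    se <- sqrt(s2 * solve(XtX)[ncol(X), ncol(X)])
    c(beta = co[ncol(X)], se = se)
  }, c(beta = 0, se = 0)))
}
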