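# Per-variant association scan: OLS with a Wald chi-square per variant,
# computed by residualizing both phenotype and genotype on the covariate
# design (Frisch-Waugh-Lovell), which matches the joint fit exactly and costs
# one projection instead of m.

#' Residualize a matrix on a covariate design
#'
#' Returns P M where P = I - Z (Z'Z)^-1 Z' projects onto the orthogonal
#' complement of the column span of Z. The result is orthogonal to every
#' column of Z; applying the projector twice is the identity on its image.
#'
#' @param M numeric vector or matrix (n rows).
#' @param Z numeric n x p covariate design of full column rank.
#' @return matrix (or vector) of residuals.
#' @export
residualize <- function(M, Z) {
  Z <- as.matrix(Z)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    dn_stop("residualize: design is rank deficient (rank %d of %d columns)",
            qz$rank, ncol(Z))
  qr.resid(qz, as.matrix(M))
}

# Build the linear adjustment design [1 | X-tilde | h], with rank checking
# that names the offending columns.
dn_design <- function(n, covariates = NULL, columns = NULL, prediction = NULL,
                      intercept = TRUE, keys = NULL) {
  parts <- list()
  if (intercept) parts[["(Intercept)"]] <- rep(1, n)
  if (!is.null(covariates)) {
    columns <- columns %||% attr(covariates, "adjustment") %||%
      setdiff(names(covariates), c("fid", "iid"))
    cv <- as.data.frame(covariates)
    if (!is.null(keys)) {
      idx <- match(keys, dn_key(cv$fid, cv$iid))
      if (anyNA(idx)) dn_stop("dn_design: %d samples missing from covariates",
                              sum(is.na(idx)))
      cv <- cv[idx, , drop = FALSE]
    }
    for (col in columns) {
      if (is.null(cv[[col]])) dn_stop("dn_design: unknown column %s", col)
      parts[[col]] <- cv[[col]]
    }
  }
  if (!is.null(prediction)) {
    if (!is.null(keys) && !is.null(names(prediction))) {
      idx <- match(keys, names(prediction))
      if (anyNA(idx)) dn_stop("dn_design: %d samples missing a prediction",
                              sum(is.na(idx)))
      prediction <- prediction[idx]
    }
    parts[["deepnull_pred"]] <- as.numeric(prediction)
  }
  Z <- do.call(cbind, parts)
  colnames(Z) <- names(parts)
  if (anyNA(Z)) dn_stop("dn_design: missing values in the design")
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dropped <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    dn_stop("dn_design: rank-deficient design; collinear column(s): %s",
            paste(dropped, collapse = ", "))
  }
  Z
}

#' Per-variant association scan
#'
#' Tests each variant j with the linear model
#' y = g_j beta_j + (covariate design) gamma + error, where the design holds
#' an intercept, the adjustment covariates, and optionally the cross-fitted
#' phenotype prediction as one extra column. Implemented by projecting y and
#' all genotype columns on the design once and running the simple regressions
#' on the residuals; this equals the joint per-variant OLS fit exactly. The
#' Wald statistic is (beta/se)^2 on 1 df; the residual variance uses
#' df = n - (design columns + 1).
#'
#' @param geno \code{\link{standardized_genotypes}} (or genotype_matrix, which
#'   is standardized on the fly).
#' @param y phenotype: named vector, phenotype_table, or plain vector aligned
#'   with \code{geno} rows.
#' @param covariates optional \code{\link{covariate_table}}.
#' @param columns covariate columns for the adjustment set (default: the
#'   table's adjustment attribute).
#' @param prediction optional cross-fitted prediction (named vector or
#'   \code{deepnull} fit) appended as the \code{deepnull_pred} column.
#' @param intercept include an intercept (default TRUE).
#' @param alpha unused here; significance is decided downstream.
#' @return data.frame of class \code{dn_assoc} with columns CHR, POS, ID, A1,
#'   BETA, SE, CHISQ, P, N and EXCLUDED (zero-variance variants get NA
#'   statistics and EXCLUDED = TRUE). P values are floored at 1e-300.
#' @export
dn_scan <- function(geno, y, covariates = NULL, columns = NULL,
                    prediction = NULL, intercept = TRUE, alpha = NULL) {
  if (inherits(geno, "genotype_matrix")) geno <- standardize_genotypes(geno)
  if (!inherits(geno, "standardized_genotypes"))
    dn_stop("dn_scan: geno must be (standardized) genotypes")
  keys <- dn_key(geno$samples$fid, geno$samples$iid)
  if (inherits(y, "phenotype_table") || is.data.frame(y)) y <- phenotype_vector(y)
  if (!is.null(names(y))) {
    idx <- match(keys, names(y))
    if (anyNA(idx)) dn_stop("dn_scan: %d genotyped samples lack a phenotype",
                            sum(is.na(idx)))
    y <- as.numeric(y[idx])
  }
  n <- nrow(geno$values)
  if (length(y) != n) dn_stop("dn_scan: phenotype length %d, expected %d",
                              length(y), n)
  if (inherits(prediction, "deepnull")) prediction <- prediction$prediction
  Z <- dn_design(n, covariates, columns, prediction, intercept, keys = keys)

  # Residualize-both via the thin orthonormal basis Q of the design:
  # ||P g_j||^2 = ||g_j||^2 - ||Q'g_j||^2 and <P g_j, P y> = g_j'(y - QQ'y),
  # so the per-variant statistics come from two small matrix products without
  # ever materializing the n x m residual matrix. Equals joint OLS exactly.
  qz <- qr(Z)
  Q <- qr.Q(qz)
  ry <- y - drop(Q %*% crossprod(Q, y))
  G <- geno$values
  QtG <- crossprod(Q, G)
  denom <- .colsums_sq(G) - colSums(QtG^2)
  denom[denom < 0] <- 0
  usable <- !geno$excluded & denom > n * 1e-12
  df <- n - ncol(Z) - 1L
  if (df < 1) dn_stop("dn_scan: fewer samples than design columns")

  beta <- se <- chisq <- p <- rep(NA_real_, ncol(G))
  xy <- drop(crossprod(G, ry))
  beta[usable] <- xy[usable] / denom[usable]
  rss <- sum(ry^2) - beta[usable]^2 * denom[usable]
  rss[rss < 0] <- 0
  sigma2 <- rss / df
  se[usable] <- sqrt(sigma2 / denom[usable])
  chisq[usable] <- (beta[usable] / se[usable])^2
  p[usable] <- pmax(stats::pchisq(chisq[usable], 1, lower.tail = FALSE),
                    1e-300)

  v <- geno$variants
  out <- data.frame(CHR = v$chrom, POS = v$pos, ID = v$id, A1 = v$a1,
                    BETA = beta, SE = se, CHISQ = chisq, P = p,
                    N = n, EXCLUDED = !usable,
                    stringsAsFactors = FALSE)
  class(out) <- c("dn_assoc", "data.frame")
  attr(out, "design_columns") <- colnames(Z)
  out
}

#' Write / read association summary statistics
#'
#' Tab-separated with columns CHR, POS, ID, A1, BETA, SE, CHISQ, P (plus N),
#' consumable by standard post-GWAS tools. Excluded variants are written with
#' NA statistics.
#'
#' @param assoc \code{dn_assoc} data.frame.
#' @param path file path.
#' @param stamp optional named list echoed as header comments.
#' @return invisibly, the path (writer) / the table (reader).
#' @export
write_sumstats <- function(assoc, path, stamp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(dn_stamp(stamp), con)
  utils::write.table(as.data.frame(assoc)[, c("CHR", "POS", "ID", "A1",
                                              "BETA", "SE", "CHISQ", "P", "N")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  lines <- dn_read_lines_nocomment(path)
  out <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           colClasses = c(CHR = "character", ID = "character",
                                          A1 = "character"))
  out$EXCLUDED <- is.na(out$BETA)
  class(out) <- c("dn_assoc", "data.frame")
  out
}

#' Estimator comparison for the adjusted-covariate bias demonstration
#'
#' Given replicate data from \code{\link{simulate_bias_demo}} (phenotype
#' y = g beta + x gamma1 + x^2 gamma2 + e with the fitted oracle-form
#' prediction h of y from (1, x, x^2) attached), estimates the genetic effect
#' beta
#' under three models: \code{unadjusted} regresses y on [1, g, h(x)]
#' (the raw covariate omitted), \code{adjusted} on [1, g, x, h(x)], and
#' \code{generative} on [1, g, x, x^2]. The unadjusted estimator is biased
#' whenever g and x are correlated; the adjusted and generative estimators
#' are not.
#'
#' @param data \code{bias_demo_data} from \code{\link{simulate_bias_demo}}.
#' @param mode one of "unadjusted", "adjusted", "generative".
#' @return list of class \code{dn_bias_est}: per-replicate \code{beta_hat},
#'   \code{relative_bias} = (mean(beta_hat) - beta) / beta, its Monte-Carlo
#'   \code{se}, and the z statistic \code{z = relative_bias / se}.
#' @export
bias_demo_estimates <- function(data,
                                mode = c("unadjusted", "adjusted",
                                         "generative")) {
  mode <- match.arg(mode)
  beta <- data$params$beta
  if (beta == 0)
    dn_stop("bias_demo_estimates: relative bias undefined at beta = 0")
  bh <- vapply(seq_len(data$params$replicates), function(r) {
    g <- data$g[, r]; x <- data$x[, r]; y <- data$y[, r]; h <- data$h[, r]
    Z <- switch(mode,
                unadjusted = cbind(1, g, h),
                adjusted   = cbind(1, g, x, h),
                generative = cbind(1, g, x, x^2))
    qr.coef(qr(Z), y)[2]
  }, numeric(1))
  rel <- (bh - beta) / beta
  est <- mean(rel)
  se <- stats::sd(rel) / sqrt(length(rel))
  structure(list(mode = mode, beta = beta, beta_hat = bh,
                 relative_bias = est, se = se, z = est / se),
            class = "dn_bias_est")
}

#' @export
print.dn_bias_est <- function(x, ...) {
  cat(sprintf(
    "%s estimator, beta = %g: relative bias %.4f (MC se %.4f, z = %.2f)\n",
    x$mode, x$beta, x$relative_bias, x$se, x$z))
  invisible(x)
}
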