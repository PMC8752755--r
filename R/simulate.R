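# Quantitative-trait simulator with explicit variance partitioning:
#   Y = G_std beta + sum_k f(X_.k) gamma_k + eps
# where beta_j ~ N(0, sigma_g2 / m_causal), gamma_k ~ N(0, sigma_x2 / q),
# eps ~ N(0, 1 - sigma_g2 - sigma_x2), so E(Y) = 0 and Var(Y) = 1 and the
# variance components are interpretable as phenotypic variance shares.

#' Simulate unlinked genotypes under Hardy-Weinberg equilibrium
#'
#' Per-variant minor-allele frequencies are drawn uniformly in \code{maf};
#' counts are binomial(2, p) independently per individual. With
#' \code{ld_blocks}, consecutive variants form blocks whose haplotypes share
#' a latent Gaussian factor (correlation \code{r} within block), giving
#' correlated allele counts for exercising LD-clumping code.
#'
#' @param n individuals (>= 2).
#' @param m variants.
#' @param maf length-2 allele-frequency range, 0 < low <= high <= 0.5.
#' @param chrom chromosome label for all m variants.
#' @param pos_start,pos_step 1-based bp positions pos_start + (0:(m-1)) * step.
#' @param seed integer seed.
#' @param ld_blocks optional list(size =, r =) for correlated blocks.
#' @return \code{\link{genotype_matrix}}.
#' @export
simulate_genotypes <- function(n, m, maf = c(0.01, 0.5), chrom = "1",
                               pos_start = 1e6, pos_step = 5000,
                               seed = NULL, ld_blocks = NULL) {
  if (n < 2) dn_stop("simulate_genotypes: need n >= 2")
  if (maf[1] <= 0 || maf[2] > 0.5 || maf[1] > maf[2])
    dn_stop("simulate_genotypes: maf range must satisfy 0 < low <= high <= 0.5")
  counts <- with_seed(seed, {
    p <- stats::runif(m, maf[1], maf[2])
    if (is.null(ld_blocks)) {
      matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    } else {
      size <- ld_blocks$size
      r <- ld_blocks$r
      block <- rep(seq_len(ceiling(m / size)), each = size)[seq_len(m)]
      cnt <- matrix(0L, n, m)
      for (hap in 1:2) {
        u <- matrix(stats::rnorm(n * max(block)), n)[, block, drop = FALSE]
        e <- matrix(stats::rnorm(n * m), n, m)
        z <- sqrt(r) * u + sqrt(1 - r) * e
        thr <- stats::qnorm(p)
        cnt <- cnt + (z < matrix(thr, n, m, byrow = TRUE))
      }
      cnt
    }
  })
  ids <- sprintf("chr%s:v%05d", chrom, seq_len(m))
  variants <- data.frame(chrom = chrom, id = ids,
                         pos = as.integer(pos_start + (seq_len(m) - 1) *
                                            pos_step),
                         a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  samples <- data.frame(fid = "0", iid = sprintf("I%06d", seq_len(n)),
                        stringsAsFactors = FALSE)
  genotype_matrix(counts, variants, samples)
}

#' Simulate the standard non-genetic covariates
#'
#' Produces an age-like continuous covariate (standard normal), a sex-like
#' binary covariate and a genotyping-array-like binary covariate (both
#' Bernoulli(0.5)), each empirically standardized to mean 0, variance 1
#' (population convention) so their variance share in the phenotype model is
#' exact.
#'
#' @param n individuals.
#' @param seed integer seed.
#' @return \code{\link{covariate_table}} with columns age, sex, array.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  raw <- with_seed(seed, cbind(age = stats::rnorm(n),
                               sex = stats::rbinom(n, 1, 0.5),
                               array = stats::rbinom(n, 1, 0.5)))
  st <- standardize_columns(raw)
  df <- data.frame(fid = "0", iid = sprintf("I%06d", seq_len(n)),
                   st$values, stringsAsFactors = FALSE)
  covariate_table(df, non_genetic = c("age", "sex", "array"))
}

#' Named scalar link functions for covariate effects
#'
#' Available links: identity, square, sin, exp, log_abs (|x| clamped at
#' 1e-12 before the log), sigmoid, and pairwise_product (binary: takes two
#' columns and returns their product).
#'
#' @param name link name.
#' @return a function of one argument (two for pairwise_product).
#' @export
link_function <- function(name) {
  switch(name,
         identity = function(x) x,
         square = function(x) x^2,
         sin = function(x) sin(x),
         exp = function(x) exp(x),
         log_abs = function(x) log(pmax(abs(x), 1e-12)),
         sigmoid = function(x) 1 / (1 + exp(-x)),
         pairwise_product = function(x1, x2) x1 * x2,
         dn_stop("link_function: unknown link '%s'", name))
}

#' Truth-term sets for the phenotype generator
#'
#' \code{setting = "linear"} uses the three raw covariates (age, sex, array);
#' \code{setting = "interactions"} uses the six terms age, sex, array, age^2,
#' age x sex, age x array. The named \code{link} is applied to every term
#' column before effect sizes are drawn (identity leaves them as stated).
#' Analysts are only ever shown the three raw covariates; the extra terms
#' exist solely in the generative truth.
#'
#' @param setting "linear" or "interactions".
#' @param link link name applied to each term (see
#'   \code{\link{link_function}}).
#' @return list of term specifications (cols, link).
#' @export
dn_truth_terms <- function(setting = c("linear", "interactions"),
                           link = "identity") {
  setting <- match.arg(setting)
  base <- list(list(cols = "age"), list(cols = "sex"), list(cols = "array"))
  if (setting == "interactions")
    base <- c(base, list(list(cols = c("age", "age")),
                         list(cols = c("age", "sex")),
                         list(cols = c("age", "array"))))
  lapply(base, function(t) { t$link <- link; t })
}

term_label <- function(term) {
  base <- paste(term$cols, collapse = "*")
  if (identical(term$link, "identity")) base else sprintf("%s(%s)", term$link, base)
}

#' Simulate a phenotype with explicit variance partitioning
#'
#' Assembles Y = G_std beta + sum_k f_k(T_k) gamma_k + eps on the standardized
#' causal genotypes, where T_k is a product of standardized covariate columns
#' and f_k the term's link. Each transformed term column is re-standardized
#' (population convention) before multiplying by gamma_k, so sigma_x2 keeps
#' its meaning as the covariate share of phenotypic variance for every link.
#' The returned truth record (effect sizes, realized components, term scale
#' factors) is sufficient to reconstruct Y exactly.
#'
#' @param geno \code{\link{genotype_matrix}} for the cohort.
#' @param covar \code{\link{covariate_table}} for the same individuals.
#' @param sigma_g2 genotype variance share, in [0, 1).
#' @param sigma_x2 covariate variance share, in [0, 1); sum must be < 1.
#' @param terms list of truth terms (see \code{\link{dn_truth_terms}}).
#' @param causal variant ids carrying effects (default: all variants on
#'   chromosome "22" if present, else all variants).
#' @param seed integer seed.
#' @return object of class \code{simulated_cohort}: genotypes, covariates,
#'   phenotype (named vector), truth record.
#' @export
simulate_phenotype <- function(geno, covar, sigma_g2, sigma_x2,
                               terms = dn_truth_terms("linear"),
                               causal = NULL, seed = NULL) {
  if (sigma_g2 < 0 || sigma_x2 < 0 || sigma_g2 + sigma_x2 >= 1)
    dn_stop("simulate_phenotype: need sigma_g2, sigma_x2 >= 0 and sigma_g2 + sigma_x2 < 1")
  keys <- dn_key(geno$samples$fid, geno$samples$iid)
  if (!identical(keys, dn_key(covar$fid, covar$iid)))
    dn_stop("simulate_phenotype: genotype and covariate samples differ")
  n <- length(keys)
  causal <- causal %||% {
    on22 <- geno$variants$id[geno$variants$chrom == "22"]
    if (length(on22)) on22 else geno$variants$id
  }
  if (sigma_g2 > 0 && !length(causal))
    dn_stop("simulate_phenotype: sigma_g2 > 0 needs at least one causal variant")
  m <- length(causal)
  q <- length(terms)

  gstd <- standardize_genotypes(geno[, causal])
  cv <- as.data.frame(covar)

  res <- with_seed(seed, {
    beta <- stats::rnorm(m, 0, sqrt(sigma_g2 / max(m, 1)))
    gamma <- stats::rnorm(q, 0, sqrt(sigma_x2 / max(q, 1)))
    eps <- stats::rnorm(n, 0, sqrt(1 - sigma_g2 - sigma_x2))
    list(beta = beta, gamma = gamma, eps = eps)
  })
  genetic <- if (sigma_g2 > 0) unname(drop(gstd$values %*% res$beta))
             else numeric(n)

  term_mat <- matrix(0, n, q)
  term_scale <- term_center <- numeric(q)
  for (k in seq_len(q)) {
    tk <- terms[[k]]
    raw <- Reduce(`*`, lapply(tk$cols, function(cl) {
      if (is.null(cv[[cl]])) dn_stop("simulate_phenotype: unknown covariate %s", cl)
      cv[[cl]]
    }))
    val <- link_function(tk$link)(raw)
    mu <- mean(val)
    sdev <- sqrt(mean(val^2) - mu^2)
    if (sdev < 1e-12) sdev <- 1
    term_center[k] <- mu
    term_scale[k] <- sdev
    term_mat[, k] <- (val - mu) / sdev
  }
  covariate <- if (sigma_x2 > 0 && q > 0) drop(term_mat %*% res$gamma)
               else numeric(n)
  y <- genetic + covariate + res$eps
  names(y) <- keys

  truth <- list(beta = stats::setNames(res$beta, causal),
                gamma = stats::setNames(res$gamma,
                                        vapply(terms, term_label, character(1))),
                causal = causal, terms = terms,
                sigma_g2 = sigma_g2, sigma_x2 = sigma_x2,
                term_center = term_center, term_scale = term_scale,
                components = list(genetic = genetic, covariate = covariate,
                                  noise = res$eps),
                covariate_signal = covariate, seed = seed)
  structure(list(genotypes = geno, covariates = covar, phenotype = y,
                 truth = truth),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "simulated_cohort: n = %d, m = %d (%d causal), sigma_g2 = %g, sigma_x2 = %g\n",
    length(x$phenotype), ncol(x$genotypes$counts), length(x$truth$causal),
    x$truth$sigma_g2, x$truth$sigma_x2))
  cat(sprintf("  truth terms: %s\n", paste(names(x$truth$gamma),
                                           collapse = ", ")))
  invisible(x)
}

#' Simulate a full cohort: causal and null chromosomes plus covariates
#'
#' Genotypes comprise a causal chromosome labelled "22" holding
#' \code{m_causal} variants (all causal) and two null chromosomes "1" and "2"
#' splitting \code{m_null} variants between them. Covariates are age, sex and
#' array (see \code{\link{simulate_covariates}}); the phenotype follows the
#' variance-partitioned model with the requested truth-term setting and link.
#'
#' @param n individuals.
#' @param m_causal causal variants on chromosome 22 (default 127).
#' @param m_null total null variants split over chromosomes 1 and 2
#'   (default 3000).
#' @param sigma_g2,sigma_x2 variance shares.
#' @param setting truth-term setting ("linear" or "interactions").
#' @param link link applied to each truth term.
#' @param maf allele-frequency range.
#' @param seed integer seed (drives genotypes, covariates and phenotype).
#' @param ld_blocks optional LD-block settings passed to the genotype
#'   simulator.
#' @return \code{simulated_cohort}.
#' @export
simulate_cohort <- function(n, m_causal = 127, m_null = 3000,
                            sigma_g2 = 0.2, sigma_x2 = 0.1,
                            setting = "linear", link = "identity",
                            maf = c(0.01, 0.5), seed = 1,
                            ld_blocks = NULL) {
  m1 <- m_null %/% 2
  m2 <- m_null - m1
  geno <- if (is.null(ld_blocks)) {
    # single-pass generation of all three chromosomes (equivalent in
    # distribution to three separate calls; avoids large intermediate copies)
    m <- m_causal + m_null
    counts <- with_seed(seed, {
      p <- stats::runif(m, maf[1], maf[2])
      matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    })
    chrom <- rep(c("22", "1", "2"), c(m_causal, m1, m2))
    within_chrom <- sequence(c(m_causal, m1, m2))
    genotype_matrix(
      counts,
      data.frame(chrom = chrom,
                 id = sprintf("chr%s:v%05d", chrom, within_chrom),
                 pos = as.integer(1e6 + (within_chrom - 1) * 5000),
                 a1 = "A", a2 = "B", stringsAsFactors = FALSE),
      data.frame(fid = "0", iid = sprintf("I%06d", seq_len(n)),
                 stringsAsFactors = FALSE))
  } else {
    bind_variants(list(
      simulate_genotypes(n, m_causal, maf, chrom = "22", seed = seed,
                         ld_blocks = ld_blocks),
      simulate_genotypes(n, m1, maf, chrom = "1", seed = seed + 1,
                         ld_blocks = ld_blocks),
      simulate_genotypes(n, m2, maf, chrom = "2", seed = seed + 2,
                         ld_blocks = ld_blocks)))
  }
  covar <- simulate_covariates(n, seed = seed + 3)
  simulate_phenotype(geno, covar, sigma_g2, sigma_x2,
                     terms = dn_truth_terms(setting, link),
                     causal = geno$variants$id[geno$variants$chrom == "22"],
                     seed = seed + 4)
}

#' Correlated genotype-covariate replicates for the bias demonstration
#'
#' Per replicate, a continuous "genotype" g and a covariate x are drawn
#' bivariate standard normal with correlation \code{rho}, and the phenotype is
#' y = g beta + x gamma1 + x^2 gamma2 + e with standard-normal noise. The
#' attached covariate model h is the per-replicate least-squares fit of y on
#' (1, x, x^2) — the oracle functional form trained to predict the phenotype,
#' as a covariate-prediction network would be. Because g and x are
#' correlated, the fitted h absorbs part of the genetic signal (its x
#' coefficient converges to gamma1 + rho * beta), which is exactly why the
#' "unadjusted" association model that omits the raw covariate is biased.
#'
#' @param n individuals per replicate.
#' @param rho correlation between g and x, |rho| <= 1.
#' @param gamma1,gamma2 covariate effect sizes.
#' @param beta genetic effect size.
#' @param replicates number of replicate datasets.
#' @param seed integer seed.
#' @return object of class \code{bias_demo_data}: n x replicates matrices
#'   \code{g}, \code{x}, \code{y}, \code{h} plus \code{params}.
#' @export
simulate_bias_demo <- function(n = 1000, rho = 0.5, gamma1 = 2, gamma2 = -1,
                               beta = 1, replicates = 1000, seed = 1) {
  if (abs(rho) > 1) dn_stop("simulate_bias_demo: |rho| must be <= 1")
  res <- with_seed(seed, {
    x <- matrix(stats::rnorm(n * replicates), n)
    z <- matrix(stats::rnorm(n * replicates), n)
    g <- rho * x + sqrt(1 - rho^2) * z
    e <- matrix(stats::rnorm(n * replicates), n)
    y <- g * beta + x * gamma1 + x^2 * gamma2 + e
    h <- vapply(seq_len(replicates), function(r) {
      D <- cbind(1, x[, r], x[, r]^2)
      drop(D %*% qr.coef(qr(D), y[, r]))
    }, numeric(n))
    list(g = g, x = x, y = y, h = h)
  })
  structure(c(res, list(params = list(n = n, rho = rho, gamma1 = gamma1,
                                      gamma2 = gamma2, beta = beta,
                                      replicates = replicates, seed = seed))),
            class = "bias_demo_data")
}

#' Write a simulated cohort to PLINK-dialect files
#'
#' Emits genotypes (bed/bim/fam), phenotype and covariate tables, and a
#' tab-separated truth sidecar (variant effect sizes and term effect sizes),
#' each stamped with the generating configuration.
#'
#' @param cohort \code{simulated_cohort}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the named list of paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, prefix)
  stamp <- list(sigma_g2 = cohort$truth$sigma_g2,
                sigma_x2 = cohort$truth$sigma_x2,
                seed = cohort$truth$seed %||% NA,
                terms = paste(names(cohort$truth$gamma), collapse = "+"))
  write_genotypes(cohort$genotypes, paste0(stem, ".bed"))
  pheno <- data.frame(fid = cohort$genotypes$samples$fid,
                      iid = cohort$genotypes$samples$iid,
                      pheno = as.numeric(cohort$phenotype))
  write_table(pheno, paste0(stem, ".pheno.txt"), stamp = stamp)
  write_table(as.data.frame(cohort$covariates), paste0(stem, ".covar.txt"),
              stamp = stamp)
  truth_path <- paste0(stem, ".truth.tsv")
  con <- file(truth_path, "w")
  writeLines(dn_stamp(stamp), con)
  utils::write.table(
    rbind(data.frame(kind = "variant", name = names(cohort$truth$beta),
                     effect = as.numeric(cohort$truth$beta)),
          data.frame(kind = "term", name = names(cohort$truth$gamma),
                     effect = as.numeric(cohort$truth$gamma))),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(list(bed = paste0(stem, ".bed"),
                 pheno = paste0(stem, ".pheno.txt"),
                 covar = paste0(stem, ".covar.txt"),
                 truth = truth_path))
}
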