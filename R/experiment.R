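# Reference experiment: simulate a cohort, cross-fit the covariate model,
# run Baseline and prediction-augmented association scans, and evaluate both.
# This is the recipe behind the simulation-study numbers and the CLI.

#' Run replicate simulation experiments comparing Baseline and augmented scans
#'
#' For each replicate: simulate a cohort (causal chromosome 22 plus null
#' chromosomes 1 and 2), cross-fit the covariate predictor on the three raw
#' covariates (age, sex, array) only, then scan every variant twice — the
#' Baseline scan adjusts linearly for the raw covariates; the augmented scan
#' adds the cross-fitted prediction as one extra covariate — and evaluate
#' power, type-I error and expected chi-square in the causal and null strata.
#'
#' @param replicates number of simulation replicates.
#' @param n individuals per replicate.
#' @param m_causal,m_null variant counts (defaults 127 causal, 3000 null).
#' @param sigma_g2,sigma_x2 variance shares of genotype and covariates.
#' @param setting truth-term setting ("linear" or "interactions").
#' @param link link applied to each truth term.
#' @param k cross-fitting partitions.
#' @param config training configuration (default \code{\link{dn_desk_config}}).
#' @param predictor optional \code{dn_predictor} overriding the MLP.
#' @param alpha significance threshold for power and type-I error.
#' @param seed integer seed; replicate r uses seed + 100 * (r - 1).
#' @return object of class \code{dn_experiment}: per-replicate
#'   \code{dn_eval}s for both methods, aggregated summaries, and the settings.
#' @export
run_experiment <- function(replicates = 25, n = 10000,
                           m_causal = 127, m_null = 3000,
                           sigma_g2 = 0.2, sigma_x2 = 0.1,
                           setting = "linear", link = "identity",
                           k = 5, config = dn_desk_config(),
                           predictor = NULL, alpha = 0.05, seed = 1) {
  evals <- list(baseline = vector("list", replicates),
                deepnull = vector("list", replicates))
  diffs <- data.frame(mean_abs_beta_diff_over_se = numeric(replicates))
  for (r in seq_len(replicates)) {
    rseed <- seed + 100L * (r - 1L)
    cohort <- simulate_cohort(n, m_causal, m_null, sigma_g2, sigma_x2,
                              setting, link, seed = rseed)
    gstd <- standardize_genotypes(cohort$genotypes)
    covar <- cohort$covariates
    df <- as.data.frame(covar)
    df$y <- as.numeric(cohort$phenotype)
    cfg <- config
    cfg$seed <- rseed + 7L
    fit <- deepnull(y ~ age + sex + array, df, k = k,
                    predictor = predictor,
                    config = cfg, seed = rseed + 11L)
    scan_base <- dn_scan(gstd, cohort$phenotype, covar,
                         columns = c("age", "sex", "array"))
    scan_dn <- dn_scan(gstd, cohort$phenotype, covar,
                       columns = c("age", "sex", "array"),
                       prediction = fit)
    evals$baseline[[r]] <- eval_scan(scan_base, cohort$truth$causal, alpha)
    evals$deepnull[[r]] <- eval_scan(scan_dn, cohort$truth$causal, alpha)
    nullv <- !scan_base$EXCLUDED & !scan_dn$EXCLUDED &
      !(scan_base$ID %in% cohort$truth$causal)
    diffs$mean_abs_beta_diff_over_se[r] <-
      mean(abs(scan_base$BETA[nullv] - scan_dn$BETA[nullv]) /
             scan_base$SE[nullv])
    rm(cohort, gstd, scan_base, scan_dn)
    gc(verbose = FALSE)
  }
  structure(list(evals = evals,
                 baseline = aggregate_evals(evals$baseline),
                 deepnull = aggregate_evals(evals$deepnull),
                 null_beta_shift = diffs,
                 settings = list(replicates = replicates, n = n,
                                 m_causal = m_causal, m_null = m_null,
                                 sigma_g2 = sigma_g2, sigma_x2 = sigma_x2,
                                 setting = setting, link = link, k = k,
                                 alpha = alpha, seed = seed)),
            class = "dn_experiment")
}

#' @export
print.dn_experiment <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "simulation experiment: %d replicates, n = %d, %s terms, link = %s\n",
    s$replicates, s$n, s$setting, s$link))
  cat(sprintf("  sigma_g2 = %g, sigma_x2 = %g, alpha = %g\n",
              s$sigma_g2, s$sigma_x2, s$alpha))
  cat("baseline:\n"); print(x$baseline, row.names = FALSE)
  cat("augmented (deepnull):\n"); print(x$deepnull, row.names = FALSE)
  imp <- experiment_improvement(x)
  cat(sprintf("relative improvement: power %+.2f%%, causal chi2 %+.2f%%\n",
              imp["power"], imp["chi2_causal"]))
  invisible(x)
}

#' Relative improvement of the augmented scan over Baseline
#'
#' @param exper \code{dn_experiment}.
#' @return named vector: percent relative improvement in power and in mean
#'   causal chi-square.
#' @export
experiment_improvement <- function(exper) {
  b <- exper$baseline; d <- exper$deepnull
  get <- function(tab, mt) tab$mean[tab$metric == mt]
  c(power = 100 * (get(d, "power") - get(b, "power")) / get(b, "power"),
    chi2_causal = 100 * (get(d, "expected_chi2_causal") -
                           get(b, "expected_chi2_causal")) /
      get(b, "expected_chi2_causal"))
}
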