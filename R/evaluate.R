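# Evaluation harness: power/type-I/expected chi-square summaries, greedy LD
# clumping into independent hits, locus merging, cross-scan overlap, phenotype
# prediction R^2, and polygenic scores.

#' Power, type-I error and expected chi-square for one scan
#'
#' Splits variants into the causal stratum (ids in \code{causal}) and the
#' null stratum, and reports the fraction significant at \code{alpha}
#' (power and type-I error respectively) and the mean chi-square of each
#' stratum, with within-scan standard errors. Excluded variants are dropped.
#' An empty stratum yields NA fields, never zero.
#'
#' @param results \code{dn_assoc} scan output.
#' @param causal character vector of causal variant ids (must be a subset of
#'   the scan's ids).
#' @param alpha significance threshold (default 0.05).
#' @return object of class \code{dn_eval}: power, type_I,
#'   expected_chi2_causal, expected_chi2_null, their SEs and stratum counts.
#' @export
eval_scan <- function(results, causal, alpha = 0.05) {
  if (!all(causal %in% results$ID))
    dn_stop("eval_scan: causal ids missing from results")
  res <- results[!results$EXCLUDED, , drop = FALSE]
  is_causal <- res$ID %in% causal
  strat <- function(sub) {
    if (!nrow(sub)) return(list(rate = NA_real_, rate_se = NA_real_,
                                chi2 = NA_real_, chi2_se = NA_real_, n = 0L))
    rate <- mean(sub$P <= alpha)
    list(rate = rate,
         rate_se = sqrt(rate * (1 - rate) / nrow(sub)),
         chi2 = mean(sub$CHISQ),
         chi2_se = stats::sd(sub$CHISQ) / sqrt(nrow(sub)),
         n = nrow(sub))
  }
  ca <- strat(res[is_causal, , drop = FALSE])
  nu <- strat(res[!is_causal, , drop = FALSE])
  structure(list(alpha = alpha,
                 power = ca$rate, power_se = ca$rate_se,
                 type_I = nu$rate, type_I_se = nu$rate_se,
                 expected_chi2_causal = ca$chi2,
                 expected_chi2_causal_se = ca$chi2_se,
                 expected_chi2_null = nu$chi2,
                 expected_chi2_null_se = nu$chi2_se,
                 n_causal = ca$n, n_null = nu$n),
            class = "dn_eval")
}

#' @export
print.dn_eval <- function(x, ...) {
  cat(sprintf("scan evaluation at alpha = %g\n", x$alpha))
  cat(sprintf("  power      = %s (%d causal variants)\n",
              format(x$power, digits = 4), x$n_causal))
  cat(sprintf("  type I     = %s (%d null variants)\n",
              format(x$type_I, digits = 4), x$n_null))
  cat(sprintf("  E[chi2] causal = %s, null = %s\n",
              format(x$expected_chi2_causal, digits = 4),
              format(x$expected_chi2_null, digits = 4)))
  invisible(x)
}

#' Aggregate per-replicate evaluations
#'
#' @param evals list of \code{dn_eval} objects (one per replicate).
#' @return data.frame with one row per metric: mean across replicates, the
#'   standard error of that mean, and the replicate count.
#' @export
aggregate_evals <- function(evals) {
  metrics <- c("power", "type_I", "expected_chi2_causal", "expected_chi2_null")
  do.call(rbind, lapply(metrics, function(mt) {
    v <- vapply(evals, function(e) e[[mt]], numeric(1))
    v <- v[!is.na(v)]
    data.frame(metric = mt, mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA,
               replicates = length(v))
  }))
}

panel_r2 <- function(panel_counts, j, idx) {
  x <- panel_counts[, j]
  suppressWarnings(stats::cor(x, panel_counts[, idx, drop = FALSE]))^2
}

#' Greedy LD clumping of significant variants into independent hits
#'
#' Repeatedly takes the remaining variant with the smallest p value (ties
#' broken by chromosome then position) among those with p <= \code{p_thresh}
#' as a lead, then removes every remaining significant variant whose squared
#' Pearson correlation of allele counts in \code{panel} is >=
#' \code{r2_thresh} with it. Each hit carries a span: the positional range of
#' panel variants on the lead's chromosome in LD with it at R^2 >=
#' \code{r2_thresh} (the lead itself included).
#'
#' @param results \code{dn_assoc} scan output.
#' @param panel \code{\link{genotype_matrix}} LD reference containing the
#'   scanned variants (for simulated data, the generating genotypes).
#' @param p_thresh significance threshold (default 5e-8).
#' @param r2_thresh LD independence threshold (default 0.1).
#' @return data.frame of class \code{dn_hits}: ID, CHR, POS, P, BETA,
#'   SPAN_START, SPAN_END. May have zero rows.
#' @export
clump <- function(results, panel, p_thresh = 5e-8, r2_thresh = 0.1) {
  cnt <- impute_mean(panel)
  sig <- results[!results$EXCLUDED & results$P <= p_thresh, , drop = FALSE]
  sig <- sig[order(sig$P, sig$CHR, sig$POS), , drop = FALSE]
  pidx <- match(sig$ID, panel$variants$id)
  if (anyNA(pidx)) dn_stop("clump: %d significant variants missing from panel",
                           sum(is.na(pidx)))
  hits <- list()
  remaining <- seq_len(nrow(sig))
  while (length(remaining)) {
    lead <- remaining[1]
    jlead <- pidx[lead]
    chrom <- sig$CHR[lead]
    same_chr <- panel$variants$chrom == chrom
    r2_panel <- suppressWarnings(
      stats::cor(cnt[, jlead], cnt[, same_chr, drop = FALSE]))^2
    r2_panel[is.na(r2_panel)] <- 0
    in_ld <- panel$variants$pos[same_chr][drop(r2_panel) >= r2_thresh]
    span <- if (length(in_ld)) range(in_ld) else rep(sig$POS[lead], 2)
    hits[[length(hits) + 1]] <- data.frame(
      ID = sig$ID[lead], CHR = chrom, POS = sig$POS[lead],
      P = sig$P[lead], BETA = sig$BETA[lead],
      SPAN_START = span[1], SPAN_END = span[2],
      stringsAsFactors = FALSE)
    others <- setdiff(remaining, lead)
    if (length(others)) {
      r2_others <- suppressWarnings(
        stats::cor(cnt[, jlead], cnt[, pidx[others], drop = FALSE]))^2
      r2_others[is.na(r2_others)] <- 0
      remaining <- others[drop(r2_others) < r2_thresh]
    } else remaining <- integer(0)
  }
  out <- if (length(hits)) do.call(rbind, hits)
         else data.frame(ID = character(0), CHR = character(0),
                         POS = integer(0), P = numeric(0), BETA = numeric(0),
                         SPAN_START = integer(0), SPAN_END = integer(0))
  class(out) <- c("dn_hits", "data.frame")
  out
}

#' Merge hits into loci by single-linkage within a window
#'
#' Hits on the same chromosome whose positions are within \code{window} bp
#' join one locus; chains merge transitively (single linkage), so a run of
#' hits each within the window of its neighbour forms a single locus. The
#' locus interval is the union of the member hit spans.
#'
#' @param hits \code{dn_hits} from \code{\link{clump}}.
#' @param window merge distance in bp (default 250000).
#' @return data.frame of class \code{dn_loci}: CHR, START, END, N_HITS,
#'   LEAD_ID, LEAD_P.
#' @export
merge_loci <- function(hits, window = 250000) {
  if (!nrow(hits))
    return(structure(data.frame(CHR = character(0), START = integer(0),
                                END = integer(0), N_HITS = integer(0),
                                LEAD_ID = character(0), LEAD_P = numeric(0)),
                     class = c("dn_loci", "data.frame")))
  hits <- hits[order(hits$CHR, hits$POS), , drop = FALSE]
  newlocus <- c(TRUE, diff(hits$POS) > window | hits$CHR[-1] !=
                  hits$CHR[-nrow(hits)])
  grp <- cumsum(newlocus)
  out <- do.call(rbind, lapply(split(hits, grp), function(h) {
    lead <- which.min(h$P)
    data.frame(CHR = h$CHR[1],
               START = min(h$SPAN_START %||% h$POS),
               END = max(h$SPAN_END %||% h$POS),
               N_HITS = nrow(h),
               LEAD_ID = h$ID[lead], LEAD_P = h$P[lead],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("dn_loci", "data.frame")
  out
}

#' Classify hits of one scan as shared with or unique to another
#'
#' A hit from scan A is shared if its span overlaps the span of any hit from
#' scan B on the same chromosome, otherwise unique.
#'
#' @param hits_a,hits_b \code{dn_hits} with spans attached.
#' @return \code{hits_a} with a logical \code{SHARED} column.
#' @export
compare_scans <- function(hits_a, hits_b) {
  for (h in list(hits_a, hits_b))
    if (nrow(h) && (anyNA(h$SPAN_START) || anyNA(h$SPAN_END)))
      dn_stop("compare_scans: hits are missing spans")
  shared <- vapply(seq_len(nrow(hits_a)), function(i) {
    b <- hits_b[hits_b$CHR == hits_a$CHR[i], , drop = FALSE]
    any(b$SPAN_START <= hits_a$SPAN_END[i] &
          b$SPAN_END >= hits_a$SPAN_START[i])
  }, logical(1))
  hits_a$SHARED <- shared
  hits_a
}

#' Squared Pearson correlation between observed and predicted phenotype
#'
#' R^2 here is the square of Pearson's correlation; the standard error comes
#' from a seeded nonparametric bootstrap over individuals. If either vector
#' has zero variance, R^2 is defined as 0 with a warning.
#'
#' @param y observed values.
#' @param yhat predicted values (same length, >= 3).
#' @param bootstrap_trials bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with \code{r2} and \code{se}.
#' @export
prediction_r2 <- function(y, yhat, bootstrap_trials = 1000, seed = 1) {
  if (length(y) != length(yhat) || length(y) < 3)
    dn_stop("prediction_r2: need equal lengths >= 3")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    warning("prediction_r2: zero variance; R^2 defined as 0")
    return(list(r2 = 0, se = NA_real_))
  }
  r2 <- stats::cor(y, yhat)^2
  boots <- with_seed(seed, vapply(seq_len(bootstrap_trials), function(b) {
    idx <- sample.int(length(y), replace = TRUE)
    if (stats::sd(y[idx]) == 0 || stats::sd(yhat[idx]) == 0) return(NA_real_)
    stats::cor(y[idx], yhat[idx])^2
  }, numeric(1)))
  list(r2 = r2, se = stats::sd(boots, na.rm = TRUE))
}

#' Clump-and-sum polygenic score
#'
#' score_i = sum over hits of (standardized genotype) x (estimated effect),
#' using the clumped independent hits and their scan effect sizes.
#'
#' @param geno \code{\link{standardized_genotypes}} containing the hit
#'   variants.
#' @param hits \code{dn_hits} with a BETA column.
#' @return numeric per-individual score named by sample key.
#' @export
prs_score <- function(geno, hits) {
  n <- nrow(geno$values)
  keys <- dn_key(geno$samples$fid, geno$samples$iid)
  if (!nrow(hits)) {
    warning("prs_score: empty hit list; scores are all zero")
    return(stats::setNames(numeric(n), keys))
  }
  idx <- match(hits$ID, geno$variants$id)
  if (anyNA(idx)) dn_stop("prs_score: %d hit variants missing from genotypes",
                          sum(is.na(idx)))
  stats::setNames(drop(geno$values[, idx, drop = FALSE] %*% hits$BETA), keys)
}

#' Write hits/loci as BED-like intervals
#' @param x \code{dn_hits} or \code{dn_loci}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_intervals <- function(x, path) {
  df <- if (inherits(x, "dn_hits"))
    data.frame(chrom = x$CHR, start = x$SPAN_START, end = x$SPAN_END,
               lead_id = x$ID, lead_p = x$P)
  else
    data.frame(chrom = x$CHR, start = x$START, end = x$END,
               lead_id = x$LEAD_ID, lead_p = x$LEAD_P)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
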