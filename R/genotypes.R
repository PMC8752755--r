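#' Genotype matrix container
#'
#' Holds an n individuals by m variants matrix of minor-allele counts together
#' with per-variant metadata and per-individual identifiers. Counts are stored
#' as integers in \{0, 1, 2\} with \code{NA} marking missing genotypes; the
#' count always refers to allele 1 (the minor allele by construction in the
#' simulators and fixtures shipped with the package).
#'
#' @param counts integer matrix (n x m) with entries in \{0, 1, 2\} or NA.
#' @param variants data.frame with columns \code{chrom}, \code{id},
#'   \code{pos} (1-based bp), \code{a1}, \code{a2}; one row per column of
#'   \code{counts}.
#' @param samples data.frame with columns \code{fid}, \code{iid}; one row per
#'   row of \code{counts}.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(counts, variants, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) != nrow(samples))
    dn_stop("genotype_matrix: %d count rows but %d samples",
            nrow(counts), nrow(samples))
  if (ncol(counts) != nrow(variants))
    dn_stop("genotype_matrix: %d count columns but %d variants",
            ncol(counts), nrow(variants))
  need <- c("chrom", "id", "pos", "a1", "a2")
  if (!all(need %in% names(variants)))
    dn_stop("genotype_matrix: variants must have columns %s",
            paste(need, collapse = ", "))
  if (length(counts)) {
    rng <- suppressWarnings(range(counts, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))
      dn_stop("genotype_matrix: counts outside {0,1,2}")
  }
  if (any(variants$pos < 0))
    dn_stop("genotype_matrix: negative variant position")
  dup <- duplicated(paste(variants$chrom, variants$id))
  if (any(dup))
    dn_stop("genotype_matrix: duplicated variant id within chromosome: %s",
            paste(unique(variants$id[dup]), collapse = ", "))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$chrom <- as.character(variants$chrom)
  variants$id <- as.character(variants$id)
  variants$pos <- as.integer(variants$pos)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$fid <- as.character(samples$fid)
  samples$iid <- as.character(samples$iid)
  rownames(counts) <- dn_key(samples$fid, samples$iid)
  colnames(counts) <- variants$id
  structure(list(counts = counts, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  nmiss <- sum(is.na(x$counts))
  if (nmiss) cat(sprintf("  missing genotypes: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by individuals and/or variants
#' @param x genotype_matrix.
#' @param i row (individual) index.
#' @param j column (variant) index or variant ids.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(j)) j <- match(j, x$variants$id)
  genotype_matrix(x$counts[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  x$samples[i, , drop = FALSE])
}

#' Column-bind genotype matrices over the same individuals
#' @param gm_list list of genotype_matrix objects with identical samples.
#' @return combined genotype_matrix.
#' @export
bind_variants <- function(gm_list) {
  keys <- lapply(gm_list, function(g) dn_key(g$samples$fid, g$samples$iid))
  if (!all(vapply(keys, identical, logical(1), y = keys[[1]])))
    dn_stop("bind_variants: sample sets differ")
  genotype_matrix(do.call(cbind, lapply(gm_list, `[[`, "counts")),
                  do.call(rbind, lapply(gm_list, `[[`, "variants")),
                  gm_list[[1]]$samples)
}

#' Impute missing genotype counts to the per-variant mean
#'
#' Returns a numeric matrix where each missing entry is replaced by the mean
#' count of the non-missing entries of its variant (standard GWAS convention
#' before standardization). Variants that are entirely missing become all-zero
#' columns and are excluded downstream by \code{\link{standardize_genotypes}}.
#'
#' @param geno genotype_matrix.
#' @return numeric n x m matrix.
#' @export
impute_mean <- function(geno) {
  g <- geno$counts
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    miss <- is.na(g)
    mu <- colMeans(g, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(miss, arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  g
}

#' Standardize genotype columns to mean zero and unit variance
#'
#' Missing genotypes are mean-imputed, then each column is centred and scaled
#' using the population convention (divisor n), so that the empirical mean of
#' each retained column is 0 and the empirical variance is exactly 1.
#' Zero-variance (monomorphic) variants are flagged as excluded and their
#' columns set to zero rather than silently kept.
#'
#' @param geno genotype_matrix.
#' @return object of class \code{standardized_genotypes}: list with
#'   \code{values} (numeric matrix), \code{center}, \code{scale},
#'   \code{excluded} (logical per variant), \code{variants}, \code{samples}.
#' @export
standardize_genotypes <- function(geno) {
  g <- impute_mean(geno)              # fresh matrix: safe to transform in place
  st <- standardize_columns_owned(g, allow_all_excluded = TRUE)
  structure(list(values = st$values, center = st$center, scale = st$scale,
                 excluded = st$excluded, variants = geno$variants,
                 samples = geno$samples),
            class = "standardized_genotypes")
}

#' @export
print.standardized_genotypes <- function(x, ...) {
  cat(sprintf("standardized_genotypes: %d x %d (%d excluded zero-variance)\n",
              nrow(x$values), ncol(x$values), sum(x$excluded)))
  invisible(x)
}
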