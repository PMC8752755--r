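#' Standardize matrix columns to mean zero, variance one
#'
#' Centres and scales each column using the population variance convention
#' (divisor n, not n - 1), so each retained column has empirical mean 0 and
#' empirical variance 1. Columns with zero variance are reported in
#' \code{excluded} and returned as all-zero columns; they are never silently
#' passed through.
#'
#' @param M numeric matrix with at least 2 rows and no missing values.
#' @param allow_all_excluded if FALSE (default), an error is raised when every
#'   column has zero variance.
#' @return list with \code{values} (matrix), \code{center}, \code{scale}
#'   (per-column mean and population sd), \code{excluded} (logical vector).
#' @export
standardize_columns <- function(M, allow_all_excluded = FALSE) {
  M <- as.matrix(M)
  if (is.integer(M)) storage.mode(M) <- "double" else M <- M + 0  # own a copy
  standardize_columns_owned(M, allow_all_excluded)
}

# in-place variant for matrices the caller owns (avoids duplicating large
# genotype matrices); M must be a freshly allocated double matrix
standardize_columns_owned <- function(M, allow_all_excluded = FALSE) {
  n <- nrow(M)
  if (n < 2) dn_stop("standardize_columns: need >= 2 rows")
  if (anyNA(M)) dn_stop("standardize_columns: missing values; impute first")
  st <- .standardize_cols_inplace(M)
  excluded <- as.logical(st$excluded)
  if (all(excluded) && !allow_all_excluded)
    dn_stop("standardize_columns: no usable columns (all zero variance)")
  center <- as.numeric(st$center)
  scale <- as.numeric(st$scale)
  names(center) <- names(scale) <- names(excluded) <- colnames(M)
  list(values = M, center = center, scale = scale, excluded = excluded)
}

#' Apply a stored standardization to new rows
#'
#' Uses the centre/scale fitted on one row set (e.g. training folds) to
#' transform a disjoint row set, never recomputing statistics from the new
#' rows. Excluded columns map to zero.
#'
#' @param M numeric matrix with the same columns as the fitted matrix.
#' @param state list with \code{center}, \code{scale}, \code{excluded} as
#'   returned by \code{\link{standardize_columns}}.
#' @return transformed matrix.
#' @export
apply_standardization <- function(M, state) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (ncol(M) != length(state$center))
    dn_stop("apply_standardization: %d columns but state has %d",
            ncol(M), length(state$center))
  values <- sweep(M, 2, state$center, "-")
  values <- sweep(values, 2, state$scale, "/")
  values[, state$excluded] <- 0
  values
}
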