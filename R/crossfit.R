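# k-partition cross-fitting: every individual receives exactly one
# out-of-sample prediction, from a model that neither trained nor validated
# on them.

#' Assign individuals to k balanced folds
#'
#' A seeded uniform random permutation of the sample keys is cut into k
#' contiguous blocks whose sizes differ by at most one. Fold indices run
#' 0..k-1. The permutation is drawn over the lexicographically sorted keys,
#' so the key-to-fold map depends only on the key set and seed, never on the
#' order samples were supplied. k must be at least 3: the scheme needs one
#' prediction partition, one validation partition, and at least one training
#' partition.
#'
#' @param keys character vector of unique sample keys.
#' @param k number of folds (>= 3, <= number of samples).
#' @param seed integer seed.
#' @return object of class \code{fold_assignment}: data.frame (key, fold)
#'   plus attributes k, seed.
#' @export
assign_folds <- function(keys, k, seed = 1) {
  n <- length(keys)
  if (anyDuplicated(keys)) dn_stop("assign_folds: duplicated sample keys")
  if (k < 3) dn_stop("assign_folds: k must be >= 3, got %d", k)
  if (k > n) dn_stop("assign_folds: k = %d exceeds n = %d", k, n)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_sorted <- integer(n)
  fold_sorted[perm] <- rep.int(0:(k - 1L), times = sizes)
  fold <- fold_sorted[match(keys, sort(keys))]
  structure(data.frame(key = keys, fold = fold, stringsAsFactors = FALSE),
            k = as.integer(k), seed = seed,
            class = c("fold_assignment", "data.frame"))
}

#' Cross-fitted out-of-sample predictions
#'
#' For each fold f, the validation/model-selection partition is fold
#' (f + 1) mod k and the training partitions are the remaining k - 2 folds;
#' the model with the best validation score then predicts all individuals in
#' fold f. Each partition is used as the validation partition exactly once,
#' and every individual receives exactly one prediction, from a model whose
#' training and validation sets excluded them. Both properties are asserted
#' at run time.
#'
#' @param X n x q covariate matrix (non-genetic covariates only; rows keyed
#'   by \code{folds$key} order).
#' @param y length-n phenotype vector.
#' @param folds \code{\link{fold_assignment}} for the same n individuals.
#' @param predictor a \code{dn_predictor} (default: the residual MLP).
#' @return list with \code{prediction} (length-n vector named by key) and
#'   \code{fold_fits} (per-fold fitted models and metadata).
#' @export
crossfit_predict <- function(X, y, folds,
                             predictor = mlp_predictor()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n || nrow(folds) != n)
    dn_stop("crossfit_predict: X, y and folds sizes disagree")
  k <- attr(folds, "k")
  fold <- folds$fold
  pred <- rep(NA_real_, n)
  filled <- integer(n)
  val_used <- integer(0)
  fold_fits <- vector("list", k)
  for (f in 0:(k - 1L)) {
    val_f <- (f + 1L) %% k
    pred_idx <- which(fold == f)
    val_idx <- which(fold == val_f)
    train_idx <- which(fold != f & fold != val_f)
    if (length(intersect(pred_idx, c(val_idx, train_idx))) ||
        length(intersect(val_idx, train_idx)))
      dn_stop("crossfit_predict: fold partitions overlap")   # unreachable guard
    model <- predictor$fit(X[train_idx, , drop = FALSE], y[train_idx],
                           X[val_idx, , drop = FALSE], y[val_idx])
    pred[pred_idx] <- predictor$predict(model, X[pred_idx, , drop = FALSE])
    filled[pred_idx] <- filled[pred_idx] + 1L
    val_used <- c(val_used, val_f)
    fold_fits[[f + 1L]] <- list(fold = f, validation_fold = val_f,
                                n_train = length(train_idx),
                                model = model)
  }
  if (!all(filled == 1L))
    dn_stop("crossfit_predict: %d individuals not predicted exactly once",
            sum(filled != 1L))
  if (!identical(sort(val_used), 0:(k - 1L)))
    dn_stop("crossfit_predict: validation folds did not rotate over 0..k-1")
  names(pred) <- folds$key
  list(prediction = pred, fold_fits = fold_fits)
}
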