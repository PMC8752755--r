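#' Fit a cross-fitted non-linear covariate model for a quantitative phenotype
#'
#' Learns the phenotype-covariate relationship with a residual-style MLP (a
#' 4-hidden-layer ReLU network in parallel with a direct linear path) and
#' produces one strictly out-of-sample prediction per individual via a
#' k-partition cross-fitting scheme: for each partition, a model is trained on
#' k - 2 partitions, selected on one held-out validation partition, and used
#' to predict the remaining partition. The resulting prediction column is
#' intended to be added to the linear covariate set of a per-variant
#' association scan (see \code{\link{dn_scan}}); the raw covariates must stay
#' in that scan as well, since the prediction captures covariate-phenotype but
#' not covariate-genotype association.
#'
#' Only non-genetic covariates (age, sex, batch, ...) may appear on the
#' right-hand side of the formula; genetic principal components belong in the
#' association adjustment set, not here.
#'
#' @param formula model formula, phenotype ~ covariates (no transformations
#'   needed; the network learns them).
#' @param data data.frame (e.g. a \code{\link{covariate_table}} joined with
#'   the phenotype); if it carries \code{fid}/\code{iid} columns they are used
#'   as sample keys.
#' @param k number of cross-fitting partitions (default 5).
#' @param predictor a \code{dn_predictor} adapter; default the residual MLP
#'   with \code{config}.
#' @param config \code{\link{dn_training_config}} used when \code{predictor}
#'   is not supplied.
#' @param seed integer seed controlling fold assignment and training.
#' @return object of class \code{deepnull} with components \code{prediction}
#'   (cross-fitted, named by sample key), \code{folds}, \code{fold_fits},
#'   \code{y}, \code{covariate_names}, \code{call}.
#' @examples
#' set.seed(1)
#' d <- data.frame(age = rnorm(600), sex = rbinom(600, 1, 0.5))
#' d$y <- d$age^2 + 0.5 * d$sex + rnorm(600, sd = 0.3)
#' fit <- deepnull(y ~ age + sex, d, k = 5,
#'                 config = dn_desk_config(epochs = 60, batch_size = 128),
#'                 seed = 7)
#' summary(fit)
#' @export
deepnull <- function(formula, data, k = 5,
                     predictor = NULL,
                     config = dn_training_config(),
                     seed = 1) {
  cl <- match.call()
  mf <- stats::model.frame(formula, as.data.frame(data), na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (any(grepl("^PC[0-9]+$", colnames(X))))
    dn_stop("deepnull: PC-like columns are genetic and cannot be predictors")
  keys <- if (all(c("fid", "iid") %in% names(data)))
    dn_key(data$fid, data$iid) else as.character(seq_len(nrow(X)))
  if (!is.numeric(y) || anyNA(y)) dn_stop("deepnull: phenotype must be numeric and complete")
  if (is.null(predictor)) {
    if (is.null(config$seed))
      config$seed <- seed + 1L
    predictor <- mlp_predictor(config)
  }
  folds <- assign_folds(keys, k, seed = seed)
  cf <- crossfit_predict(X, y, folds, predictor)
  structure(list(call = cl, formula = formula, k = as.integer(k),
                 seed = seed, predictor_label = predictor$label,
                 covariate_names = colnames(X),
                 folds = folds, fold_fits = cf$fold_fits,
                 prediction = cf$prediction,
                 y = stats::setNames(as.numeric(y), keys)),
            class = "deepnull")
}

#' @export
print.deepnull <- function(x, ...) {
  cat("Cross-fitted covariate model (", x$predictor_label, " predictor)\n",
      sep = "")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  n = %d individuals, k = %d partitions, covariates: %s\n",
              length(x$y), x$k, paste(x$covariate_names, collapse = ", ")))
  r2 <- stats::cor(x$y, x$prediction)^2
  cat(sprintf("  out-of-sample prediction R^2 = %.4f\n", r2))
  invisible(x)
}

#' @export
summary.deepnull <- function(object, ...) {
  per_fold <- do.call(rbind, lapply(object$fold_fits, function(ff) {
    data.frame(fold = ff$fold, validation_fold = ff$validation_fold,
               n_train = ff$n_train,
               best_val_mse = ff$model$best_val_mse %||% NA_real_,
               best_epoch = ff$model$best_epoch %||% NA_integer_)
  }))
  out <- list(call = object$call,
              n = length(object$y), k = object$k,
              predictor = object$predictor_label,
              covariates = object$covariate_names,
              r2 = stats::cor(object$y, object$prediction)^2,
              mse = mean((object$y - object$prediction)^2),
              per_fold = per_fold)
  class(out) <- "summary.deepnull"
  out
}

#' @export
print.summary.deepnull <- function(x, ...) {
  cat("Cross-fitted covariate model (", x$predictor, " predictor)\n", sep = "")
  cat(sprintf("  n = %d, k = %d, covariates: %s\n", x$n, x$k,
              paste(x$covariates, collapse = ", ")))
  cat(sprintf("  out-of-sample R^2 = %.4f, MSE = %.4f\n", x$r2, x$mse))
  cat("  per-fold fits:\n")
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.deepnull <- function(object, ...) object$prediction

#' @export
residuals.deepnull <- function(object, ...) object$y - object$prediction

#' Predict phenotype from covariates for new individuals
#'
#' For individuals seen at fit time the stored cross-fitted (out-of-sample)
#' prediction is the right quantity and is what \code{fitted()} returns. For
#' genuinely new rows no fold owns them, so the k per-fold models are averaged.
#'
#' @param object \code{deepnull} fit.
#' @param newdata data.frame containing the fitted covariate columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.deepnull <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$prediction)
  X <- as.matrix(as.data.frame(newdata)[, object$covariate_names, drop = FALSE])
  preds <- lapply(object$fold_fits, function(ff) {
    if (inherits(ff$model, "dn_mlp")) predict(ff$model, X)
    else dn_stop("predict.deepnull: new-data prediction requires the MLP predictor")
  })
  Reduce(`+`, preds) / length(preds)
}

#' Linear skip-path coefficients
#'
#' Returns the weights of the direct linear path from covariates to phenotype
#' (on the standardized-input scale), averaged across the k per-fold models.
#' These summarize the linear component the network attributes to each
#' covariate; the MLP path holds the remainder.
#'
#' @param object \code{deepnull} fit with the MLP predictor.
#' @param ... unused.
#' @return named numeric vector (intercept plus one weight per covariate).
#' @export
coef.deepnull <- function(object, ...) {
  ws <- lapply(object$fold_fits, function(ff) {
    if (!inherits(ff$model, "dn_mlp")) return(NULL)
    c(ff$model$params$b6, drop(ff$model$params$W6))
  })
  ws <- Filter(Negate(is.null), ws)
  if (!length(ws)) return(NULL)
  out <- Reduce(`+`, ws) / length(ws)
  stats::setNames(out, c("(Intercept)", object$covariate_names))
}

#' Plot observed phenotype against cross-fitted prediction
#' @param x \code{deepnull} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.deepnull <- function(x, ...) {
  graphics::plot(x$prediction, x$y,
                 xlab = "cross-fitted prediction", ylab = "phenotype",
                 main = sprintf("out-of-sample R^2 = %.3f",
                                stats::cor(x$y, x$prediction)^2), ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Append the cross-fitted prediction to a covariate table
#'
#' Joins on (fid, iid) and adds a \code{deepnull_pred} column, yielding a
#' covariate file consumable by external association tools.
#'
#' @param covar \code{\link{covariate_table}}.
#' @param fit \code{deepnull} object (or a named prediction vector).
#' @param column name for the new column.
#' @return covariate_table with the prediction column appended to the
#'   adjustment set.
#' @export
augment_covariates <- function(covar, fit, column = "deepnull_pred") {
  pred <- if (inherits(fit, "deepnull")) fit$prediction else fit
  key <- dn_key(covar$fid, covar$iid)
  idx <- match(key, names(pred))
  if (anyNA(idx))
    dn_stop("augment_covariates: %d covariate rows have no prediction",
            sum(is.na(idx)))
  df <- as.data.frame(covar)
  df[[column]] <- as.numeric(pred[idx])
  covariate_table(df,
                  non_genetic = attr(covar, "non_genetic"),
                  adjustment = c(attr(covar, "adjustment"), column))
}
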