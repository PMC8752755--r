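# Pluggable predictor contract: any list of class "dn_predictor" with
#   $fit(X, y, X_val, y_val) -> fitted model object
#   $predict(model, X)       -> numeric predictions
# may stand in for the network (spline or gradient-boosted-tree baselines can
# be wrapped the same way).

#' Predictor adapters for cross-fitting
#'
#' \code{mlp_predictor} wraps the residual MLP (\code{\link{mlp_train}});
#' \code{linear_predictor} wraps ordinary least squares on the raw covariates
#' (the linear baseline); \code{mean_predictor} memorizes the training-set
#' mean (a stub useful for leakage diagnostics).
#'
#' @param config \code{\link{dn_training_config}} for the MLP.
#' @return list of class \code{dn_predictor} with \code{fit} and
#'   \code{predict} functions and a \code{label}.
#' @export
mlp_predictor <- function(config = dn_training_config()) {
  structure(list(
    label = "mlp",
    config = config,
    fit = function(X, y, X_val, y_val) mlp_train(X, y, X_val, y_val, config),
    predict = function(model, X) predict(model, X)
  ), class = "dn_predictor")
}

#' @rdname mlp_predictor
#' @export
linear_predictor <- function() {
  structure(list(
    label = "linear",
    fit = function(X, y, X_val, y_val) {
      Xd <- cbind(1, as.matrix(X))
      list(coef = qr.coef(qr(Xd), y))
    },
    predict = function(model, X) {
      co <- model$coef
      co[is.na(co)] <- 0
      drop(cbind(1, as.matrix(X)) %*% co)
    }
  ), class = "dn_predictor")
}

#' @rdname mlp_predictor
#' @export
mean_predictor <- function() {
  structure(list(
    label = "mean",
    fit = function(X, y, X_val, y_val) list(mu = mean(y)),
    predict = function(model, X) rep(model$mu, nrow(as.matrix(X)))
  ), class = "dn_predictor")
}
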