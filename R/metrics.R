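#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` of predictions against observed values (the quantity
#' reported as R2c on the calibration set and R2p on the prediction set).
#'
#' @param y_true observed values (length >= 2, non-constant).
#' @param y_pred predicted values.
#' @return numeric; 1 for perfect prediction, 0 for predicting the mean, and
#'   negative when worse than the mean.
#' @export
r_squared <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("y_true is constant; R^2 undefined")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Root-mean-square error
#'
#' @param y_true observed values (vector or matrix; matrices are compared
#'   elementwise, pooling all entries).
#' @param y_pred predictions, same shape.
#' @return non-negative numeric (RMSEC / RMSEP depending on the set).
#' @export
rmse <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0L) stop("empty vectors")
  sqrt(mean((y_true - y_pred)^2))
}

#' Pseudounivariate limit of detection
#'
#' The original study reports an LOD per model without defining it; this
#' package adopts the pseudounivariate convention for multivariate
#' calibration: regress predictions on observed concentrations and return
#' `factor * s_res / |b1|`, where `b1` is the slope and `s_res` the residual
#' standard deviation of that least-squares line. `factor = 3.3` (the common
#' "3.3 sigma" detection criterion) by default; `3` is the other convention.
#'
#' @param y_true observed concentrations (length >= 3, non-constant).
#' @param y_pred predicted concentrations.
#' @param factor detection multiplier (default 3.3).
#' @return positive numeric in concentration units (0 for an exact fit).
#' @export
lod <- function(y_true, y_pred, factor = 3.3) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3L)
  fit <- stats::lm(y_pred ~ y_true)
  b1 <- stats::coef(fit)[["y_true"]]
  if (!is.finite(b1) || abs(b1) < .Machine$double.eps^0.5)
    stop("zero slope of predictions on observations; LOD undefined")
  s_res <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  factor * s_res / abs(b1)
}

#' Calibration/prediction metrics table for a fitted regressor
#'
#' Computes R2c/RMSEC on the calibration set, R2p/RMSEP on the prediction
#' set and the LOD (on the prediction set), per target property — the layout
#' of a standard chemometrics results table.
#'
#' @param model a fitted regressor: a regressor `fitted_stack`, a
#'   `nirstack_model`, a `ridge_multioutput` or a `pls_model`.
#' @param cal,pred `spectra_dataset`s carrying the features the model was
#'   fitted on (already masked/standardized as at fit time).
#' @param targets character vector of metadata target columns, in the order
#'   the model's outputs were trained (default `c("nitrogen",
#'   "organic_matter")`).
#' @return data.frame with columns `property, R2c, RMSEC, R2p, RMSEP, LOD`,
#'   one row per target.
#' @export
evaluate_model <- function(model, cal, pred,
                           targets = c("nitrogen", "organic_matter")) {
  pc <- predict_regressor(model, cal$reflectance)
  pp <- predict_regressor(model, pred$reflectance)
  if (ncol(pc) != length(targets))
    stop("model predicts ", ncol(pc), " target(s) but ", length(targets),
         " target names were given")
  rows <- lapply(seq_along(targets), function(j) {
    yc <- cal$meta[[targets[j]]]; yp <- pred$meta[[targets[j]]]
    data.frame(property = targets[j],
               R2c = r_squared(yc, pc[, j]), RMSEC = rmse(yc, pc[, j]),
               R2p = r_squared(yp, pp[, j]), RMSEP = rmse(yp, pp[, j]),
               LOD = lod(yp, pp[, j]))
  })
  do.call(rbind, rows)
}

# Uniform prediction interface over the package's regressor objects.
predict_regressor <- function(model, X) {
  X <- as.matrix(X)
  p <- if (inherits(model, "fitted_stack")) {
    predict_stack(model, X)
  } else if (inherits(model, "nirstack_model")) {
    predict_base_model(model, X)
  } else if (inherits(model, "ridge_multioutput") ||
             inherits(model, "pls_model")) {
    predict(model, X)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  as.matrix(p)
}
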