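#' Multi-output ridge regression (closed form)
#'
#' Ridge least squares with a shared penalty across outputs, the simple
#' multi-output model used throughout the study to predict nitrogen and
#' organic matter simultaneously. Solves the normal equations
#' `(Xc'Xc + lambda I) B = Xc'Yc` on column-centered data; the intercept is
#' recovered from the means, so predictions are on the original target scale.
#'
#' @param X numeric feature matrix.
#' @param Y numeric target matrix `n x t` (a vector is one target).
#' @param strength non-negative penalty `lambda` (default 0.1, the tuned
#'   value of the study).
#' @return an object of class `ridge_multioutput` with a `predict` method.
#' @export
fit_ridge_multioutput <- function(X, Y, strength = 0.1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (strength < 0) stop("strength must be >= 0")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx)
  B <- solve(crossprod(Xc) + strength * diag(ncol(X)),
             crossprod(Xc, sweep(Y, 2L, my)))
  structure(list(B = B, mx = mx, my = my, strength = strength),
            class = "ridge_multioutput")
}

#' @export
predict.ridge_multioutput <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(sweep(newdata, 2L, object$mx) %*% object$B, 2L, object$my, "+")
}

#' Partial least squares regression
#'
#' PLS with a chosen number of latent variables (the `Lv` of chemometrics
#' results tables), backed by [mixOmics::pls()] in regression mode on
#' standardized predictors and centered responses; predictions are returned
#' on the original target scale.
#'
#' @param X numeric feature matrix.
#' @param Y numeric target matrix or vector.
#' @param n_latent number of latent variables, `1 <= n_latent <=
#'   min(nrow(X) - 1, ncol(X))`.
#' @return an object of class `pls_model` with a `predict` method.
#' @export
fit_pls <- function(X, Y, n_latent) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n_latent <- as.integer(n_latent)
  if (n_latent < 1L || n_latent > min(nrow(X) - 1L, ncol(X)))
    stop("n_latent must be in [1, ", min(nrow(X) - 1L, ncol(X)), "]")
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  fit <- mixOmics::pls(X, Y, ncomp = n_latent, mode = "regression",
                       scale = TRUE)
  structure(list(fit = fit, n_latent = n_latent, n_targets = ncol(Y)),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- paste0("x", seq_len(ncol(newdata)))
  pr <- predict(object$fit, newdata)$predict
  matrix(pr[, , object$n_latent], nrow = nrow(newdata),
         ncol = object$n_targets)
}
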