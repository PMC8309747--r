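#' Stacked-generalization specification
#'
#' Describes a Wolpert stack: an ordered list of base learners whose
#' out-of-fold predictions become the features of a meta learner. Both the
#' classification stack (used as the PSO fitness model) and the regression
#' stack (the final calibration model) are instances of this one structure.
#'
#' @param base list of `model_spec` objects (>= 2), all of the stack's task.
#' @param meta a single `model_spec` for the final estimator. Defaults:
#'   L2-penalized logistic regression for classifier stacks, ridge for
#'   regressor stacks.
#' @param internal_folds folds used to produce the out-of-fold meta-features
#'   (default 5).
#' @param task `"classifier"` or `"regressor"`.
#' @return an object of class `stack_spec`.
#' @export
stack_spec <- function(base, meta = NULL, internal_folds = 5L,
                       task = c("classifier", "regressor")) {
  task <- match.arg(task)
  if (length(base) < 2L) stop("a stack needs at least 2 base members")
  for (b in base) {
    stopifnot(inherits(b, "model_spec"))
    if (b$task != task)
      stop("base member '", b$family, "' is a ", b$task,
           " but the stack task is ", task)
  }
  defs <- default_model_specs()
  if (is.null(meta))
    meta <- if (task == "classifier") defs$logistic else defs$ridge_reg
  if (meta$task != task) stop("meta learner task must be ", task)
  structure(list(base = base, meta = meta,
                 internal_folds = as.integer(internal_folds), task = task),
            class = "stack_spec")
}

#' Build the classification stack (FSGC)
#'
#' The first stacked generalization: a variety classifier whose
#' cross-validated accuracy drives the PSO wavelength-selection fitness.
#' Default members are the four families that survived the accuracy/time
#' screen — SVM, KNN, logistic regression and ridge classifier — with an
#' L2-penalized logistic meta learner.
#'
#' @param members list of classifier `model_spec`s (default the four above).
#' @param internal_folds out-of-fold folds (default 5).
#' @return a classifier `stack_spec`.
#' @export
build_fsgc <- function(members = NULL, internal_folds = 5L) {
  defs <- default_model_specs()
  if (is.null(members))
    members <- defs[c("svm", "knn", "logistic", "ridge")]
  stack_spec(members, internal_folds = internal_folds, task = "classifier")
}

#' Build the regression stack (SSGR)
#'
#' The second stacked generalization: predicts nitrogen and organic matter
#' (jointly) from the selected wavelengths. Members mirror the classification
#' stack except that logistic regression — defined only for categorical
#' outcomes — is replaced by an MLP, giving SVR, KNN regressor, MLP regressor
#' and ridge, with a ridge meta learner.
#'
#' @param members list of regressor `model_spec`s (default the four above).
#' @param internal_folds out-of-fold folds (default 5).
#' @return a regressor `stack_spec`.
#' @export
build_ssgr <- function(members = NULL, internal_folds = 5L) {
  defs <- default_model_specs()
  if (is.null(members))
    members <- defs[c("svr", "knn_reg", "mlp_reg", "ridge_reg")]
  stack_spec(members, internal_folds = internal_folds, task = "regressor")
}

#' Fit a stacked generalization
#'
#' Wolpert stacking: each base learner is fit `internal_folds` times on
#' internal training folds to produce out-of-fold predictions for every
#' training row; the meta learner is trained on those out-of-fold
#' meta-features (class-probability/score columns per base for classifiers,
#' one column per target per base for regressors); finally each base learner
#' is refit on all rows for use at prediction time. No row's meta-feature is
#' ever produced by a base model that saw that row.
#'
#' @param spec a `stack_spec`.
#' @param X numeric feature matrix.
#' @param y factor/labels (classifier) or numeric vector/matrix of targets
#'   (regressor; both study properties may be passed as a 2-column matrix).
#' @param seed integer seed controlling fold assignment and learner RNG.
#' @return an object of class `fitted_stack`.
#' @export
fit_stack <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "stack_spec"))
  X <- as.matrix(X)
  k <- spec$internal_folds
  if (nrow(X) < k) stop("need at least internal_folds (", k, ") rows")
  is_cls <- spec$task == "classifier"
  if (is_cls) {
    y <- as.factor(y)
    if (min(table(y)) < k)
      stop("class '", names(which.min(table(y))), "' has fewer rows (",
           min(table(y)), ") than internal_folds (", k,
           "); stratified folding needs every class in every training fold")
  } else {
    y <- as.matrix(y)
  }
  fold <- make_folds(nrow(X), k, y = if (is_cls) y else NULL,
                     seed = derive_seed(seed, 1L))
  meta_parts <- vector("list", length(spec$base))
  for (b in seq_along(spec$base)) {
    bs <- spec$base[[b]]
    width <- if (is_cls) nlevels(y) else ncol(y)
    oof <- matrix(NA_real_, nrow(X), width)
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- fit_base_model(bs, X[tr, , drop = FALSE],
                          if (is_cls) y[tr] else y[tr, , drop = FALSE],
                          seed = derive_seed(seed, 100L * b + f))
      oof[!tr, ] <- if (is_cls) {
        predict_base_model(m, X[!tr, , drop = FALSE], type = "score")
      } else {
        predict_base_model(m, X[!tr, , drop = FALSE])
      }
    }
    meta_parts[[b]] <- oof
  }
  Z <- do.call(cbind, meta_parts)
  meta_fit <- fit_base_model(spec$meta, Z,
                             if (is_cls) y else y,
                             seed = derive_seed(seed, 7L))
  base_full <- lapply(seq_along(spec$base), function(b)
    fit_base_model(spec$base[[b]], X,
                   if (is_cls) y else y,
                   seed = derive_seed(seed, 1000L + b)))
  structure(list(spec = spec, base = base_full, meta = meta_fit,
                 levels = if (is_cls) levels(y) else NULL,
                 n_targets = if (!is_cls) ncol(y) else NULL,
                 n_features = ncol(X)),
            class = "fitted_stack")
}

# Meta-feature matrix for new data from the full-data base fits.
stack_meta_features <- function(fitted, X) {
  parts <- lapply(fitted$base, function(m) {
    if (fitted$spec$task == "classifier") {
      predict_base_model(m, X, type = "score")
    } else {
      predict_base_model(m, X)
    }
  })
  do.call(cbind, parts)
}

#' Predict from a fitted stack
#'
#' Applies every full-data base learner to `X`, assembles their predictions
#' into the meta-feature matrix, and returns the meta learner's prediction.
#'
#' @param fitted a `fitted_stack`.
#' @param X numeric feature matrix with the training column count.
#' @return factor of labels (classifier stack) or numeric matrix
#'   `n x n_targets` (regressor stack).
#' @export
predict_stack <- function(fitted, X) {
  X <- as.matrix(X)
  if (ncol(X) != fitted$n_features)
    stop("feature count ", ncol(X), " does not match training (",
         fitted$n_features, ")")
  Z <- stack_meta_features(fitted, X)
  if (fitted$spec$task == "classifier") {
    predict_base_model(fitted$meta, Z)
  } else {
    predict_base_model(fitted$meta, Z)
  }
}

#' Cross-validated accuracy of a classification stack
#'
#' Mean stratified k-fold accuracy of the full stack (each fold fits the
#' stack, including its internal out-of-fold construction, on the training
#' part only). This is the classifier-performance term of the PSO subset
#' fitness.
#'
#' @param spec a classifier `stack_spec`.
#' @param X feature matrix.
#' @param y class labels.
#' @param folds outer CV folds (default 5).
#' @param seed integer seed; the result is deterministic given it.
#' @return numeric accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(spec, X, y, folds = 5L, seed = 1L) {
  stopifnot(folds >= 2L)
  X <- as.matrix(X)
  y <- as.factor(y)
  fold <- make_folds(nrow(X), folds, y = y, seed = derive_seed(seed, 2L))
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    fs <- fit_stack(spec, X[tr, , drop = FALSE], droplevels(y[tr]),
                    seed = derive_seed(seed, 50L + f))
    pred <- predict_stack(fs, X[!tr, , drop = FALSE])
    mean(as.character(pred) == as.character(y[!tr]))
  }, numeric(1))
  mean(acc)
}
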