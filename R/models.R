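#' Model specification
#'
#' A lightweight description of one candidate learner: its family, task
#' (classifier or regressor) and hyperparameters. Specs are the unit the
#' grid search, the benchmark screen and the stack builders exchange.
#'
#' @param family one of `"svm"`, `"knn"`, `"logistic"`, `"ridge"`, `"mlp"`,
#'   `"gaussian_nb"`, `"random_forest"`, `"svr"`, `"pls"`.
#' @param task `"classifier"` or `"regressor"`.
#' @param params named list of hyperparameters (missing entries take the
#'   family defaults of [default_model_specs()]).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family, task, params = list()) {
  families <- c("svm", "knn", "logistic", "ridge", "mlp", "gaussian_nb",
                "random_forest", "svr", "pls")
  family <- match.arg(family, families)
  task <- match.arg(task, c("classifier", "regressor"))
  classifier_only <- c("logistic", "gaussian_nb")
  regressor_only <- c("svr", "pls")
  if (task == "regressor" && family %in% classifier_only)
    stop(family, " is classifier-only")
  if (task == "classifier" && family %in% regressor_only)
    stop(family, " is regressor-only")
  structure(list(family = family, task = task, params = params),
            class = "model_spec")
}

#' Default model specifications (the tuned settings of the study)
#'
#' Returns the hyperparameter settings reported from the 5-fold grid search
#' for each candidate family: SVM `C = 1, gamma = 0.01`, RBF kernel; logistic
#' regression `C = 100`, L2 penalty; KNN `n_neighbors = 1`, uniform weights,
#' Euclidean metric; random forest `max_depth = 80, max_features = 2,
#' min_samples_leaf = 3, min_samples_split = 10, n_estimators = 200`; MLP
#' `activation = tanh, alpha = 1e-4`; ridge regularization strength `0.1`.
#' Regression counterparts (SVR, ridge regressor, KNN regressor, MLP
#' regressor, PLS) reuse the shared settings.
#'
#' The MLP hidden layout is not reported usably in the original study; the
#' package default is a single hidden layer of 16 units (the `nnet` backend is
#' single-hidden-layer by construction, with logistic rather than tanh
#' activation), `maxit = 500`.
#'
#' @return named list of `model_spec` objects: classifier entries `svm`,
#'   `knn`, `logistic`, `ridge`, `mlp`, `gaussian_nb`, `random_forest` and
#'   regressor entries `svr`, `ridge_reg`, `knn_reg`, `mlp_reg`, `pls`.
#' @export
default_model_specs <- function() {
  list(
    svm = model_spec("svm", "classifier",
                     list(C = 1, gamma = 0.01, kernel = "rbf")),
    knn = model_spec("knn", "classifier",
                     list(n_neighbors = 1, weights = "uniform",
                          metric = "euclidean")),
    logistic = model_spec("logistic", "classifier",
                          list(C = 100, penalty = "l2")),
    ridge = model_spec("ridge", "classifier",
                       list(regularization_strength = 0.1)),
    mlp = model_spec("mlp", "classifier",
                     list(hidden = 16, alpha = 1e-4, maxit = 500)),
    gaussian_nb = model_spec("gaussian_nb", "classifier", list()),
    random_forest = model_spec("random_forest", "classifier",
                               list(n_estimators = 200, max_features = 2,
                                    min_samples_leaf = 3,
                                    min_samples_split = 10, max_depth = 80)),
    svr = model_spec("svr", "regressor",
                     list(C = 1, gamma = 0.01, epsilon = 0.1)),
    ridge_reg = model_spec("ridge", "regressor",
                           list(regularization_strength = 0.1)),
    knn_reg = model_spec("knn", "regressor", list(n_neighbors = 1)),
    mlp_reg = model_spec("mlp", "regressor",
                         list(hidden = 16, alpha = 1e-4, maxit = 500)),
    pls = model_spec("pls", "regressor", list(n_latent = 9))
  )
}

# Fill missing params of a spec with family defaults.
fill_spec_defaults <- function(spec) {
  defs <- default_model_specs()
  key <- if (spec$task == "regressor" &&
             spec$family %in% c("ridge", "knn", "mlp")) {
    paste0(spec$family, "_reg")
  } else spec$family
  base <- if (key %in% names(defs)) defs[[key]]$params else list()
  spec$params <- utils::modifyList(base, spec$params)
  spec
}

# ---- single-model fit/predict backends --------------------------------------

# Fit one base learner. X numeric matrix; y factor (classifier) or numeric
# matrix n x t (regressor; a vector is treated as t = 1). Returns an object
# carrying whatever the family's backend needs for prediction.
fit_base_model <- function(spec, X, y, seed = 1L) {
  spec <- fill_spec_defaults(spec)
  X <- as.matrix(X)
  set.seed(derive_seed(seed, 17L))
  p <- spec$params
  fitted <- if (spec$task == "classifier") {
    y <- as.factor(y)
    switch(spec$family,
      svm = e1071::svm(X, y, kernel = "radial", cost = p$C, gamma = p$gamma,
                       scale = FALSE),
      knn = list(X = X, y = y, k = p$n_neighbors),
      logistic = {
        # sklearn-style C maps to lambda = 1/(C*n); on small perfectly
        # separable folds the solver can diverge at a weak penalty, so the
        # penalty is escalated tenfold until the fit succeeds with finite
        # coefficients
        Xg <- if (ncol(X) == 1L) cbind(X, 0) else X  # glmnet needs >= 2 cols
        l <- 1 / (p$C * nrow(Xg))
        fit <- NULL
        for (fac in c(1, 10, 100, 1000, 1e4)) {
          # warm-started geometric path down to the target penalty; a cold
          # single-lambda fit does not converge reliably
          path <- exp(seq(log(max(1, l * fac * 1e4)), log(l * fac),
                          length.out = 6L))
          fit <- tryCatch(
            suppressWarnings(glmnet::glmnet(Xg, y, family = "multinomial",
                                            alpha = 0, lambda = path,
                                            thresh = 1e-5, maxit = 1e5)),
            error = function(e) NULL)
          if (!is.null(fit) && length(fit$lambda) == length(path) &&
              all(vapply(fit$beta, function(b) all(is.finite(as.numeric(b))),
                         logical(1))) && all(is.finite(fit$a0))) break
          fit <- NULL
        }
        if (is.null(fit)) stop("penalized logistic regression failed")
        fit
      },
      ridge = ridge_classifier_fit(X, y, p$regularization_strength),
      mlp = {
        Y <- one_hot(y)
        utils::capture.output(m <- nnet::nnet(
          X, Y, size = p$hidden, softmax = TRUE, decay = p$alpha,
          maxit = p$maxit, MaxNWts = 1e6, trace = FALSE))
        m
      },
      gaussian_nb = e1071::naiveBayes(X, y),
      random_forest = randomForest::randomForest(
        X, y, ntree = p$n_estimators, mtry = min(p$max_features, ncol(X)),
        nodesize = p$min_samples_leaf),
      stop("no classifier backend for family ", spec$family)
    )
  } else {
    Y <- as.matrix(y)
    switch(spec$family,
      svr = lapply(seq_len(ncol(Y)), function(j)
        e1071::svm(X, Y[, j], kernel = "radial", cost = p$C, gamma = p$gamma,
                   epsilon = p$epsilon, scale = FALSE)),
      knn = list(X = X, Y = Y, k = p$n_neighbors),
      ridge = fit_ridge_multioutput(X, Y, p$regularization_strength),
      mlp = lapply(seq_len(ncol(Y)), function(j) {
        sc <- c(center = mean(Y[, j]), scale = max(stats::sd(Y[, j]), 1e-12))
        m <- nnet::nnet(X, (Y[, j] - sc["center"]) / sc["scale"],
                        size = p$hidden, linout = TRUE, decay = p$alpha,
                        maxit = p$maxit, MaxNWts = 1e6, trace = FALSE)
        list(net = m, sc = sc)
      }),
      pls = fit_pls(X, Y, p$n_latent),
      stop("no regressor backend for family ", spec$family)
    )
  }
  lv <- if (spec$task == "classifier") levels(as.factor(y)) else NULL
  structure(list(spec = spec, fit = fitted, levels = lv,
                 n_targets = if (spec$task == "regressor") ncol(as.matrix(y))
                             else NULL,
                 n_features = ncol(X)),
            class = "nirstack_model")
}

# Predict from a fitted base learner.
#  - classifier, type "class": factor of labels
#  - classifier, type "score": numeric matrix n x n_classes of probabilities
#    (or normalized scores where the backend has no probability model)
#  - regressor: numeric matrix n x t
predict_base_model <- function(model, X, type = c("class", "score")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature count ", ncol(X), " does not match training (",
         model$n_features, ")")
  spec <- model$spec
  p <- spec$params
  if (spec$task == "classifier") {
    scores <- switch(spec$family,
      svm = {
        dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                   "decision.values")
        svm_vote_scores(dv, model$levels)
      },
      knn = {
        pr <- class::knn(model$fit$X, X, model$fit$y, k = model$fit$k,
                         prob = TRUE)
        K <- length(model$levels)
        win <- match(as.character(pr), model$levels)
        p_win <- attr(pr, "prob")
        # winning-class vote share; remaining mass spread over other classes
        m <- matrix((1 - p_win) / max(K - 1L, 1L), nrow(X), K,
                    dimnames = list(NULL, model$levels))
        m[cbind(seq_len(nrow(X)), win)] <- p_win
        m
      },
      logistic = {
        Xg <- if (ncol(X) == 1L) cbind(X, 0) else X
        # stable softmax over the link predictions: glmnet's own "response"
        # overflows to NaN when the weak penalty leaves huge coefficients
        lp <- stats::predict(model$fit, Xg, type = "link",
                             s = min(model$fit$lambda))
        lp <- matrix(lp[, , 1L], nrow(X),
                     dimnames = list(NULL, dimnames(lp)[[2L]]))
        E <- exp(lp - apply(lp, 1L, max))
        E / rowSums(E)
      },
      ridge = ridge_classifier_scores(model$fit, X),
      mlp = {
        pr <- stats::predict(model$fit, X)
        colnames(pr) <- model$levels
        pr
      },
      gaussian_nb = stats::predict(model$fit, X, type = "raw"),
      random_forest = stats::predict(model$fit, X, type = "prob")
    )
    scores <- scores[, model$levels, drop = FALSE]
    if (type == "score") return(scores)
    factor(model$levels[max.col(scores, ties.method = "first")],
           levels = model$levels)
  } else {
    out <- switch(spec$family,
      svr = vapply(model$fit, function(m) as.numeric(stats::predict(m, X)),
                   numeric(nrow(X))),
      knn = knn_regress(model$fit$X, model$fit$Y, X, model$fit$k),
      ridge = predict(model$fit, X),
      mlp = vapply(model$fit, function(m)
        as.numeric(stats::predict(m$net, X)) * m$sc["scale"] + m$sc["center"],
        numeric(nrow(X))),
      pls = predict(model$fit, X)
    )
    matrix(out, nrow = nrow(X), ncol = model$n_targets)
  }
}

# One-vs-one decision values -> per-class vote fractions in [0, 1].
svm_vote_scores <- function(dv, levels) {
  n <- nrow(dv)
  votes <- matrix(0, n, length(levels), dimnames = list(NULL, levels))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    pos <- dv[, j] > 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
  }
  votes / max(length(pairs), 1L)
}

# Ridge-penalized least squares on one-hot labels (standard ridge classifier):
# coefficients solve (X'X + lambda I) B = X'Y with centered X and one-hot Y.
ridge_classifier_fit <- function(X, y, lambda) {
  Y <- one_hot(y)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx)
  B <- solve(crossprod(Xc) + lambda * diag(ncol(X)),
             crossprod(Xc, sweep(Y, 2L, my)))
  list(B = B, mx = mx, my = my, levels = colnames(Y))
}

ridge_classifier_scores <- function(fit, X) {
  S <- sweep(X, 2L, fit$mx) %*% fit$B
  S <- sweep(S, 2L, fit$my, "+")
  colnames(S) <- fit$levels
  # map linear scores to a simplex via softmax so all meta-features share scale
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

# k-nearest-neighbour regression (Euclidean, uniform weights).
knn_regress <- function(Xtr, Ytr, Xte, k) {
  k <- min(k, nrow(Xtr))
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  res <- apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    colMeans(Ytr[nn, , drop = FALSE])
  })
  if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
}

# ---- grid search, benchmark, member screening -------------------------------

#' Exhaustive grid-search cross-validation for one family
#'
#' Evaluates every point of a hyperparameter grid by k-fold cross-validation
#' (stratified folds for classification, plain folds for regression) and
#' returns the best spec. Score is classification accuracy or negative RMSE.
#' Ties keep the first point in grid enumeration order (row order of
#' `expand.grid` over the supplied lists).
#'
#' @param family model family string.
#' @param grid named list mapping parameter name to a vector of candidate
#'   values.
#' @param X feature matrix.
#' @param y labels (classification) or numeric target(s) (regression).
#' @param folds number of CV folds (default 5).
#' @param task `"classifier"` or `"regressor"`.
#' @param seed integer seed controlling fold assignment and learner RNG.
#' @return list with `spec` (the winning `model_spec`), `score` (its mean CV
#'   score) and `results` (data.frame of all grid points and scores).
#' @export
grid_search_cv <- function(family, grid, X, y, folds = 5L,
                           task = "classifier", seed = 1L) {
  stopifnot(folds >= 2L)
  pts <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(pts) == 0L) stop("empty grid")
  X <- as.matrix(X)
  is_cls <- task == "classifier"
  if (is_cls) {
    y <- as.factor(y)
    if (min(table(y)) < folds)
      stop("fold count ", folds, " exceeds the smallest class size (",
           min(table(y)), ")")
  }
  fold <- make_folds(nrow(X), folds, y = if (is_cls) y else NULL, seed = seed)
  scores <- vapply(seq_len(nrow(pts)), function(i) {
    spec <- model_spec(family, task, as.list(pts[i, , drop = FALSE]))
    per_fold <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_base_model(spec, X[tr, , drop = FALSE],
                          if (is_cls) y[tr] else as.matrix(y)[tr, , drop = FALSE],
                          seed = derive_seed(seed, f))
      if (is_cls) {
        mean(predict_base_model(m, X[!tr, , drop = FALSE]) == y[!tr])
      } else {
        -rmse(as.matrix(y)[!tr, , drop = FALSE],
              predict_base_model(m, X[!tr, , drop = FALSE]))
      }
    }, numeric(1))
    mean(per_fold)
  }, numeric(1))
  best <- which.max(scores)  # which.max takes the first maximum: tie-break
  list(spec = model_spec(family, task, as.list(pts[best, , drop = FALSE])),
       score = scores[best],
       results = cbind(pts, score = scores))
}

#' Screen candidate classifier families on variety labels
#'
#' Cross-validated variety-classification accuracy and mean fit+score wall
#' time for each requested family, the screening used to pick the members of
#' the classification stack. Rows are sorted by accuracy (descending), then
#' time (ascending), so ties on accuracy are broken in favor of the cheaper
#' model.
#'
#' @param dataset a `spectra_dataset` with variety labels.
#' @param families character vector of classifier families to screen
#'   (default: all seven candidates).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @return data.frame with columns `family`, `accuracy`, `time_s`, sorted as
#'   described.
#' @export
benchmark_candidates <- function(dataset,
                                 families = c("svm", "knn", "logistic",
                                              "ridge", "mlp", "gaussian_nb",
                                              "random_forest"),
                                 folds = 5L, seed = 1L) {
  X <- dataset$reflectance
  y <- as.factor(dataset$meta$variety)
  fold <- make_folds(nrow(X), folds, y = y, seed = seed)
  defs <- default_model_specs()
  rows <- lapply(families, function(fam) {
    spec <- defs[[fam]]
    t0 <- proc.time()[["elapsed"]]
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_base_model(spec, X[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, f))
      mean(predict_base_model(m, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    data.frame(family = fam, accuracy = mean(acc),
               time_s = (proc.time()[["elapsed"]] - t0) / folds)
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy, out$time_s), , drop = FALSE]
}

#' Pick stack members from a benchmark table
#'
#' Top-k families by (accuracy descending, time ascending) — the rule that,
#' with several families tied at perfect accuracy, keeps the k fastest (the
#' study's screen kept SVM, KNN, logistic regression and ridge, dropping the
#' slower MLP).
#'
#' @param rows data.frame from [benchmark_candidates()].
#' @param k number of members to keep (>= 2).
#' @return character vector of k family names.
#' @export
select_stack_members <- function(rows, k = 4L) {
  if (k < 2L) stop("a stack needs at least 2 members")
  if (k > nrow(rows)) stop("k exceeds the number of benchmarked families")
  ord <- rows[order(-rows$accuracy, rows$time_s), , drop = FALSE]
  as.character(ord$family[seq_len(k)])
}
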