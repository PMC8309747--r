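#' Lasso channel selection
#'
#' L1-penalized linear regression of the targets on all channels; the mask
#' keeps every channel with a nonzero coefficient for at least one target.
#' When `strength` is not given, each target's penalty is chosen by 5-fold
#' cross-validation over [glmnet::cv.glmnet()]'s logarithmic grid
#' (lambda.min).
#'
#' @param X feature matrix (calibration spectra).
#' @param Y numeric target matrix (n x t) or vector.
#' @param strength optional fixed penalty lambda (> 0).
#' @param seed integer seed for the CV fold assignment.
#' @return 0/1 integer mask over the channels.
#' @export
lasso_select <- function(X, Y, strength = NULL, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.null(strength) && strength <= 0) stop("strength must be > 0")
  mask <- rep(0L, ncol(X))
  for (j in seq_len(ncol(Y))) {
    if (is.null(strength)) {
      set.seed(derive_seed(seed, j))
      cvfit <- glmnet::cv.glmnet(X, Y[, j], alpha = 1, nfolds = 5L)
      co <- stats::coef(cvfit, s = "lambda.min")
    } else {
      fit <- glmnet::glmnet(X, Y[, j], alpha = 1,
                            lambda = strength * c(100, 10, 1))
      co <- stats::coef(fit, s = strength)
    }
    nz <- which(as.numeric(co)[-1L] != 0)  # drop intercept
    mask[nz] <- 1L
  }
  if (sum(mask) == 0L)
    stop("lasso selected no channels; use a smaller strength")
  mask
}

#' Genetic-algorithm configuration
#'
#' Defaults mirror the PSO budget: population 50, 10 generations, one-point
#' crossover at 0.9, per-bit mutation 1/D, tournament size 3, elitism of 1.
#'
#' @param population population size (>= 2). Default 50.
#' @param generations generations (>= 1). Default 10.
#' @param crossover crossover probability. Default 0.9.
#' @param mutation per-bit flip probability (default `NULL` = 1/D).
#' @param tournament tournament size. Default 3.
#' @param seed integer seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population = 50L, generations = 10L, crossover = 0.9,
                      mutation = NULL, tournament = 3L, seed = 1L) {
  stopifnot(population >= 2L, generations >= 1L,
            crossover >= 0, crossover <= 1,
            is.null(mutation) || (mutation >= 0 && mutation <= 1))
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover = crossover, mutation = mutation,
                 tournament = as.integer(tournament),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm channel selection
#'
#' Generational GA over bit-string masks: tournament selection, one-point
#' crossover, per-bit flip mutation, elitism of 1 (the best-ever individual
#' survives unchanged, so best fitness is non-decreasing). Same fitness
#' contract and caching as [run_pso()]; all-zero offspring are repaired by
#' setting one random bit.
#'
#' @param dataset a `spectra_dataset`.
#' @param fitness function `(mask, dataset) -> numeric`, larger is better.
#' @param config a `ga_config`.
#' @return list with `mask`, `fitness`, `history` (best-ever per
#'   generation).
#' @export
ga_select <- function(dataset, fitness, config) {
  D <- length(dataset$wavelengths)
  P <- config$population
  pmut <- config$mutation %||% (1 / D)
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(mask) {
    key <- paste(mask, collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    rng <- get(".Random.seed", envir = globalenv())
    val <- fitness(mask, dataset)
    assign(".Random.seed", rng, envir = globalenv())
    cache[[key]] <- val
    val
  }
  repair <- function(m) {
    if (sum(m) == 0L) m[sample.int(D, 1L)] <- 1L
    m
  }
  pop <- matrix(stats::rbinom(P * D, 1L, 0.5), P, D)
  for (i in seq_len(P)) pop[i, ] <- repair(pop[i, ])
  best_mask <- NULL; best_fit <- -Inf
  history <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    fit <- vapply(seq_len(P), function(i) eval_mask(pop[i, ]), numeric(1))
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fit) {
      best_fit <- fit[gen_best]
      best_mask <- pop[gen_best, ]
    }
    history[g] <- best_fit
    if (g == config$generations) break
    tournament_pick <- function() {
      cand <- sample.int(P, config$tournament)
      cand[which.max(fit[cand])]
    }
    children <- matrix(0L, P, D)
    children[1L, ] <- best_mask            # elitism of 1
    i <- 2L
    while (i <= P) {
      a <- pop[tournament_pick(), ]; b <- pop[tournament_pick(), ]
      if (stats::runif(1) < config$crossover && D > 1L) {
        cut <- sample.int(D - 1L, 1L)
        child1 <- c(a[seq_len(cut)], b[(cut + 1L):D])
        child2 <- c(b[seq_len(cut)], a[(cut + 1L):D])
      } else {
        child1 <- a; child2 <- b
      }
      for (child in list(child1, child2)) {
        if (i > P) break
        flip <- stats::runif(D) < pmut
        child[flip] <- 1L - child[flip]
        children[i, ] <- repair(child)
        i <- i + 1L
      }
    }
    pop <- children
  }
  list(mask = best_mask, fitness = best_fit, history = history)
}

#' PSO-SVM channel selection (baseline)
#'
#' The same binary-PSO engine as the main method, but with a single RBF SVM
#' (`C = 1, gamma = 0.01`) as the fitness classifier instead of the
#' classification stack — the conventional wrapper this package's stacked
#' fitness is benchmarked against.
#'
#' @param dataset a `spectra_dataset`.
#' @param config a `pso_config`.
#' @param alpha trade-off weight (default `config$alpha`).
#' @param aggregate_replicates average replicates before the fitness CV
#'   (default FALSE).
#' @return as [run_pso()].
#' @export
pso_svm_select <- function(dataset, config, alpha = config$alpha,
                           aggregate_replicates = FALSE) {
  svm_spec <- default_model_specs()$svm
  fitness <- make_subset_fitness(svm_spec, alpha = alpha,
                                 folds = config$fitness_folds,
                                 seed = config$seed,
                                 aggregate_replicates = aggregate_replicates)
  run_pso(dataset, fitness, config)
}

#' Compare channel selectors through a common ridge regression
#'
#' The benchmarking harness: each selector picks channels on the calibration
#' set only; a multi-output ridge (strength 0.1) is fit on the masked,
#' standardized calibration spectra to predict nitrogen and organic matter
#' simultaneously; joint metrics are computed on both sets. The joint
#' two-target R2/RMSE standardizes each target to zero mean / unit SD using
#' calibration statistics and stacks the two standardized columns into one
#' vector, so neither target's scale dominates. A no-selection baseline row
#' (all channels) is always appended.
#'
#' @param dataset a `spectra_dataset`.
#' @param selectors subset of `c("pso-fsgc", "pso-svm", "ga", "lasso")`.
#' @param seed integer seed (split, selectors, CV).
#' @param prediction_fraction split fraction (default 0.25).
#' @param pso a `pso_config` for the PSO selectors.
#' @param ga a `ga_config` for the GA.
#' @param fitness_model classifier for the wrapper fitness of `pso-fsgc` and
#'   `ga` (default [build_fsgc()]).
#' @param alpha wrapper trade-off weight (default 0.5).
#' @param aggregate_replicates average replicates inside wrapper fitness.
#' @return data.frame, one row per selector plus `none`: `selector`,
#'   `regressor`, `n_selected`, `R2c`, `RMSEC`, `R2p`, `RMSEP`, `LOD` (joint
#'   over the standardized targets).
#' @export
compare_feature_selectors <- function(dataset,
                                      selectors = c("pso-fsgc", "pso-svm",
                                                    "ga", "lasso"),
                                      seed = 1L,
                                      prediction_fraction = 0.25,
                                      pso = pso_config(seed = seed),
                                      ga = ga_config(seed = seed),
                                      fitness_model = build_fsgc(),
                                      alpha = 0.5,
                                      aggregate_replicates = FALSE) {
  stopifnot(length(selectors) >= 1L)
  split <- split_calibration_prediction(dataset, prediction_fraction,
                                        seed = seed)
  cal <- subset_spectra(dataset, split$calibration)
  pred <- subset_spectra(dataset, split$prediction)
  scaler <- standardize_fit(cal)
  cal_s <- standardize_apply(scaler, cal)
  pred_s <- standardize_apply(scaler, pred)
  Ycal <- cbind(cal$meta$nitrogen, cal$meta$organic_matter)
  Ypred <- cbind(pred$meta$nitrogen, pred$meta$organic_matter)

  stack_fitness <- make_subset_fitness(fitness_model, alpha = alpha,
                                       folds = pso$fitness_folds,
                                       seed = seed,
                                       aggregate_replicates =
                                         aggregate_replicates)
  select_mask <- function(sel) {
    switch(sel,
      "pso-fsgc" = run_pso(cal_s, stack_fitness, pso)$mask,
      "pso-svm" = pso_svm_select(cal_s, pso, alpha = alpha,
                                 aggregate_replicates =
                                   aggregate_replicates)$mask,
      "ga" = ga_select(cal_s, stack_fitness, ga)$mask,
      "lasso" = lasso_select(cal_s$reflectance, Ycal, seed = seed),
      "none" = rep(1L, length(dataset$wavelengths)),
      stop("unknown selector: ", sel)
    )
  }

  joint_row <- function(sel, mask) {
    keep <- mask == 1L
    model <- fit_ridge_multioutput(cal_s$reflectance[, keep, drop = FALSE],
                                   Ycal, strength = 0.1)
    pc <- predict(model, cal_s$reflectance[, keep, drop = FALSE])
    pp <- predict(model, pred_s$reflectance[, keep, drop = FALSE])
    mu <- colMeans(Ycal); sdv <- apply(Ycal, 2L, stats::sd)
    zs <- function(M) sweep(sweep(M, 2L, mu), 2L, sdv, "/")
    yc <- as.numeric(zs(Ycal)); pcz <- as.numeric(zs(pc))
    yp <- as.numeric(zs(Ypred)); ppz <- as.numeric(zs(pp))
    data.frame(selector = sel, regressor = "ridge", n_selected = sum(mask),
               R2c = r_squared(yc, pcz), RMSEC = rmse(yc, pcz),
               R2p = r_squared(yp, ppz), RMSEP = rmse(yp, ppz),
               LOD = lod(yp, ppz))
  }

  rows <- lapply(selectors, function(sel) joint_row(sel, select_mask(sel)))
  rows <- c(rows, list(joint_row("none",
                                 rep(1L, length(dataset$wavelengths)))))
  do.call(rbind, rows)
}
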