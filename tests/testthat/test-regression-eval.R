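test_that("R2 and RMSE match direct formula evaluation", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  # oracle: explicit sums on random vectors
  set.seed(21)
  for (i in 1:10) {
    y <- rnorm(20); p <- rnorm(20)
    expect_equal(r_squared(y, p),
                 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_equal(rmse(y, p), sqrt(sum((y - p)^2) / 20), tolerance = 1e-12)
    # homogeneity of RMSE
    expect_equal(rmse(3 * y, 3 * p), 3 * rmse(y, p), tolerance = 1e-12)
  }
})

test_that("pseudounivariate LOD follows 3.3 * s_res / |slope|", {
  y <- seq(1, 5, length.out = 20)
  expect_equal(lod(y, y), 0)

  # slope halved at fixed residuals doubles the LOD
  set.seed(31)
  e <- rnorm(200, 0, 0.2)
  y <- runif(200, 1, 5)
  l1 <- lod(y, y + e)
  l2 <- lod(y, 0.5 * y + e)
  expect_equal(l2 / l1, 2, tolerance = 0.05)

  # consistency: y_pred = y + N(0, 0.1) at large n -> LOD ~ 3.3 * 0.1
  set.seed(32)
  y <- runif(1e4, 1, 5)
  p <- y + rnorm(1e4, 0, 0.1)
  expect_equal(lod(y, p), 0.33, tolerance = 0.05)
  expect_equal(lod(y, p, factor = 3) / lod(y, p), 3 / 3.3, tolerance = 1e-10)

  expect_error(lod(y, rep(2, 1e4) + rnorm(1e4, 0, 1e-20)), "slope")
})

test_that("multi-output ridge equals the normal-equation solution", {
  set.seed(41)
  X <- matrix(rnorm(15), 5, 3)
  Y <- matrix(rnorm(10), 5, 2)
  lam <- 0.7
  fit <- fit_ridge_multioutput(X, Y, lam)
  # direct oracle on centered data
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  B <- solve(t(Xc) %*% Xc + lam * diag(3)) %*% t(Xc) %*% Yc
  expect_equal(unname(fit$B), unname(B), tolerance = 1e-8)

  # strength 0 on exact-linear data recovers coefficients
  Xf <- matrix(rnorm(60), 20, 3)
  Yf <- Xf %*% cbind(c(1, 2, -1), c(0, 1, 3))
  f0 <- fit_ridge_multioutput(Xf, Yf, 0)
  expect_equal(unname(f0$B), cbind(c(1, 2, -1), c(0, 1, 3)),
               tolerance = 1e-8)

  # strength -> infinity shrinks predictions to the training means
  finf <- fit_ridge_multioutput(Xf, Yf, 1e12)
  expect_equal(predict(finf, Xf),
               matrix(colMeans(Yf), 20, 2, byrow = TRUE),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("PLS recovers full-rank linear data and is monotone in latent variables", {
  set.seed(51)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- X %*% cbind(rnorm(6), rnorm(6))
  full <- fit_pls(X, Y, 6)
  expect_gt(r_squared(Y[, 1], predict(full, X)[, 1]), 1 - 1e-6)

  # calibration R2 never decreases as Lv grows
  Yn <- Y + matrix(rnorm(80, 0, 0.5), 40, 2)
  r2 <- vapply(1:6, function(lv) {
    p <- predict(fit_pls(X, Yn, lv), X)
    r_squared(as.numeric(Yn), as.numeric(p))
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-8))

  # a single latent variable cannot capture two orthogonal factors
  one <- fit_pls(X, Y, 1)
  expect_lt(r_squared(as.numeric(Y), as.numeric(predict(one, X))), 1 - 1e-4)

  expect_error(fit_pls(X, Y, 50), "n_latent")
})

test_that("lasso keeps informative channels and errors on an excessive penalty", {
  set.seed(61)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10)
  Y <- cbind(3 * X[, 4] + rnorm(n, 0, 0.1))
  mask <- lasso_select(X, Y, seed = 1)
  expect_equal(mask[4], 1L)
  expect_lte(sum(mask), 3L)
  expect_error(lasso_select(X, Y, strength = 1e6), "smaller strength")
  # tiny penalty keeps everything on a small full-rank problem
  m0 <- lasso_select(X[, 1:3], cbind(X[, 1] + 2 * X[, 2] - X[, 3]),
                     strength = 1e-8)
  expect_equal(sum(m0), 3L)
})

test_that("GA converges on a size-only objective and respects elitism", {
  ds <- toy_dataset(n = 6L, D = 10L)
  size_fit <- function(mask, dataset) 1 - sum(mask) / length(mask)
  res <- ga_select(ds, size_fit, ga_config(population = 30L,
                                           generations = 30L, seed = 2))
  expect_equal(sum(res$mask), 1L)
  expect_true(all(diff(res$history) >= 0))
})

test_that("GA matches the exhaustive oracle on most seeds of the 8-channel benchmark", {
  bench <- d8_benchmark()
  oracle <- exhaustive_best_subset(bench$dataset, bench$fitness)
  hits <- 0L
  for (s in 1:20) {
    res <- ga_select(bench$dataset, bench$fitness,
                     ga_config(population = 50L, generations = 10L,
                               seed = s))
    expect_lte(res$fitness, oracle$fitness + 1e-12)
    if (abs(res$fitness - oracle$fitness) < 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
})

test_that("PSO-SVM baseline returns a non-empty mask through the same engine", {
  gen <- reduced_benchmark()
  ds8 <- apply_feature_mask(gen$dataset, gen$truth)
  res <- pso_svm_select(ds8, pso_config(n_particles = 10L,
                                        n_iterations = 5L, seed = 4,
                                        fitness_folds = 3L))
  expect_gte(sum(res$mask), 1L)
  expect_true(all(diff(res$history) >= 0))
})

test_that("evaluate_model returns the two-property metrics table", {
  gen <- reduced_benchmark()
  sp <- split_calibration_prediction(gen$dataset, 0.25, seed = 1)
  cal <- subset_spectra(gen$dataset, sp$calibration)
  pred <- subset_spectra(gen$dataset, sp$prediction)
  model <- fit_ridge_multioutput(cal$reflectance,
                                 cbind(cal$meta$nitrogen,
                                       cal$meta$organic_matter), 0.1)
  m <- evaluate_model(model, cal, pred)
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(m$property, c("nitrogen", "organic_matter"))
  expect_true(all(m$RMSEC >= 0) && all(m$RMSEP >= 0))
  expect_true(all(m$R2c <= 1) && all(m$LOD >= 0))

  # memorizing model evaluated on cal = pred gives R2c = R2p
  same <- evaluate_model(model, cal, cal)
  expect_equal(same$R2c, same$R2p)
})

test_that("selector comparison runs leakage-free with a shared ridge", {
  gen <- reduced_benchmark()
  ds <- gen$dataset
  cmp <- compare_feature_selectors(
    ds, selectors = c("lasso", "ga"), seed = 1,
    pso = pso_config(n_particles = 10L, n_iterations = 3L, seed = 1,
                     fitness_folds = 3L),
    ga = ga_config(population = 10L, generations = 3L, seed = 1),
    fitness_model = default_model_specs()$ridge)
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$selector, c("lasso", "ga", "none"))
  expect_equal(cmp$n_selected[cmp$selector == "none"], 64L)
  expect_true(all(cmp$n_selected >= 1))
  expect_true(all(cmp$RMSEC >= 0))

  # leakage invariance: shuffling prediction-set targets must not change
  # the selected mask (selection sees calibration rows only)
  sp <- split_calibration_prediction(ds, 0.25, seed = 1)
  ds_shuf <- ds
  set.seed(77)
  perm <- sample(sp$prediction)
  ds_shuf$meta$nitrogen[sp$prediction] <- ds$meta$nitrogen[perm]
  ds_shuf$meta$organic_matter[sp$prediction] <- ds$meta$organic_matter[perm]
  ds_shuf$meta$sample_id[sp$prediction] <- ds$meta$sample_id[perm]
  ds_shuf$meta$variety[sp$prediction] <- ds$meta$variety[perm]
  cal <- subset_spectra(ds, sp$calibration)
  cal2 <- subset_spectra(ds_shuf, sp$calibration)
  m1 <- lasso_select(cal$reflectance,
                     cbind(cal$meta$nitrogen, cal$meta$organic_matter),
                     seed = 1)
  m2 <- lasso_select(cal2$reflectance,
                     cbind(cal2$meta$nitrogen, cal2$meta$organic_matter),
                     seed = 1)
  expect_identical(m1, m2)
})
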