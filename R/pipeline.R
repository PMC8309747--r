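#' Down-bin channels by block averaging
#'
#' Averages consecutive blocks of `width` channels (the last block may be
#' shorter), the tractability device that turns the 2151-channel grid into a
#' ~215-bin grid before wrapper selection. The binned grid's wavelengths are
#' the block means. The returned `map` lets [expand_mask()] translate a mask
#' on the binned grid back to the full grid.
#'
#' @param dataset a `spectra_dataset`.
#' @param width block width in channels (1 = no binning).
#' @return list with `dataset` (binned `spectra_dataset`) and `map` (list of
#'   original channel indices per bin).
#' @export
bin_channels <- function(dataset, width) {
  width <- as.integer(width)
  stopifnot(width >= 1L)
  D <- length(dataset$wavelengths)
  bins <- split(seq_len(D), ceiling(seq_len(D) / width))
  refl <- vapply(bins, function(ix)
    rowMeans(dataset$reflectance[, ix, drop = FALSE]),
    numeric(nrow(dataset$reflectance)))
  if (nrow(dataset$reflectance) == 1L) refl <- matrix(refl, nrow = 1L)
  wl <- vapply(bins, function(ix) mean(dataset$wavelengths[ix]), numeric(1))
  out <- dataset
  out$wavelengths <- as.numeric(wl)
  out$reflectance <- refl
  list(dataset = out, map = bins)
}

#' Expand a binned-grid mask to the full grid
#'
#' Every original channel belonging to a selected bin becomes selected.
#'
#' @param mask 0/1 mask over the bins.
#' @param map bin-to-channel map from [bin_channels()].
#' @return 0/1 integer mask over the original channels.
#' @export
expand_mask <- function(mask, map) {
  stopifnot(length(mask) == length(map))
  D <- max(unlist(map))
  out <- rep(0L, D)
  for (b in which(mask == 1L)) out[map[[b]]] <- 1L
  out
}

default_run_config <- function() {
  list(
    input = NULL,                   # path to a spectra CSV; NULL = simulate
    preset = "study",               # generator preset when simulating
    output_dir = NULL,              # NULL = no files written
    seed = 1L,
    smoothing = list(window = 11L, polyorder = 2L),
    split = list(prediction_fraction = 0.25, stratify_by_variety = TRUE,
                 group_by_sample = FALSE),
    bin_width = 10L,
    selector = list(method = "pso-fsgc", alpha = 0.5, particles = 50L,
                    iterations = 10L, fitness_folds = 3L,
                    internal_folds = 3L, aggregate_replicates = TRUE),
    regressors = c("ssgr", "ridge", "svr", "pls3", "pls6", "pls9")
  )
}

#' Parse a pipeline run configuration
#'
#' Reads a JSON or YAML file (by extension; anything not `.yml`/`.yaml` is
#' parsed as JSON) and fills every missing entry with the package defaults
#' (wrapper selector `pso-fsgc`, `alpha = 0.5`, 50 particles, 10 iterations,
#' a 75:25 stratified split, Savitzky-Golay window 11 / polyorder 2, bin
#' width 10). An empty or absent file yields the all-defaults configuration.
#' Unknown keys are an error.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return validated `run_config` list.
#' @export
parse_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
      if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE)
      else NULL
    }
    if (!is.null(raw)) cfg <- merge_config(cfg, raw, "")
  }
  validate_run_config(cfg)
  cfg
}

merge_config <- function(base, override, prefix) {
  for (key in names(override)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop("config key ", full, " must be a mapping")
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(full, "."))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  s <- cfg$selector
  if (s$alpha < 0 || s$alpha > 1) stop("selector.alpha must be in [0, 1]")
  if (!(s$method %in% c("pso-fsgc", "pso-svm", "ga", "lasso", "none")))
    stop("unknown selector.method: ", s$method)
  if (cfg$smoothing$window %% 2L == 0L) stop("smoothing.window must be odd")
  if (cfg$bin_width < 1L) stop("bin_width must be >= 1")
  bad <- setdiff(cfg$regressors,
                 c("ssgr", "ridge", "svr", "pls3", "pls6", "pls9"))
  if (length(bad)) stop("unknown regressor(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Run the full selection + calibration pipeline
#'
#' Orchestrates one end-to-end run: load (or simulate) spectra ->
#' Savitzky-Golay smoothing -> stratified calibration/prediction split ->
#' channel binning -> standardization (fit on calibration only) -> wavelength
#' selection on the calibration set -> regressor training on the selected
#' bins -> metrics on both sets. When `config$output_dir` is set, writes
#' `mask.json` (selected wavelengths and fitness history), `metrics.csv`
#' (one row per regressor and property, table-2 layout) and `report.json`
#' (config, seed, counts, timings). Deterministic given `config$seed`.
#'
#' @param config a `run_config` from [parse_config()] (default: all
#'   defaults, which simulates the study-design dataset).
#' @param quiet suppress the per-stage progress messages. Default FALSE.
#' @return the run report, invisibly: list with `config`, `mask` (full-grid
#'   0/1), `wavelengths_selected`, `n_selected`, `fitness_history`,
#'   `metrics` (data.frame), `timings_s`.
#' @export
run_full_pipeline <- function(config = parse_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[nirstack] ", ...)
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage, t0) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  t0 <- proc.time()[["elapsed"]]
  if (is.null(config$input)) {
    say("simulating ", config$preset, "-preset dataset (seed ",
        config$seed, ")")
    gen <- generate_dataset(generator_config(config$preset,
                                             seed = config$seed))
    dataset <- gen$dataset
  } else {
    if (!file.exists(config$input))
      stop("input spectra file not found: ", config$input)
    say("reading ", config$input)
    dataset <- read_spectra_csv(config$input)
  }
  tick("load", t0)

  t0 <- proc.time()[["elapsed"]]
  say("Savitzky-Golay smoothing (window ", config$smoothing$window,
      ", polyorder ", config$smoothing$polyorder, ")")
  dataset <- savgol_smooth(dataset, config$smoothing$window,
                           config$smoothing$polyorder)
  tick("smooth", t0)

  t0 <- proc.time()[["elapsed"]]
  split <- split_calibration_prediction(
    dataset, config$split$prediction_fraction, seed = config$seed,
    stratify_by_variety = config$split$stratify_by_variety,
    group_by_sample = config$split$group_by_sample)
  say("split: ", length(split$calibration), " calibration / ",
      length(split$prediction), " prediction spectra")

  binned <- bin_channels(dataset, config$bin_width)
  cal <- subset_spectra(binned$dataset, split$calibration)
  pred <- subset_spectra(binned$dataset, split$prediction)
  scaler <- standardize_fit(cal)
  cal_s <- standardize_apply(scaler, cal)
  pred_s <- standardize_apply(scaler, pred)
  tick("split_standardize", t0)

  t0 <- proc.time()[["elapsed"]]
  sel <- config$selector
  D_bins <- length(cal_s$wavelengths)
  history <- NULL
  if (sel$method == "none") {
    mask_bins <- rep(1L, D_bins)
  } else if (sel$method == "lasso") {
    say("lasso selection")
    mask_bins <- lasso_select(cal_s$reflectance,
                              cbind(cal_s$meta$nitrogen,
                                    cal_s$meta$organic_matter),
                              seed = config$seed)
  } else {
    pso <- pso_config(n_particles = sel$particles,
                      n_iterations = sel$iterations, alpha = sel$alpha,
                      seed = config$seed, fitness_folds = sel$fitness_folds)
    if (sel$method == "pso-svm") {
      say("PSO-SVM selection (", sel$particles, " particles x ",
          sel$iterations, " iterations)")
      res <- pso_svm_select(cal_s, pso, alpha = sel$alpha,
                            aggregate_replicates = sel$aggregate_replicates)
    } else {
      fsgc <- build_fsgc(internal_folds = sel$internal_folds)
      fitness <- make_subset_fitness(
        fsgc, alpha = sel$alpha, folds = sel$fitness_folds,
        seed = config$seed,
        aggregate_replicates = sel$aggregate_replicates)
      if (sel$method == "ga") {
        say("GA selection")
        res <- ga_select(cal_s, fitness,
                         ga_config(population = sel$particles,
                                   generations = sel$iterations,
                                   seed = config$seed))
      } else {
        say("PSO-FSGC selection (", sel$particles, " particles x ",
            sel$iterations, " iterations, alpha ", sel$alpha, ")")
        res <- run_pso(cal_s, fitness, pso)
      }
    }
    mask_bins <- res$mask
    history <- res$history
    say("selection fitness ", round(res$fitness, 4), ", ",
        sum(mask_bins), "/", D_bins, " bins selected")
  }
  mask_full <- expand_mask(mask_bins, binned$map)
  tick("select", t0)

  t0 <- proc.time()[["elapsed"]]
  keep <- mask_bins == 1L
  cal_m <- cal_s; pred_m <- pred_s
  cal_m$wavelengths <- cal_s$wavelengths[keep]
  cal_m$reflectance <- cal_s$reflectance[, keep, drop = FALSE]
  pred_m$wavelengths <- pred_s$wavelengths[keep]
  pred_m$reflectance <- pred_s$reflectance[, keep, drop = FALSE]
  Ycal <- cbind(cal_m$meta$nitrogen, cal_m$meta$organic_matter)
  X <- cal_m$reflectance

  fit_one <- function(name) {
    say("fitting ", name, " on ", sum(keep), " bins")
    switch(name,
      ssgr = fit_stack(build_ssgr(), X, Ycal, seed = config$seed),
      ridge = fit_ridge_multioutput(X, Ycal, strength = 0.1),
      svr = fit_base_model(default_model_specs()$svr, X, Ycal,
                           seed = config$seed),
      pls3 = fit_pls(X, Ycal, 3L),
      pls6 = fit_pls(X, Ycal, 6L),
      pls9 = fit_pls(X, Ycal, 9L)
    )
  }
  metrics <- if (length(config$regressors)) {
    do.call(rbind, lapply(config$regressors, function(name) {
      m <- evaluate_model(fit_one(name), cal_m, pred_m)
      cbind(method = name, m)
    }))
  } else NULL
  tick("train_evaluate", t0)

  report <- list(
    config = config,
    n_spectra = n_spectra(dataset),
    n_calibration = length(split$calibration),
    n_prediction = length(split$prediction),
    mask = mask_full,
    wavelengths_selected = dataset$wavelengths[mask_full == 1L],
    n_selected = sum(mask_full),
    n_bins_selected = sum(mask_bins),
    fitness_history = history,
    metrics = metrics,
    timings_s = timings,
    r_version = as.character(getRversion())
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(wavelengths_selected = report$wavelengths_selected,
           fitness_history = history %||% numeric(0)),
      file.path(config$output_dir, "mask.json"), digits = NA)
    if (!is.null(metrics))
      utils::write.csv(metrics, file.path(config$output_dir, "metrics.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "metrics")],
                         file.path(config$output_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    say("outputs written to ", config$output_dir)
  }
  say("done in ", round(proc.time()[["elapsed"]] - t_start, 1), " s")
  invisible(report)
}
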