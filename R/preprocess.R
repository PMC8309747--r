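#' Savitzky-Golay smoothing of all spectra
#'
#' Replaces each spectrum by its Savitzky-Golay least-squares polynomial
#' smoothing, the only preprocessing applied to the reflectance data before
#' modeling (no derivative is taken). Delegates to [signal::sgolayfilt()],
#' whose projection matrix handles the window transients at both ends of the
#' spectrum, so a polynomial of degree `<= polyorder` is reproduced exactly
#' over the whole grid.
#'
#' @param dataset a `spectra_dataset`.
#' @param window odd integer, filter length in channels. Default 11.
#' @param polyorder integer polynomial degree, `< window`. Default 2.
#' @return a `spectra_dataset` with smoothed reflectance; metadata unchanged.
#' @export
savgol_smooth <- function(dataset, window = 11L, polyorder = 2L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  if (polyorder >= window) stop("polyorder (", polyorder,
                                ") must be smaller than window (", window, ")")
  if (window > length(dataset$wavelengths))
    stop("window (", window, ") exceeds channel count (",
         length(dataset$wavelengths), ")")
  out <- dataset
  out$reflectance <- t(apply(dataset$reflectance, 1L, signal::sgolayfilt,
                             p = polyorder, n = window))
  if (nrow(dataset$reflectance) == 1L)
    out$reflectance <- matrix(out$reflectance, nrow = 1L)
  out
}

#' Fit a per-channel standardization scaler
#'
#' Computes the per-channel mean and sample (n-1) standard deviation of the
#' calibration spectra. The scaler is fit on the calibration set only and then
#' applied unchanged to the prediction set, so no prediction-set statistics
#' leak into the model.
#'
#' @param calibration a `spectra_dataset` with at least 2 spectra.
#' @return an object of class `spectra_scaler`: list with `wavelengths`,
#'   `mean`, `sd`.
#' @export
standardize_fit <- function(calibration) {
  if (nrow(calibration$reflectance) < 2L)
    stop("need at least 2 spectra to fit a scaler")
  mu <- colMeans(calibration$reflectance)
  sd <- apply(calibration$reflectance, 2L, stats::sd)
  if (any(sd <= 0)) {
    bad <- calibration$wavelengths[sd <= 0]
    stop("zero-variance channel(s) at wavelength(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  structure(list(wavelengths = calibration$wavelengths, mean = mu, sd = sd),
            class = "spectra_scaler")
}

#' Apply a fitted scaler to a dataset
#'
#' Transforms reflectance to `(x - mean)/sd` per channel using the statistics
#' stored in the scaler (i.e. the calibration statistics).
#'
#' @param scaler a `spectra_scaler` from [standardize_fit()].
#' @param dataset a `spectra_dataset` on the same grid.
#' @return the standardized `spectra_dataset`.
#' @export
standardize_apply <- function(scaler, dataset) {
  if (!identical(as.numeric(scaler$wavelengths),
                 as.numeric(dataset$wavelengths)))
    stop("dataset grid does not match the scaler's grid")
  out <- dataset
  out$reflectance <- sweep(sweep(dataset$reflectance, 2L, scaler$mean, "-"),
                           2L, scaler$sd, "/")
  out
}

#' Serialize a scaler to JSON
#' @param scaler a `spectra_scaler`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_scaler_json <- function(scaler, path) {
  jsonlite::write_json(unclass(scaler), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a scaler from JSON
#' @param path path written by [write_scaler_json()].
#' @return a `spectra_scaler`.
#' @export
read_scaler_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(wavelengths = as.numeric(x$wavelengths),
                 mean = as.numeric(x$mean), sd = as.numeric(x$sd)),
            class = "spectra_scaler")
}

#' Split spectra into calibration and prediction sets
#'
#' Draws a deterministic (seeded) split with prediction size
#' `ceiling(prediction_fraction * n)`; at fraction 0.25 this reproduces the
#' study's 607-calibration / 203-prediction partition of 810 spectra. With
#' `stratify_by_variety = TRUE` (default) the prediction set is allocated
#' proportionally across varieties by largest remainder, so each variety is
#' represented in both sets.
#'
#' With `group_by_sample = TRUE`, all replicate spectra of one physical sample
#' are assigned to the same side, preventing replicate leakage between the
#' sets; the default is `FALSE`, which splits individual spectra and mirrors
#' the study's 607/203 spectrum counts.
#'
#' @param dataset a `spectra_dataset`.
#' @param prediction_fraction fraction in (0, 1) of spectra assigned to the
#'   prediction set. Default 0.25.
#' @param seed integer seed; the split is a pure function of (dataset, args).
#' @param stratify_by_variety allocate proportionally per variety. Default TRUE.
#' @param group_by_sample keep replicates of one sample together. Default FALSE.
#' @return object of class `split_indices`: list with integer vectors
#'   `calibration` and `prediction` (disjoint, covering all rows).
#' @export
split_calibration_prediction <- function(dataset, prediction_fraction = 0.25,
                                         seed = 1L,
                                         stratify_by_variety = TRUE,
                                         group_by_sample = FALSE) {
  n <- n_spectra(dataset)
  if (prediction_fraction <= 0 || prediction_fraction >= 1)
    stop("prediction_fraction must be in (0, 1)")
  n_pred <- as.integer(ceiling(prediction_fraction * n))
  if (n_pred >= n) stop("prediction_fraction leaves an empty calibration set")

  # unit = spectrum row, or sample group when group_by_sample
  if (group_by_sample) {
    units <- unique(dataset$meta$sample_id)
    unit_var <- dataset$meta$variety[match(units, dataset$meta$sample_id)]
    n_units <- length(units)
    n_pred_units <- as.integer(ceiling(prediction_fraction * n_units))
  } else {
    units <- seq_len(n)
    unit_var <- dataset$meta$variety
    n_units <- n
    n_pred_units <- n_pred
  }

  pred_units <- local({
    set.seed(as.integer(seed))
    if (stratify_by_variety) {
      vars <- sort(unique(unit_var))
      counts <- vapply(vars, function(v) sum(unit_var == v), integer(1))
      exact <- prediction_fraction * counts
      base <- pmin(floor(exact), counts - 1L)  # keep >= 1 unit in calibration
      rem <- n_pred_units - sum(base)
      extra <- integer(length(vars))
      if (rem > 0) {
        ord <- order(-(exact - floor(exact)), seq_along(vars))
        take <- utils::head(ord[base[ord] + 1L <= counts[ord]], rem)
        extra[take] <- 1L
      }
      alloc <- base + extra
      unlist(lapply(seq_along(vars), function(k) {
        pool <- units[unit_var == vars[k]]
        pool[sample.int(length(pool), alloc[k])]
      }), use.names = FALSE)
    } else {
      units[sample.int(n_units, n_pred_units)]
    }
  })

  if (group_by_sample) {
    pred_rows <- which(dataset$meta$sample_id %in% pred_units)
  } else {
    pred_rows <- sort(pred_units)
  }
  structure(list(calibration = setdiff(seq_len(n), pred_rows),
                 prediction = sort(pred_rows)),
            class = "split_indices")
}

#' Serialize split indices to JSON
#' @param split a `split_indices`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE)
  invisible(path)
}
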