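#' Construct a Vis-NIR spectra dataset
#'
#' Bundles a reflectance matrix with its wavelength grid and per-spectrum
#' metadata (fertilizer variety, sample id, replicate id, nitrogen and
#' organic-matter concentrations). This is the container every other function
#' in the package consumes.
#'
#' @param reflectance numeric matrix, one row per spectrum, one column per
#'   wavelength channel. Unitless reflectance; values are expected in
#'   `[0, 1.5]` (slightly above 1 is tolerated for white-reference artifacts)
#'   but are not clipped.
#' @param wavelengths strictly increasing numeric vector of channel center
#'   wavelengths in nm; length must equal `ncol(reflectance)`.
#' @param variety integer vector (1-9 in the study design) of variety labels,
#'   one per spectrum.
#' @param sample_id integer vector identifying the physical sample; replicate
#'   spectra of one sample share its id, variety and concentrations.
#' @param replicate_id integer vector (1-3 in the study design).
#' @param nitrogen,organic_matter numeric concentration per spectrum, in the
#'   units of the study's reference chemistry.
#'
#' @return an object of class `spectra_dataset`: a list with elements
#'   `wavelengths`, `reflectance`, and `meta` (a data.frame with columns
#'   `variety`, `sample_id`, `replicate_id`, `nitrogen`, `organic_matter`).
#' @export
spectra_dataset <- function(reflectance, wavelengths, variety, sample_id,
                            replicate_id, nitrogen, organic_matter) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  meta <- data.frame(
    variety = as.integer(variety),
    sample_id = as.integer(sample_id),
    replicate_id = as.integer(replicate_id),
    nitrogen = as.numeric(nitrogen),
    organic_matter = as.numeric(organic_matter)
  )
  out <- structure(
    list(wavelengths = as.numeric(wavelengths),
         reflectance = reflectance,
         meta = meta),
    class = "spectra_dataset"
  )
  validate_spectra_dataset(out)
  out
}

#' Validate a spectra dataset's invariants
#'
#' Checks the structural invariants: matching dimensions, a strictly
#' increasing grid, no missing values, and replicate consistency (all
#' replicates of one `sample_id` share variety and concentrations).
#'
#' @param x a `spectra_dataset`.
#' @return `x` invisibly; an error describing the first violated invariant
#'   otherwise.
#' @export
validate_spectra_dataset <- function(x) {
  stopifnot(inherits(x, "spectra_dataset"))
  wl <- x$wavelengths
  if (length(wl) != ncol(x$reflectance))
    stop("reflectance has ", ncol(x$reflectance), " columns but grid has ",
         length(wl), " wavelengths")
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (nrow(x$meta) != nrow(x$reflectance))
    stop("metadata rows (", nrow(x$meta), ") do not match spectra (",
         nrow(x$reflectance), ")")
  if (anyNA(x$reflectance)) stop("missing values in reflectance")
  if (anyNA(x$meta)) stop("missing values in metadata")
  # replicate consistency: one (variety, N, OM) triple per sample_id
  if (nrow(x$meta) > 0) {
    per_sample <- unique(x$meta[, c("sample_id", "variety", "nitrogen",
                                    "organic_matter")])
    if (anyDuplicated(per_sample$sample_id))
      stop("replicates of one sample_id disagree on variety or concentrations")
  }
  invisible(x)
}

#' @export
print.spectra_dataset <- function(x, ...) {
  wl <- x$wavelengths
  cat("<spectra_dataset> ", nrow(x$reflectance), " spectra x ",
      length(wl), " channels", sep = "")
  if (length(wl)) cat(" (", wl[1], "-", wl[length(wl)], " nm)", sep = "")
  cat("\n")
  if (nrow(x$meta)) {
    cat("  varieties: ", paste(sort(unique(x$meta$variety)), collapse = " "),
        "; samples: ", length(unique(x$meta$sample_id)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$reflectance)

#' Number of spectra in a dataset
#' @param x a `spectra_dataset`.
#' @return integer count of spectra (rows).
#' @export
n_spectra <- function(x) nrow(x$reflectance)

#' Subset a spectra dataset by spectrum (row)
#'
#' @param x a `spectra_dataset`.
#' @param i row index vector (integer or logical).
#' @return a `spectra_dataset` with the selected spectra.
#' @export
subset_spectra <- function(x, i) {
  spectra_dataset(x$reflectance[i, , drop = FALSE], x$wavelengths,
                  x$meta$variety[i], x$meta$sample_id[i],
                  x$meta$replicate_id[i], x$meta$nitrogen[i],
                  x$meta$organic_matter[i])
}

#' Restrict a dataset to the channels of a feature mask
#'
#' A feature mask is a binary 0/1 vector over channels, the interpretation of
#' a binary-PSO particle position: entry j selects wavelength j. The returned
#' dataset keeps only the selected channels (grid restricted accordingly);
#' metadata is unchanged.
#'
#' @param dataset a `spectra_dataset`.
#' @param mask integer/numeric 0/1 vector of length `length(dataset$wavelengths)`
#'   with at least one selected channel.
#' @return a `spectra_dataset` over the selected channels.
#' @export
apply_feature_mask <- function(dataset, mask) {
  mask <- check_feature_mask(mask, length(dataset$wavelengths))
  keep <- mask == 1L
  out <- dataset
  out$wavelengths <- dataset$wavelengths[keep]
  out$reflectance <- dataset$reflectance[, keep, drop = FALSE]
  out
}

# Coerce and validate a 0/1 mask of expected length; requires >= 1 selected.
check_feature_mask <- function(mask, n_channels) {
  mask <- as.integer(round(mask))
  if (length(mask) != n_channels)
    stop("mask length ", length(mask), " does not match channel count ",
         n_channels)
  if (!all(mask %in% c(0L, 1L))) stop("mask entries must be 0 or 1")
  if (sum(mask) < 1L) stop("mask selects no channels")
  mask
}

#' Per-variety mean spectra
#'
#' Arithmetic mean of the reflectance rows of each variety present in the
#' dataset, the quantity plotted as "average spectra of the nine varieties"
#' in Vis-NIR survey figures.
#'
#' @param dataset a `spectra_dataset`.
#' @return numeric matrix, one row per variety present (rownames are the
#'   variety labels), one column per channel.
#' @export
mean_spectrum_by_variety <- function(dataset) {
  vars <- sort(unique(dataset$meta$variety))
  out <- t(vapply(vars, function(v) {
    colMeans(dataset$reflectance[dataset$meta$variety == v, , drop = FALSE])
  }, numeric(length(dataset$wavelengths))))
  rownames(out) <- vars
  colnames(out) <- dataset$wavelengths
  out
}

#' Read a spectra table from CSV
#'
#' Expects the layout written by [write_spectra_csv()]: a header row with the
#' five metadata columns `variety, sample_id, replicate_id, nitrogen,
#' organic_matter` followed by one column per wavelength channel, named by its
#' center wavelength in nm. Wavelength columns are sorted ascending on read.
#'
#' @param path path to a CSV file.
#' @return a validated `spectra_dataset`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("variety", "sample_id", "replicate_id", "nitrogen",
                "organic_matter")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("spectra CSV is missing metadata column(s): ",
         paste(missing, collapse = ", "))
  wl_names <- setdiff(names(df), required)
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl))
    stop("non-numeric wavelength column name(s): ",
         paste(wl_names[is.na(wl)], collapse = ", "))
  ord <- order(wl)
  if (anyDuplicated(wl))
    stop("duplicated wavelength column(s): ",
         paste(unique(wl[duplicated(wl)]), collapse = ", "))
  refl <- as.matrix(df[, wl_names[ord], drop = FALSE])
  if (!is.numeric(refl)) {
    bad <- wl_names[ord][!vapply(df[, wl_names[ord], drop = FALSE],
                                 is.numeric, logical(1))]
    stop("non-numeric reflectance in column(s): ", paste(bad, collapse = ", "))
  }
  for (col in required[4:5])
    if (!is.numeric(df[[col]])) stop("non-numeric values in column: ", col)
  spectra_dataset(refl, wl[ord], df$variety, df$sample_id, df$replicate_id,
                  df$nitrogen, df$organic_matter)
}

#' Write a spectra dataset to CSV
#'
#' Inverse of [read_spectra_csv()]; values are written at full double
#' precision (15 significant digits) so a read/write round trip is the
#' identity to machine precision.
#'
#' @param dataset a `spectra_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(dataset, path) {
  validate_spectra_dataset(dataset)
  df <- cbind(dataset$meta,
              as.data.frame(dataset$reflectance))
  names(df) <- c(names(dataset$meta), format(dataset$wavelengths, trim = TRUE,
                                             digits = 15, scientific = FALSE))
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
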