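#' Concentration statistics of the nine fertilizer varieties
#'
#' The published per-variety summary statistics (min, max, mean, SD) of the
#' reference-chemistry nitrogen and organic-matter concentrations, the
#' constants that parameterize the synthetic concentration sampler. Several
#' rows are internally inconsistent as printed (e.g. variety 1 OM: the SD
#' exceeds half the min-max range; variety 8 resembles a mixture); they are
#' reproduced verbatim, and the sampler uses only mean and SD.
#'
#' @return data.frame with columns `property` ("N"/"OM"), `variety` (1-9),
#'   `min`, `max`, `mean`, `sd`.
#' @export
table1_stats <- function() {
  rbind(
    data.frame(property = "N", variety = 1:9,
               min = c(1.460, 2.030, 1.540, 1.220, 2.110, 1.350, 2.220,
                       1.220, 5.190),
               max = c(1.480, 2.070, 1.560, 1.260, 2.160, 1.360, 2.240,
                       5.330, 5.330),
               mean = c(1.470, 2.047, 1.550, 1.237, 2.140, 1.353, 2.230,
                        2.107, 5.250),
               sd = c(0.010, 0.020, 0.010, 0.020, 0.026, 0.005, 0.010,
                      1.117, 0.072)),
    data.frame(property = "OM", variety = 1:9,
               min = c(55.97, 40.23, 40.56, 58.15, 57.11, 47.12, 54.12,
                       40.23, 45.65),
               max = c(56.12, 40.34, 40.98, 58.22, 57.46, 47.29, 54.33,
                       58.22, 45.98),
               mean = c(56.02, 40.30, 40.78, 58.19, 57.29, 47.22, 54.25,
                        50.21, 45.78),
               sd = c(0.083, 0.058, 0.210, 0.035, 0.175, 0.090, 0.111,
                      6.348, 0.175))
  )
}

#' Draw synthetic concentrations for one variety
#'
#' I.i.d. Normal(mean, SD) draws per property, parameterized from
#' [table1_stats()], without min/max truncation (the printed min/max bounds
#' are inconsistent with the SDs for several varieties, so no bounded
#' distribution can honor all four statistics; the sampler matches mean and
#' SD exactly in expectation).
#'
#' @param stats data.frame from [table1_stats()] (or a same-shaped override).
#' @param variety variety label 1-9.
#' @param n number of samples to draw.
#' @param seed integer seed; draws are deterministic given it.
#' @return list with numeric vectors `nitrogen` and `organic_matter` of
#'   length `n`.
#' @export
sample_concentrations <- function(stats, variety, n, seed = 1L) {
  stopifnot(n >= 1L)
  rn <- stats[stats$property == "N" & stats$variety == variety, ]
  ro <- stats[stats$property == "OM" & stats$variety == variety, ]
  if (nrow(rn) != 1L || nrow(ro) != 1L)
    stop("no statistics for variety ", variety)
  set.seed(as.integer(seed))
  list(nitrogen = stats::rnorm(n, rn$mean, rn$sd),
       organic_matter = stats::rnorm(n, ro$mean, ro$sd))
}

#' Synthetic-generator configuration
#'
#' The study design the generator emulates. The `"study"` preset is the full
#' design: 9 varieties x 30 samples x 3 replicate spectra on the canonical
#' 2151-channel grid (integer nm, 350-2500). The `"reduced"` preset is a
#' small benchmark for selector/optimizer tests: 64 channels, 8 of them
#' informative, 9 varieties x 10 samples x 1 replicate.
#'
#' @param preset `"study"` or `"reduced"`.
#' @param noise_sd per-channel Gaussian noise SD in reflectance units
#'   (default 0.005 study / 0.02 reduced).
#' @param baseline_shift_sd SD of the per-spectrum additive baseline shift
#'   emulating loading-density/particle-size disparity (default 0.02 study /
#'   0.005 reduced).
#' @param samples_per_variety,replicates override the preset's counts.
#' @param seed integer seed for [generate_dataset()].
#' @return object of class `generator_config`: list with `preset`,
#'   `wavelengths`, `n_varieties`, `samples_per_variety`, `replicates`,
#'   `noise_sd`, `baseline_shift_sd`, `informative_ranges` (2-column matrix
#'   of nm intervals), `seed`.
#' @export
generator_config <- function(preset = c("study", "reduced"),
                             noise_sd = NULL, baseline_shift_sd = NULL,
                             samples_per_variety = NULL, replicates = NULL,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "study") {
    wl <- 350:2500
    cfg <- list(preset = preset, wavelengths = wl, n_varieties = 9L,
                samples_per_variety = samples_per_variety %||% 30L,
                replicates = replicates %||% 3L,
                noise_sd = noise_sd %||% 0.005,
                baseline_shift_sd = baseline_shift_sd %||% 0.02,
                informative_ranges = cbind(lo = c(400, 900, 1400, 1800),
                                           hi = c(600, 1000, 1600, 2300)),
                seed = as.integer(seed))
  } else {
    wl <- round(seq(350, 2500, length.out = 64))
    inf_idx <- c(8L, 15L, 22L, 29L, 36L, 43L, 50L, 57L)
    cfg <- list(preset = preset, wavelengths = wl, n_varieties = 9L,
                samples_per_variety = samples_per_variety %||% 10L,
                replicates = replicates %||% 1L,
                noise_sd = noise_sd %||% 0.02,
                baseline_shift_sd = baseline_shift_sd %||% 0.005,
                informative_ranges = cbind(lo = wl[inf_idx] - 31,
                                           hi = wl[inf_idx] + 31),
                seed = as.integer(seed))
  }
  structure(cfg, class = "generator_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-variety spectral profiles
#'
#' Deterministic construction of the nine variety profiles: a smooth
#' low-order polynomial baseline plus Gaussian absorption bands, each band a
#' row `(center, width, depth, a_N, b_OM)` where the effective band depth is
#' `depth + a_N * N + b_OM * OM` (positive coefficients deepen the band, i.e.
#' lower reflectance, as concentration rises). Band placement follows the
#' study's qualitative description:
#' all varieties absorb inside 1887-2200 nm (nitrogen-coupled); varieties
#' 1, 3, 8, 9 carry an extra peak inside 1388-1549 nm; variety 9 additionally
#' carries marker bands at 844, 1733 and 2310 nm (uncoupled). Nitrogen
#' couplings sit inside 400-600 and 1800-2300 nm, organic-matter couplings
#' inside 1400-1600 nm; all couplings are zero outside
#' `config$informative_ranges` (validated at construction).
#'
#' @param config a `generator_config`.
#' @return list of 9 profiles, each a list with `baseline` (numeric vector
#'   over the grid) and `bands` (numeric matrix with columns
#'   `center, width, depth, a_N, b_OM`).
#' @export
build_variety_profiles <- function(config) {
  wl <- config$wavelengths
  u <- (wl - min(wl)) / diff(range(wl))
  band <- function(center, width, depth, a_N = 0, b_OM = 0)
    c(center = center, width = width, depth = depth, a_N = a_N, b_OM = b_OM)

  profiles <- lapply(seq_len(config$n_varieties), function(v) {
    if (config$preset == "study") {
      baseline <- 0.30 + 0.015 * ((2 * v) %% 7) + 0.25 * u - 0.12 * u^2
      bands <- list(
        # shared absorption complex, 1887-2200 nm, nitrogen-coupled
        band(2050, 55, 0.05 + 0.006 * (v %% 4), a_N = 0.020),
        band(1930, 35, 0.04 + 0.004 * ((v + 1) %% 3), a_N = 0.014),
        # visible range, nitrogen-coupled
        band(500, 30, 0.03 + 0.005 * ((3 * v) %% 5), a_N = 0.012),
        # 900-1000 nm structure (uncoupled; overtone region)
        band(950, 25, 0.02 + 0.006 * (v %% 3)),
        # organic-matter coupling, 1400-1600 nm, all varieties
        band(1500, 28, 0.02, b_OM = 0.0020)
      )
      if (v %in% c(1, 3, 8, 9))
        bands <- c(bands, list(band(1480, 25, 0.06 + 0.01 * (v %% 2),
                                    b_OM = 0.0012)))
      if (v == 9)
        bands <- c(bands, list(band(844, 20, 0.07), band(1733, 20, 0.06),
                               band(2310, 20, 0.06)))
    } else {
      baseline <- rep(0.55, length(wl)) + 0.05 * u
      centers <- rowMeans(config$informative_ranges)
      # one marker bit per variety: variety v > 1 deepens only channel v - 1,
      # so channel k is the sole separator of the pair {1, k + 1} and every
      # informative channel is individually necessary for full accuracy
      bands <- lapply(seq_along(centers), function(k) {
        depth <- 0.10 + 0.18 * as.numeric(v == k + 1L)
        a_N <- if (k %% 2L == 1L) 0.015 else 0
        b_OM <- if (k %% 2L == 0L) 0.0015 else 0
        band(centers[k], 10, depth, a_N = a_N, b_OM = b_OM)
      })
    }
    bands <- do.call(rbind, bands)
    if (any(bands[, "center"] < min(wl) | bands[, "center"] > max(wl)))
      stop("band center outside the wavelength grid")
    # coupled bands must keep their support (at the 1% level) inside the
    # informative ranges, so the ground-truth mask is consistent
    coupled <- bands[, "a_N"] != 0 | bands[, "b_OM"] != 0
    if (any(coupled)) {
      half <- bands[coupled, "width"] * sqrt(-2 * log(0.01))
      lo <- bands[coupled, "center"] - half
      hi <- bands[coupled, "center"] + half
      ok <- vapply(seq_along(lo), function(i)
        any(lo[i] >= config$informative_ranges[, "lo"] &
            hi[i] <= config$informative_ranges[, "hi"]), logical(1))
      if (!all(ok))
        stop("coupled band support leaks outside the informative ranges")
    }
    list(variety = v, baseline = baseline, bands = bands)
  })
  profiles
}

#' Generate one synthetic reflectance spectrum
#'
#' Beer-Lambert-style additive model: the variety baseline, minus each
#' Gaussian band scaled by its concentration-dependent depth, plus a
#' per-spectrum constant baseline shift `Normal(0, baseline_shift_sd)` and
#' per-channel noise `Normal(0, noise_sd)`; the result is clipped to
#' `(0.001, 1.2)`.
#'
#' @param profile one element of [build_variety_profiles()].
#' @param wavelengths the grid the profile was built on.
#' @param nitrogen,organic_matter concentrations of the sample.
#' @param noise_sd,baseline_shift_sd noise levels (0 for a deterministic
#'   spectrum).
#' @return numeric reflectance vector over the grid. Uses the session RNG.
#' @export
generate_spectrum <- function(profile, wavelengths, nitrogen, organic_matter,
                              noise_sd = 0, baseline_shift_sd = 0) {
  r <- profile$baseline
  b <- profile$bands
  for (k in seq_len(nrow(b))) {
    depth <- b[k, "depth"] + b[k, "a_N"] * nitrogen +
      b[k, "b_OM"] * organic_matter
    r <- r - depth * exp(-0.5 * ((wavelengths - b[k, "center"]) /
                                   b[k, "width"])^2)
  }
  if (baseline_shift_sd > 0) r <- r + stats::rnorm(1, 0, baseline_shift_sd)
  if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
  pmin(pmax(r, 0.001), 1.2)
}

#' Generate a full synthetic study dataset
#'
#' Draws per-sample concentrations from the published per-variety statistics
#' and emits `replicates` spectra per sample — replicates share the sample's
#' concentrations but have independent baseline shift and noise. The
#' `"study"` preset yields 810 spectra over 270 samples on 2151 channels.
#'
#' @param config a `generator_config`.
#' @return list with `dataset` (a `spectra_dataset`), `truth` (0/1
#'   ground-truth informative-channel mask from [ground_truth_mask()]) and
#'   `profiles`.
#' @export
generate_dataset <- function(config) {
  profiles <- build_variety_profiles(config)
  wl <- config$wavelengths
  n_per <- config$samples_per_variety
  reps <- config$replicates
  stats <- table1_stats()
  rows <- config$n_varieties * n_per * reps
  refl <- matrix(NA_real_, rows, length(wl))
  meta <- data.frame(variety = integer(rows), sample_id = integer(rows),
                     replicate_id = integer(rows), nitrogen = numeric(rows),
                     organic_matter = numeric(rows))
  i <- 0L
  for (v in seq_len(config$n_varieties)) {
    conc <- sample_concentrations(stats, v, n_per,
                                  seed = derive_seed(config$seed, v))
    set.seed(derive_seed(config$seed, 1000L + v))
    for (s in seq_len(n_per)) {
      sid <- (v - 1L) * n_per + s
      for (r in seq_len(reps)) {
        i <- i + 1L
        refl[i, ] <- generate_spectrum(profiles[[v]], wl,
                                       conc$nitrogen[s],
                                       conc$organic_matter[s],
                                       noise_sd = config$noise_sd,
                                       baseline_shift_sd =
                                         config$baseline_shift_sd)
        meta$variety[i] <- v
        meta$sample_id[i] <- sid
        meta$replicate_id[i] <- r
        meta$nitrogen[i] <- conc$nitrogen[s]
        meta$organic_matter[i] <- conc$organic_matter[s]
      }
    }
  }
  ds <- spectra_dataset(refl, wl, meta$variety, meta$sample_id,
                        meta$replicate_id, meta$nitrogen, meta$organic_matter)
  list(dataset = ds, truth = ground_truth_mask(profiles, wl),
       profiles = profiles)
}

#' Ground-truth informative-channel mask
#'
#' Channels where any variety's concentration coupling carries weight: bit j
#' is 1 when `|coupling| * GaussianWeight_j` exceeds `threshold` times its
#' peak value for at least one coupled band of one variety. The oracle
#' selector-recovery tests score masks against this.
#'
#' @param profiles from [build_variety_profiles()].
#' @param wavelengths the grid.
#' @param threshold fraction of the peak coupling weight (default 0.01).
#' @return 0/1 integer mask over the grid.
#' @export
ground_truth_mask <- function(profiles, wavelengths, threshold = 0.01) {
  mask <- rep(0L, length(wavelengths))
  for (p in profiles) {
    b <- p$bands
    for (k in seq_len(nrow(b))) {
      coupling <- abs(b[k, "a_N"]) + abs(b[k, "b_OM"])
      if (coupling == 0) next
      w <- exp(-0.5 * ((wavelengths - b[k, "center"]) / b[k, "width"])^2)
      mask[w > threshold] <- 1L
    }
  }
  mask
}
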