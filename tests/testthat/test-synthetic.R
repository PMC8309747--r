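test_that("published concentration statistics are reproduced verbatim", {
  st <- table1_stats()
  expect_equal(nrow(st), 18L)
  expect_equal(st$mean[st$property == "N" & st$variety == 9], 5.250)
  expect_equal(st$mean[st$property == "OM" & st$variety == 1], 56.02)
  expect_equal(st$sd[st$property == "N" & st$variety == 6], 0.005)
  expect_equal(st$mean[st$property == "N"],
               c(1.470, 2.047, 1.550, 1.237, 2.140, 1.353, 2.230, 2.107,
                 5.250))
  # min <= mean <= max everywhere as printed
  expect_true(all(st$min <= st$mean & st$mean <= st$max))
})

test_that("concentration sampler is seeded and matches the target moments", {
  st <- table1_stats()
  a <- sample_concentrations(st, 4, 50, seed = 9)
  b <- sample_concentrations(st, 4, 50, seed = 9)
  expect_identical(a, b)
  expect_length(a$nitrogen, 50L)

  # CLT bound at n = 1e4: |mean - mu| < 4 * sd / sqrt(n)
  big <- sample_concentrations(st, 9, 1e4, seed = 1)
  expect_lt(abs(mean(big$nitrogen) - 5.250), 4 * 0.072 / 100)
  expect_lt(abs(mean(big$organic_matter) - 45.78), 4 * 0.175 / 100)
  expect_equal(sd(big$nitrogen), 0.072, tolerance = 0.05)

  # degenerate SD = 0 collapses to the mean
  st0 <- st
  st0$sd[st0$property == "N" & st0$variety == 1] <- 0
  z <- sample_concentrations(st0, 1, 10, seed = 2)
  expect_equal(z$nitrogen, rep(1.470, 10))

  expect_error(sample_concentrations(st, 12, 5), "variety 12")
})

test_that("variety profiles encode the study's band placement rules", {
  cfg <- generator_config("study")
  profs <- build_variety_profiles(cfg)
  expect_length(profs, 9L)

  centers <- function(p) p$bands[, "center"]
  # every variety absorbs inside 1887-2200 nm
  for (p in profs)
    expect_true(any(centers(p) >= 1887 & centers(p) <= 2200))
  # the 1388-1549 nm peak appears for varieties 1, 3, 8, 9 only
  has_peak <- vapply(profs, function(p)
    any(centers(p) >= 1388 & centers(p) <= 1549 & p$bands[, "depth"] > 0.05),
    logical(1))
  expect_equal(which(has_peak), c(1L, 3L, 8L, 9L))
  # variety 9's marker bands
  expect_true(all(c(844, 1733, 2310) %in% centers(profs[[9]])))
  expect_false(any(c(844, 1733, 2310) %in% centers(profs[[2]])))
  # variety 2 carries only the weak shared organic-matter band between the
  # visible structure and the 1887 nm complex - no discriminative peak
  mid <- profs[[2]]$bands[, "center"] >= 1300 &
    profs[[2]]$bands[, "center"] < 1887
  expect_true(all(profs[[2]]$bands[mid, "depth"] <= 0.02))

  # couplings confined to the informative ranges (construction contract)
  truth <- ground_truth_mask(profs, cfg$wavelengths)
  wl_sel <- cfg$wavelengths[truth == 1]
  in_range <- vapply(wl_sel, function(w)
    any(w >= cfg$informative_ranges[, "lo"] &
        w <= cfg$informative_ranges[, "hi"]), logical(1))
  expect_true(all(in_range))
  expect_gt(sum(truth), 0L)
})

test_that("ground-truth mask thresholds are monotone", {
  cfg <- generator_config("study")
  profs <- build_variety_profiles(cfg)
  m1 <- ground_truth_mask(profs, cfg$wavelengths, threshold = 0.01)
  m0 <- ground_truth_mask(profs, cfg$wavelengths, threshold = 1e-6)
  expect_true(all(m0[m1 == 1L] == 1L))  # lower threshold -> superset
  # zero couplings -> empty mask is permitted for this oracle
  flat <- list(list(variety = 1,
                    baseline = rep(0.5, 10),
                    bands = matrix(c(5, 1, 0.1, 0, 0), 1,
                                   dimnames = list(NULL,
                                     c("center", "width", "depth",
                                       "a_N", "b_OM")))))
  expect_equal(sum(ground_truth_mask(flat, 1:10)), 0L)
})

test_that("noise-free spectra are deterministic and deepen with nitrogen", {
  cfg <- generator_config("study")
  profs <- build_variety_profiles(cfg)
  p <- profs[[5]]
  s1 <- generate_spectrum(p, cfg$wavelengths, 2.0, 50)
  s2 <- generate_spectrum(p, cfg$wavelengths, 2.0, 50)
  expect_identical(s1, s2)
  expect_length(s1, 2151L)
  expect_true(all(s1 > 0 & s1 <= 1.2))

  # finite difference in N lowers reflectance at every N-coupled band center
  s_hi <- generate_spectrum(p, cfg$wavelengths, 3.0, 50)
  coupled <- p$bands[p$bands[, "a_N"] > 0, , drop = FALSE]
  for (k in seq_len(nrow(coupled))) {
    j <- which.min(abs(cfg$wavelengths - coupled[k, "center"]))
    expect_lt(s_hi[j], s1[j])
  }
  # organic matter likewise for OM-coupled bands
  s_om <- generate_spectrum(p, cfg$wavelengths, 2.0, 55)
  omc <- p$bands[p$bands[, "b_OM"] > 0, , drop = FALSE]
  j <- which.min(abs(cfg$wavelengths - omc[1, "center"]))
  expect_lt(s_om[j], s1[j])
})

test_that("linear regression at band centers recovers the couplings", {
  # noise off: reflectance at an N-coupled center is baseline - depth -
  # a_N * N - b_OM * OM (+ tiny overlap from neighboring bands), so an
  # within-variety least-squares fit on (N, OM) recovers the coefficients
  cfg <- generator_config("study", noise_sd = 0, baseline_shift_sd = 0)
  profs <- build_variety_profiles(cfg)
  p <- profs[[2]]
  st <- table1_stats()
  conc <- sample_concentrations(st, 2, 40, seed = 5)
  spectra <- t(vapply(seq_len(40), function(i)
    generate_spectrum(p, cfg$wavelengths, conc$nitrogen[i],
                      conc$organic_matter[i]),
    numeric(length(cfg$wavelengths))))
  band <- p$bands[which(p$bands[, "a_N"] > 0)[1], ]
  j <- which.min(abs(cfg$wavelengths - band["center"]))
  fit <- lm(spectra[, j] ~ conc$nitrogen + conc$organic_matter)
  expect_equal(unname(coef(fit)[2]), -band[["a_N"]],
               tolerance = 0.01)
})

test_that("the study-design dataset has the study's counts and structure", {
  gen <- generate_dataset(generator_config("study", seed = 2))
  ds <- gen$dataset
  expect_equal(nrow(ds$reflectance), 810L)
  expect_equal(length(unique(ds$meta$sample_id)), 270L)
  expect_equal(length(ds$wavelengths), 2151L)
  expect_equal(range(ds$wavelengths), c(350, 2500))
  expect_equal(unname(table(ds$meta$variety)), rep(90L, 9L),
               ignore_attr = TRUE)
  # replicates share concentrations (validated by the constructor, asserted
  # here explicitly for one sample)
  rows <- which(ds$meta$sample_id == ds$meta$sample_id[1])
  expect_length(rows, 3L)
  expect_length(unique(ds$meta$nitrogen[rows]), 1L)

  # bit-reproducible given the seed
  gen2 <- generate_dataset(generator_config("study", seed = 2))
  expect_identical(gen$dataset$reflectance, gen2$dataset$reflectance)
  # truth mask is confined to the informative ranges
  expect_equal(sum(gen$truth), sum(gen2$truth))
})

test_that("the reduced benchmark is small, separable and has 8 informative channels", {
  gen <- reduced_benchmark()
  expect_equal(dim(gen$dataset), c(90L, 64L))
  expect_equal(sum(gen$truth), 8L)
  acc <- subset_fitness(gen$truth, gen$dataset, default_model_specs()$knn,
                        alpha = 1, folds = 3L, seed = 1)
  expect_gte(acc, 0.9)
})
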