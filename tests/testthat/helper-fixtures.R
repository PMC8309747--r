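# Fixtures built in code; nothing is read from disk.

# Tiny deterministic dataset: n spectra on a D-channel grid, metadata cycling
# over `k` varieties, one replicate per sample.
toy_dataset <- function(n = 6L, D = 4L, k = 3L, seed = 42L) {
  set.seed(seed)
  refl <- matrix(runif(n * D, 0.2, 0.8), n, D)
  spectra_dataset(refl, seq(400, by = 50, length.out = D),
                  variety = rep_len(seq_len(k), n),
                  sample_id = seq_len(n),
                  replicate_id = rep(1L, n),
                  nitrogen = seq(1, 2, length.out = n),
                  organic_matter = seq(40, 60, length.out = n))
}

# Two well-separated Gaussian classes in `D` dimensions.
toy_blobs <- function(n_per = 20L, D = 2L, sep = 6, seed = 7L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * D), n_per, D),
             matrix(rnorm(n_per * D, mean = sep), n_per, D))
  list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
}

# Reduced-preset benchmark shared by the optimizer tests (memoised: the
# generator is deterministic, so one instance per session suffices).
reduced_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(generator_config("reduced",
                                                                    seed = 3L))
    cache
  }
})

# The D = 8 optimizer benchmark: reduced preset restricted to its 8
# informative channels, with a cheap ridge-classifier wrapper fitness.
d8_benchmark <- function() {
  gen <- reduced_benchmark()
  ds8 <- apply_feature_mask(gen$dataset, gen$truth)
  ridge <- default_model_specs()$ridge
  fitness <- make_subset_fitness(ridge, alpha = 0.5, folds = 3L, seed = 1L)
  list(dataset = ds8, fitness = fitness)
}
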