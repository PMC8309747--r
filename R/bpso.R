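#' Binary-PSO configuration
#'
#' Settings of the binary particle swarm used for wavelength selection. The
#' swarm size (50), iteration count (10) and fitness trade-off weight
#' `alpha = 0.5` are the values tuned in the original study; the kinematic
#' constants (`w`, `c1`, `c2`, `dt`, `v_max`) are standard binary-PSO
#' settings, all configurable.
#'
#' @param n_particles swarm size (>= 2). Default 50.
#' @param n_iterations iterations (>= 1). Default 10.
#' @param w inertia weight on the previous velocity. Default 0.9.
#' @param c1,c2 cognitive and social acceleration constants. Default 2.
#' @param dt time step of one iteration. Default 1.
#' @param alpha fitness trade-off weight in `[0, 1]` between classifier
#'   accuracy and subset compactness. Default 0.5.
#' @param v_max velocity clamp; also the saturation level of the
#'   premature-convergence test. Default 6.
#' @param reset_enabled apply the reset-swarm escape on premature
#'   convergence. Default TRUE.
#' @param seed integer seed; every random draw of the run descends from it.
#' @param fitness_folds CV folds used by the subset fitness. Default 5.
#' @param per_coordinate_qr draw the uniform numbers q, r of the velocity
#'   update per coordinate instead of once per particle. Default FALSE.
#' @param paper_literal_sigmoid use the decreasing transfer function
#'   `1/(1+e^v)` exactly as printed in the original study instead of the
#'   standard increasing logistic (see [bpso_sigmoid()]). Default FALSE.
#' @return an object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 50L, n_iterations = 10L, w = 0.9,
                       c1 = 2, c2 = 2, dt = 1, alpha = 0.5, v_max = 6,
                       reset_enabled = TRUE, seed = 1L, fitness_folds = 5L,
                       per_coordinate_qr = FALSE,
                       paper_literal_sigmoid = FALSE) {
  stopifnot(n_particles >= 2L, n_iterations >= 1L,
            alpha >= 0, alpha <= 1, v_max > 0, dt > 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 w = w, c1 = c1, c2 = c2, dt = dt, alpha = alpha,
                 v_max = v_max, reset_enabled = isTRUE(reset_enabled),
                 seed = as.integer(seed),
                 fitness_folds = as.integer(fitness_folds),
                 per_coordinate_qr = isTRUE(per_coordinate_qr),
                 paper_literal_sigmoid = isTRUE(paper_literal_sigmoid)),
            class = "pso_config")
}

#' Transfer (sigmoid) function of the velocity
#'
#' Maps a velocity to the probability that the corresponding position bit is
#' set. The default is the standard increasing logistic `S(v) = 1/(1+e^-v)`,
#' under which a large positive velocity drives a bit toward 1. The original study
#' study prints the decreasing form `1/(1+e^v)`; because that sign makes high
#' velocity suppress selection — inconsistent with the cited binary-PSO
#' convention — the printed form is kept behind `paper_literal = TRUE` only.
#' Overflow-safe for `|v| > 700`.
#'
#' @param v numeric velocity (vectorized).
#' @param paper_literal use the printed decreasing form. Default FALSE.
#' @return values in `(0, 1)`; `S(0) = 0.5` and `S(v) + S(-v) = 1` under
#'   either convention.
#' @export
bpso_sigmoid <- function(v, paper_literal = FALSE) {
  if (paper_literal) v <- -v
  ifelse(v >= 0, 1 / (1 + exp(-pmin(v, 700))),
         exp(pmax(v, -700)) / (1 + exp(pmax(v, -700))))
}

#' Wrapper subset fitness: accuracy traded against subset size
#'
#' The objective maximized by the PSO: `J = alpha * P + (1 - alpha) *
#' (1 - N_f / N_t)` where `P` is the cross-validated variety-classification
#' accuracy of the supplied model on the masked channels, `N_f` the number of
#' selected channels and `N_t` the total channel count. At `alpha = 1` the
#' fitness is pure accuracy; at `alpha = 0` it only rewards compactness.
#' An all-zero mask is defined-invalid and scores `-Inf`, so it can never
#' become a personal or global best.
#'
#' @param mask 0/1 channel mask.
#' @param dataset a `spectra_dataset` (variety labels are the classes).
#' @param model a classifier `stack_spec` (the FSGC) or a single classifier
#'   `model_spec` (e.g. the lone SVM of the PSO-SVM baseline).
#' @param alpha trade-off weight in `[0, 1]` (default 0.5).
#' @param folds CV folds for the accuracy term (default 5).
#' @param seed integer seed for the CV fold assignment.
#' @return numeric fitness, larger is better.
#' @export
subset_fitness <- function(mask, dataset, model, alpha = 0.5, folds = 5L,
                           seed = 1L) {
  if (sum(mask) < 1L) return(-Inf)
  mask <- check_feature_mask(mask, length(dataset$wavelengths))
  n_t <- length(mask)
  size_term <- 1 - sum(mask) / n_t
  if (alpha == 0) return(size_term)   # accuracy term has zero weight
  X <- dataset$reflectance[, mask == 1L, drop = FALSE]
  y <- dataset$meta$variety
  P <- if (inherits(model, "stack_spec")) {
    cv_accuracy(model, X, y, folds = folds, seed = seed)
  } else {
    cv_model_accuracy(model, X, y, folds = folds, seed = seed)
  }
  alpha * P + (1 - alpha) * size_term
}

# Plain k-fold CV accuracy of a single classifier spec.
cv_model_accuracy <- function(spec, X, y, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  fold <- make_folds(nrow(X), folds, y = y, seed = derive_seed(seed, 2L))
  mean(vapply(seq_len(folds), function(f) {
    tr <- fold != f
    m <- fit_base_model(spec, X[tr, , drop = FALSE], droplevels(y[tr]),
                        seed = derive_seed(seed, 50L + f))
    mean(as.character(predict_base_model(m, X[!tr, , drop = FALSE])) ==
           as.character(y[!tr]))
  }, numeric(1)))
}

#' Build a fitness closure for [run_pso()]
#'
#' Convenience wrapper binding a classifier (stack or single model), the
#' trade-off weight and the CV settings into the `(mask, dataset)` closure
#' [run_pso()] expects. With `aggregate_replicates = TRUE` the fitness is
#' evaluated on the per-sample mean spectrum (replicates averaged), which
#' both removes replicate leakage across CV folds and cuts the wrapper's
#' dominant cost.
#'
#' @param model classifier `stack_spec` or `model_spec`.
#' @param alpha trade-off weight (default 0.5).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @param aggregate_replicates average replicate spectra per sample before
#'   the accuracy CV. Default FALSE.
#' @return function `(mask, dataset) -> fitness`.
#' @export
make_subset_fitness <- function(model, alpha = 0.5, folds = 5L, seed = 1L,
                                aggregate_replicates = FALSE) {
  force(model); force(alpha); force(folds); force(seed)
  agg_cache <- new.env(parent = emptyenv())
  function(mask, dataset) {
    if (aggregate_replicates) {
      key <- "agg"
      if (is.null(agg_cache[[key]]))
        agg_cache[[key]] <- aggregate_replicate_spectra(dataset)
      dataset <- agg_cache[[key]]
    }
    subset_fitness(mask, dataset, model, alpha = alpha, folds = folds,
                   seed = seed)
  }
}

#' Average replicate spectra within each sample
#'
#' Collapses the dataset to one mean spectrum per physical sample (metadata
#' taken from the first replicate, `replicate_id` set to 1).
#'
#' @param dataset a `spectra_dataset`.
#' @return a `spectra_dataset` with one row per `sample_id`.
#' @export
aggregate_replicate_spectra <- function(dataset) {
  ids <- unique(dataset$meta$sample_id)
  idx <- match(ids, dataset$meta$sample_id)
  refl <- t(vapply(ids, function(s) {
    colMeans(dataset$reflectance[dataset$meta$sample_id == s, , drop = FALSE])
  }, numeric(length(dataset$wavelengths))))
  spectra_dataset(refl, dataset$wavelengths, dataset$meta$variety[idx], ids,
                  rep(1L, length(ids)), dataset$meta$nitrogen[idx],
                  dataset$meta$organic_matter[idx])
}

#' Initialize a swarm
#'
#' Positions are i.i.d. Bernoulli(0.5) bits (any all-zero position is
#' re-drawn, then repaired deterministically); velocities are
#' Uniform(-v_max, v_max). Personal/global best slots start at `-Inf`
#' fitness; [run_pso()] fills them with the first evaluation. Uses the
#' session RNG, seeded from `config$seed`.
#'
#' @param config a `pso_config`.
#' @param D number of channels (bits) per particle.
#' @param seed_rng seed the session RNG from `config$seed` first (default
#'   TRUE; [run_pso()] passes FALSE to keep one RNG stream for the whole
#'   run).
#' @return an object of class `pso_swarm`: list with matrices `pos`, `vel`,
#'   `pb_pos` (`n_particles x D`), vectors `pb_fit`, `gb_pos`, scalar
#'   `gb_fit`, and `iteration`.
#' @export
init_swarm <- function(config, D, seed_rng = TRUE) {
  stopifnot(D >= 1L)
  if (seed_rng) set.seed(config$seed)
  P <- config$n_particles
  pos <- matrix(stats::rbinom(P * D, 1L, 0.5), P, D)
  for (i in seq_len(P)) {
    if (sum(pos[i, ]) == 0L) pos[i, ] <- stats::rbinom(D, 1L, 0.5)
    if (sum(pos[i, ]) == 0L) pos[i, sample.int(D, 1L)] <- 1L
  }
  vel <- matrix(stats::runif(P * D, -config$v_max, config$v_max), P, D)
  structure(list(pos = pos, vel = vel,
                 pb_pos = pos, pb_fit = rep(-Inf, P),
                 gb_pos = pos[1L, ], gb_fit = -Inf,
                 iteration = 0L),
            class = "pso_swarm")
}

#' Update personal bests (strict improvement)
#'
#' A particle's personal best is replaced only when the fitness of its
#' current position is strictly greater than its personal-best fitness;
#' equal fitness keeps the incumbent.
#'
#' @param swarm a `pso_swarm`.
#' @param fitness numeric vector of fitness values at the current positions.
#' @return the updated swarm.
#' @export
update_personal_best <- function(swarm, fitness) {
  better <- fitness > swarm$pb_fit
  swarm$pb_pos[better, ] <- swarm$pos[better, , drop = FALSE]
  swarm$pb_fit[better] <- fitness[better]
  swarm
}

#' Update the global best (strict improvement, incumbent keeps ties)
#'
#' Sets the swarm best to the best personal best if it strictly exceeds the
#' incumbent's fitness, so the global-best fitness trajectory is
#' non-decreasing.
#'
#' @param swarm a `pso_swarm`.
#' @return the updated swarm.
#' @export
update_global_best <- function(swarm) {
  i <- which.max(swarm$pb_fit)
  if (swarm$pb_fit[i] > swarm$gb_fit) {
    swarm$gb_fit <- swarm$pb_fit[i]
    swarm$gb_pos <- swarm$pb_pos[i, ]
  }
  swarm
}

#' Velocity update
#'
#' `v <- w*v + c1*q*(x_pb - x)/dt + c2*r*(x_sb - x)/dt`, with `q, r ~
#' Uniform[0,1]` drawn fresh per particle per iteration (scalars by default;
#' per coordinate with `config$per_coordinate_qr`), then clamped to
#' `[-v_max, v_max]`.
#'
#' @param swarm a `pso_swarm` with current personal/global bests.
#' @param config a `pso_config`.
#' @return the swarm with updated velocities.
#' @export
update_velocity <- function(swarm, config) {
  P <- nrow(swarm$pos); D <- ncol(swarm$pos)
  if (config$per_coordinate_qr) {
    q <- matrix(stats::runif(P * D), P, D)
    r <- matrix(stats::runif(P * D), P, D)
  } else {
    q <- stats::runif(P)
    r <- stats::runif(P)
  }
  gb <- matrix(swarm$gb_pos, P, D, byrow = TRUE)
  v <- config$w * swarm$vel +
    config$c1 * q * (swarm$pb_pos - swarm$pos) / config$dt +
    config$c2 * r * (gb - swarm$pos) / config$dt
  swarm$vel <- pmin(pmax(v, -config$v_max), config$v_max)
  swarm
}

#' Position update through the velocity transfer function
#'
#' Each bit is set to 1 with probability `S(v)` (fresh uniform draw per
#' coordinate): `x <- 1 if r <= S(v), else 0`. An all-zero result is re-drawn
#' once; if still empty, the coordinate with the largest `S(v)` is forced to
#' 1, so every particle always encodes a non-empty wavelength subset.
#'
#' @param swarm a `pso_swarm` with velocities already updated.
#' @param config a `pso_config`.
#' @return the swarm with updated binary positions.
#' @export
update_position <- function(swarm, config) {
  P <- nrow(swarm$pos); D <- ncol(swarm$pos)
  S <- bpso_sigmoid(swarm$vel, paper_literal = config$paper_literal_sigmoid)
  r <- matrix(stats::runif(P * D), P, D)
  pos <- (r <= S) * 1L
  for (i in seq_len(P)) {
    if (sum(pos[i, ]) == 0L)
      pos[i, ] <- (stats::runif(D) <= S[i, ]) * 1L
    if (sum(pos[i, ]) == 0L)
      pos[i, which.max(S[i, ])] <- 1L
  }
  swarm$pos <- pos
  swarm
}

#' Detect premature convergence
#'
#' TRUE when the velocities have saturated (`max |v| >= v_max`) while the
#' swarm has collapsed in position space (mean pairwise Hamming distance per
#' bit below 1%). With a single particle the diversity term is 0 and the
#' flag depends on the velocity condition alone.
#'
#' @param swarm a `pso_swarm`.
#' @param config a `pso_config`.
#' @return logical flag.
#' @export
detect_premature_convergence <- function(swarm, config) {
  sat <- max(abs(swarm$vel)) >= config$v_max
  sat && swarm_diversity(swarm) < 0.01
}

# Mean pairwise Hamming distance between particle positions, per bit.
swarm_diversity <- function(swarm) {
  P <- nrow(swarm$pos); D <- ncol(swarm$pos)
  if (P < 2L) return(0)
  cnt <- colSums(swarm$pos)
  sum(cnt * (P - cnt)) / (choose(P, 2) * D)
}

#' Reset a collapsed swarm
#'
#' Escape from premature convergence: velocities are re-drawn
#' Uniform(-v_max, v_max) and each position bit is re-drawn from its
#' personal best (probability 0.25), the swarm best (0.25) or a fair random
#' bit (0.5) — re-dispersing the swarm around the two remembered solutions.
#' Personal and global bests are preserved, so the best fitness found so far
#' is unchanged.
#'
#' @param swarm a `pso_swarm`.
#' @param config a `pso_config`.
#' @return the reset swarm.
#' @export
reset_swarm <- function(swarm, config) {
  P <- nrow(swarm$pos); D <- ncol(swarm$pos)
  src <- matrix(stats::runif(P * D), P, D)
  rnd <- matrix(stats::rbinom(P * D, 1L, 0.5), P, D)
  gb <- matrix(swarm$gb_pos, P, D, byrow = TRUE)
  pos <- ifelse(src < 0.25, swarm$pb_pos, ifelse(src < 0.5, gb, rnd))
  for (i in seq_len(P))
    if (sum(pos[i, ]) == 0L) pos[i, sample.int(D, 1L)] <- 1L
  swarm$pos <- pos
  swarm$vel <- matrix(stats::runif(P * D, -config$v_max, config$v_max), P, D)
  swarm
}

#' Run binary-PSO wavelength selection
#'
#' Full loop: initialize, then per iteration evaluate every particle, update
#' personal and global bests (strict improvement), update velocities and
#' positions through the transfer function, and apply the reset-swarm escape
#' when premature convergence is detected. Fitness values are cached by
#' position, so re-visited subsets are not re-evaluated. Deterministic given
#' `config$seed` (the session RNG state is saved and restored around fitness
#' calls, which may seed their own CV internally).
#'
#' @param dataset a non-empty `spectra_dataset`.
#' @param fitness function `(mask, dataset) -> numeric`, larger is better;
#'   see [make_subset_fitness()].
#' @param config a `pso_config`.
#' @return list with `mask` (best 0/1 position), `fitness` (its value),
#'   `history` (best-so-far fitness after each iteration, non-decreasing),
#'   `n_evaluations` (distinct subsets evaluated) and `n_resets`.
#' @export
run_pso <- function(dataset, fitness, config) {
  D <- length(dataset$wavelengths)
  if (D < 1L || n_spectra(dataset) < 1L) stop("empty dataset")
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_mask <- function(mask) {
    key <- paste(mask, collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    rng <- get(".Random.seed", envir = globalenv())
    val <- fitness(mask, dataset)
    assign(".Random.seed", rng, envir = globalenv())
    n_eval <<- n_eval + 1L
    cache[[key]] <- val
    val
  }
  swarm <- init_swarm(config, D, seed_rng = FALSE)
  history <- numeric(config$n_iterations)
  n_resets <- 0L
  for (it in seq_len(config$n_iterations)) {
    fit <- vapply(seq_len(nrow(swarm$pos)),
                  function(i) eval_mask(swarm$pos[i, ]), numeric(1))
    swarm <- update_personal_best(swarm, fit)
    swarm <- update_global_best(swarm)
    history[it] <- swarm$gb_fit
    swarm$iteration <- it
    if (it < config$n_iterations) {
      swarm <- update_velocity(swarm, config)
      swarm <- update_position(swarm, config)
      if (config$reset_enabled &&
          detect_premature_convergence(swarm, config)) {
        swarm <- reset_swarm(swarm, config)
        n_resets <- n_resets + 1L
      }
    }
  }
  list(mask = swarm$gb_pos, fitness = swarm$gb_fit, history = history,
       n_evaluations = n_eval, n_resets = n_resets)
}

#' Exhaustive best subset (brute-force oracle)
#'
#' Evaluates the fitness of every non-empty channel subset (`2^D - 1` masks,
#' refused above D = 16) and returns the best; ties keep the mask whose
#' integer encoding (channel 1 = least-significant bit) is smallest, so a
#' size-only objective yields the single-channel mask on channel 1. Used as
#' the independent optimum against which [run_pso()] is benchmarked.
#'
#' @param dataset a `spectra_dataset` with at most 16 channels.
#' @param fitness function `(mask, dataset) -> numeric`.
#' @return list with `mask`, `fitness`.
#' @export
exhaustive_best_subset <- function(dataset, fitness) {
  D <- length(dataset$wavelengths)
  if (D > 16L) stop("exhaustive search refused for D > 16 (got ", D, ")")
  best_val <- -Inf
  best_mask <- NULL
  for (i in seq_len(2^D - 1L)) {
    mask <- as.integer(bitwAnd(bitwShiftR(i, 0:(D - 1L)), 1L))
    val <- fitness(mask, dataset)
    if (val > best_val) {
      best_val <- val
      best_mask <- mask
    }
  }
  list(mask = best_mask, fitness = best_val)
}
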