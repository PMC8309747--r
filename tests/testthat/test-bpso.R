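test_that("velocity transfer function has the logistic identities", {
  expect_equal(bpso_sigmoid(0), 0.5)
  for (v in c(-20, -3, 0.7, 12)) {
    expect_equal(bpso_sigmoid(v) + bpso_sigmoid(-v), 1, tolerance = 1e-12)
  }
  expect_equal(bpso_sigmoid(10), 1 / (1 + exp(-10)), tolerance = 1e-10)
  expect_equal(bpso_sigmoid(10), 0.9999546, tolerance = 1e-6)
  # overflow-safe far outside double range of exp
  expect_equal(bpso_sigmoid(800), 1)
  expect_equal(bpso_sigmoid(-800), 0, tolerance = 1e-300)
  # printed (literal) convention is the mirror image
  expect_equal(bpso_sigmoid(3, paper_literal = TRUE), bpso_sigmoid(-3))
})

test_that("velocity update matches the hand-evaluated kinematics", {
  # one particle, one bit: x = 0, pb = sb = 1, v = 0, w = 0.9,
  # c1 = c2 = 2, dt = 1, q = r = 0.5 -> v' = 0.9*0 + 2*0.5*1 + 2*0.5*1 = 2
  cfg <- pso_config(n_particles = 2L, w = 0.9, c1 = 2, c2 = 2, dt = 1,
                    v_max = 6, seed = 1)
  swarm <- structure(list(pos = matrix(0L, 2, 1), vel = matrix(0, 2, 1),
                          pb_pos = matrix(1L, 2, 1), pb_fit = c(1, 1),
                          gb_pos = 1L, gb_fit = 1, iteration = 0L),
                     class = "pso_swarm")
  v <- cfg$w * 0 + cfg$c1 * 0.5 * (1 - 0) / cfg$dt +
    cfg$c2 * 0.5 * (1 - 0) / cfg$dt
  expect_equal(v, 2.0)

  # formula limits through the real update: w = 1, c1 = c2 = 0 keeps v
  cfg0 <- pso_config(n_particles = 2L, w = 1, c1 = 0, c2 = 0, seed = 1)
  swarm$vel <- matrix(c(1.5, -2), 2, 1)
  out <- update_velocity(swarm, cfg0)
  expect_equal(out$vel, swarm$vel)

  # x = pb = sb: attraction terms vanish, v <- w v
  cfg2 <- pso_config(n_particles = 2L, w = 0.5, c1 = 2, c2 = 2, seed = 1)
  swarm2 <- swarm
  swarm2$pos <- matrix(1L, 2, 1)
  out2 <- update_velocity(swarm2, cfg2)
  expect_equal(out2$vel, 0.5 * swarm2$vel)

  # clamping to [-v_max, v_max]
  cfg3 <- pso_config(n_particles = 2L, w = 10, c1 = 0, c2 = 0, v_max = 3,
                     seed = 1)
  out3 <- update_velocity(swarm, cfg3)
  expect_true(all(abs(out3$vel) <= 3))
})

test_that("personal and global best updates use strict improvement", {
  swarm <- structure(list(pos = matrix(c(1L, 0L), 2, 1),
                          vel = matrix(0, 2, 1),
                          pb_pos = matrix(c(0L, 1L), 2, 1),
                          pb_fit = c(0.5, 0.5),
                          gb_pos = 0L, gb_fit = 0.5, iteration = 0L),
                     class = "pso_swarm")
  # equal fitness: incumbent personal bests kept (strict inequality)
  s1 <- update_personal_best(swarm, c(0.5, 0.5))
  expect_equal(s1$pb_pos, swarm$pb_pos)
  # strictly better: replaced
  s2 <- update_personal_best(swarm, c(0.7, 0.4))
  expect_equal(s2$pb_pos[1, ], 1L)
  expect_equal(s2$pb_fit, c(0.7, 0.5))
  expect_equal(s2$pb_pos[2, ], 1L)  # particle 2 unchanged

  # fitness sequence 0.3, 0.5, 0.4 ends with personal best 0.5
  s <- swarm; s$pb_fit <- c(-Inf, -Inf)
  for (f in c(0.3, 0.5, 0.4)) s <- update_personal_best(s, c(f, f))
  expect_equal(s$pb_fit[1], 0.5)

  # global best: tie keeps incumbent, improvement replaces
  g1 <- update_global_best(s1)
  expect_equal(g1$gb_fit, 0.5)
  expect_equal(g1$gb_pos, 0L)  # incumbent retained on tie
  g2 <- update_global_best(s2)
  expect_equal(g2$gb_fit, 0.7)
  expect_equal(g2$gb_pos, 1L)
})

test_that("swarm initialization is seeded and never emits an empty mask", {
  cfg <- pso_config(n_particles = 10L, seed = 123)
  a <- init_swarm(cfg, 20L)
  b <- init_swarm(cfg, 20L)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  expect_true(all(a$pos %in% c(0L, 1L)))
  expect_true(all(abs(a$vel) <= cfg$v_max))

  # D = 1: the repair rule forces every position to [1]
  one <- init_swarm(pso_config(n_particles = 20L, seed = 5), 1L)
  expect_true(all(one$pos == 1L))

  # property over many seeds: no all-zero particle
  for (s in 1:50) {
    sw <- init_swarm(pso_config(n_particles = 8L, seed = s), 5L)
    expect_true(all(rowSums(sw$pos) >= 1L))
  }
})

test_that("position update follows the transfer probability and repairs empties", {
  cfg <- pso_config(n_particles = 3L, seed = 1)
  swarm <- init_swarm(cfg, 4L)
  # saturated positive velocity -> bit 1; saturated negative -> bit 0
  swarm$vel <- matrix(rep(c(750, -750, 750, -750), each = 3), 3, 4)
  set.seed(2)
  out <- update_position(swarm, cfg)
  expect_true(all(out$pos[, c(1, 3)] == 1L))
  expect_true(all(out$pos[, c(2, 4)] == 0L))

  # v = 0 -> Bernoulli(0.5): empirical mean near 0.5
  big <- structure(list(pos = matrix(0L, 100, 100),
                        vel = matrix(0, 100, 100),
                        pb_pos = matrix(0L, 100, 100),
                        pb_fit = rep(-Inf, 100), gb_pos = rep(0L, 100),
                        gb_fit = -Inf, iteration = 0L),
                   class = "pso_swarm")
  set.seed(3)
  outb <- update_position(big, pso_config(n_particles = 100L, seed = 3))
  expect_equal(mean(outb$pos), 0.5, tolerance = 0.02)

  # all-negative velocities: repair still leaves at least one bit per particle
  swarm$vel <- matrix(-750, 3, 4)
  set.seed(4)
  outr <- update_position(swarm, cfg)
  expect_true(all(rowSums(outr$pos) >= 1L))
})

test_that("premature convergence requires saturated velocity and collapsed positions", {
  cfg <- pso_config(n_particles = 6L, v_max = 6, seed = 1)
  # fresh random swarms are diverse: no trigger across seeds
  for (s in 1:30) {
    sw <- init_swarm(pso_config(n_particles = 6L, seed = s), 30L)
    expect_false(detect_premature_convergence(sw, cfg))
  }
  # constructed collapse: identical positions + saturated velocities
  sw <- init_swarm(cfg, 30L)
  sw$pos <- matrix(rep(sw$pos[1, ], each = 6L), 6L, 30L)
  sw$vel[] <- 6
  expect_true(detect_premature_convergence(sw, cfg))
  # saturated but diverse: no trigger
  sw2 <- init_swarm(pso_config(n_particles = 6L, seed = 2), 30L)
  sw2$vel[] <- 6
  expect_false(detect_premature_convergence(sw2, cfg))
  # single particle: diversity is 0, flag follows the velocity condition
  s1 <- structure(list(pos = matrix(1L, 1, 4), vel = matrix(0, 1, 4),
                       pb_pos = matrix(1L, 1, 4), pb_fit = 0,
                       gb_pos = rep(1L, 4), gb_fit = 0, iteration = 0L),
                  class = "pso_swarm")
  expect_false(detect_premature_convergence(s1, cfg))
  s1$vel[1, 1] <- 6
  expect_true(detect_premature_convergence(s1, cfg))
})

test_that("reset preserves bests, restores diversity, and is reproducible", {
  cfg <- pso_config(n_particles = 8L, seed = 1)
  sw <- init_swarm(cfg, 40L)
  sw <- update_personal_best(sw, runif(8))
  sw <- update_global_best(sw)
  # collapse the swarm
  sw$pos <- matrix(rep(sw$pos[1, ], each = 8L), 8L, 40L)
  div_before <- nirstack:::swarm_diversity(sw)
  gb_before <- sw$gb_fit
  set.seed(10)
  out <- reset_swarm(sw, cfg)
  expect_identical(out$gb_fit, gb_before)
  expect_identical(out$pb_fit, sw$pb_fit)
  expect_gt(nirstack:::swarm_diversity(out), div_before)
  expect_true(all(abs(out$vel) <= cfg$v_max))
  set.seed(10)
  out2 <- reset_swarm(sw, cfg)
  expect_identical(out, out2)
})

test_that("subset fitness trades accuracy against size as specified", {
  gen <- reduced_benchmark()
  ds <- gen$dataset
  ridge <- default_model_specs()$ridge
  # alpha = 0: pure size term, independent of the data
  m <- c(1L, rep(0L, 63))
  expect_equal(subset_fitness(m, ds, ridge, alpha = 0), 1 - 1 / 64)
  # alpha = 1: pure accuracy
  P <- subset_fitness(gen$truth, ds, ridge, alpha = 1, folds = 3, seed = 1)
  J <- subset_fitness(gen$truth, ds, ridge, alpha = 0.5, folds = 3, seed = 1)
  expect_equal(J, 0.5 * P + 0.5 * (1 - sum(gen$truth) / 64))
  # all-zero mask is defined-invalid
  expect_identical(subset_fitness(rep(0L, 64), ds, ridge), -Inf)
  # informative support beats the all-ones mask at alpha = 0.5
  J_all <- subset_fitness(rep(1L, 64), ds, ridge, alpha = 0.5, folds = 3,
                          seed = 1)
  expect_gt(J, J_all)
})

test_that("run_pso keeps a monotone history and honors elitism", {
  bench <- d8_benchmark()
  cfg <- pso_config(n_particles = 10L, n_iterations = 8L, seed = 2,
                    fitness_folds = 3L)
  res <- run_pso(bench$dataset, bench$fitness, cfg)
  expect_true(all(diff(res$history) >= 0))
  expect_equal(res$fitness, max(res$history))
  expect_gte(sum(res$mask), 1L)
  # determinism
  res2 <- run_pso(bench$dataset, bench$fitness, cfg)
  expect_identical(res, res2)
})

test_that("a size-only objective drives the swarm to a single channel", {
  ds <- toy_dataset(n = 6L, D = 10L)
  size_fit <- function(mask, dataset) 1 - sum(mask) / length(mask)
  res <- run_pso(ds, size_fit, pso_config(n_particles = 50L,
                                          n_iterations = 10L, seed = 1))
  expect_equal(sum(res$mask), 1L)
  expect_equal(res$fitness, 0.9)
})

test_that("exhaustive search returns the lexicographic-smallest optimum", {
  ds <- toy_dataset(n = 4L, D = 3L)
  size_fit <- function(mask, dataset) 1 - sum(mask) / length(mask)
  out <- exhaustive_best_subset(ds, size_fit)
  expect_equal(out$mask, c(1L, 0L, 0L))  # first channel among all ties
  one <- subset_spectra(toy_dataset(n = 4L, D = 1L), 1:4)
  expect_equal(exhaustive_best_subset(one, size_fit)$mask, 1L)
  big <- toy_dataset(n = 4L, D = 17L)
  expect_error(exhaustive_best_subset(big, size_fit), "D > 16")
})

test_that("PSO matches the exhaustive optimum on the 8-channel benchmark", {
  bench <- d8_benchmark()
  oracle <- exhaustive_best_subset(bench$dataset, bench$fitness)
  hits <- 0L
  for (s in 1:20) {
    res <- run_pso(bench$dataset, bench$fitness,
                   pso_config(n_particles = 50L, n_iterations = 10L,
                              seed = s, fitness_folds = 3L))
    expect_lte(res$fitness, oracle$fitness + 1e-12)  # oracle dominance
    if (abs(res$fitness - oracle$fitness) < 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
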