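test_that("symmetric-uncertainty ranking behaves at the extremes", {
  set.seed(1)
  y <- rep(c(0L, 1L), 50)
  x <- cbind(
    copy = as.numeric(y),          # identical to the label
    noise = rnorm(100),
    const = rep(2, 100)            # constant
  )
  rk <- rank_relevance(x, y)
  expect_equal(rk$su[1], 1)
  expect_equal(rk$order[1], 1L)
  expect_equal(rk$su[3], 0)
  expect_equal(rk$order[3], 3L)

  # independence => SU near zero at large n
  set.seed(2)
  y2 <- rep(c(0L, 1L), 5000)
  x2 <- matrix(rnorm(10000), ncol = 1)
  expect_lt(rank_relevance(x2, y2)$su[1], 0.01)

  # exact ties break toward the lower column index
  x3 <- cbind(a = as.numeric(y), b = as.numeric(y))
  rk3 <- rank_relevance(x3, y)
  expect_equal(rk3$order, c(1L, 2L))
})

test_that("particle decoding applies a strict threshold on the prefix", {
  expect_equal(decode_particle(rep(1, 5), 0.6), 1:5)
  expect_equal(decode_particle(rep(0, 5), 0.6), integer(0))
  expect_equal(decode_particle(c(0.7, 0.6, 0.61), 0.6), c(1L, 3L))
})

test_that("subset fitness matches a hand-rolled CV oracle exactly", {
  # tiny 6-point toy with 2-fold CV, compared path-by-path
  set.seed(33)
  x <- matrix(rnorm(6 * 3), 6, 3)
  x[4:6, 1] <- x[4:6, 1] + 4
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  for (subset in list(1L, c(1L, 2L), 1:3, 2L)) {
    expect_equal(
      subset_fitness(x, y, subset, knn_k = 1L, folds = 2L, seed = 5L),
      fitness_oracle(x, y, subset, k = 1L, folds = 2L, seed = 5L)
    )
  }
  # larger random check, several seeds
  toy <- toy_separable(n = 24, p = 4, delta = 1.2, seed = 8)
  for (s in 1:5) {
    expect_equal(
      subset_fitness(toy$x, toy$y, c(1L, 3L), knn_k = 3L, folds = 4L,
                     seed = s),
      fitness_oracle(toy$x, toy$y, c(1L, 3L), k = 3L, folds = 4L, seed = s)
    )
  }
})

test_that("subset fitness conventions: empty set, separable bound, folds", {
  toy <- toy_separable(n = 60, p = 6, informative = 1:2, delta = 6,
                       seed = 21)
  expect_identical(subset_fitness(toy$x, toy$y, integer(0)), 1.0)
  for (subset in list(1L, 2L, c(1L, 2L), c(1L, 4L))) {
    expect_lt(subset_fitness(toy$x, toy$y, subset, knn_k = 5L,
                             folds = 10L, seed = 1L), 0.05)
  }
  # fold count above the minority class size is reduced with a warning
  y_imb <- c(rep(0L, 4L), rep(1L, 20L))
  x_imb <- matrix(rnorm(24 * 2), 24, 2)
  expect_warning(f <- subset_fitness(x_imb, y_imb, 1:2, folds = 10L),
                 "reducing folds")
  expect_true(f >= 0 && f <= 1)
})

test_that("swarm configuration is validated", {
  expect_error(swarm_config(threshold = 1), "threshold")
  expect_error(swarm_config(n_divisions = 40, population_size = 30),
               "n_divisions")
  expect_error(swarm_config(population_size = 1), "population_size")
  expect_error(swarm_config(max_iterations = 0), "max_iterations")
})

test_that("swarm runs are elitist, reproducible, and budget-respecting", {
  toy <- toy_separable(n = 40, p = 10, informative = c(1, 5), delta = 2.5,
                       seed = 13)
  cfg <- swarm_config(max_iterations = 15, population_size = 12,
                      n_divisions = 4, fitness_folds = 5, seed = 9)
  a <- vlpso_run(toy$x, toy$y, cfg)
  b <- vlpso_run(toy$x, toy$y, cfg)
  expect_identical(a[names(a) != "config"], b[names(b) != "config"])
  # elitism: non-increasing gbest trace, for several seeds
  for (s in c(9, 10, 11)) {
    cfg_s <- swarm_config(max_iterations = 10, population_size = 10,
                          n_divisions = 4, fitness_folds = 5, seed = s)
    r <- vlpso_run(toy$x, toy$y, cfg_s)
    expect_true(all(diff(r$trace) <= 0))
    expect_length(r$trace, cfg_s$max_iterations + 1L)
    # exact evaluation accounting
    expect_equal(r$n_evaluations,
                 cfg_s$population_size * (cfg_s$max_iterations + 1L) +
                   r$n_reevaluations)
    expect_gt(length(r$selected), 0L)
    expect_true(all(r$selected %in% colnames(toy$x)))
    expect_equal(r$selected_idx, sort(r$selected_idx))
  }
})

test_that("swarm finds the exhaustive optimum on a small separable toy", {
  # single-seed unit check; the 40-seed acceptance version is in
  # test-acceptance.R
  toy <- toy_separable(n = 40, p = 8, informative = 1:2, delta = 3,
                       seed = 55)
  cfg <- swarm_config(max_iterations = 25, seed = 4, fitness_folds = 5)
  res <- vlpso_run(toy$x, toy$y, cfg)
  fit_seed <- amyvoice:::derive_seed(cfg$seed, 777L)
  rk <- rank_relevance(toy$x, toy$y)
  xr <- toy$x[, rk$order]
  best <- min(vapply(1:255, function(mask) {
    subset_fitness(xr, toy$y, which(bitwAnd(mask, 2^(0:7)) != 0),
                   knn_k = cfg$knn_k, folds = cfg$fitness_folds,
                   seed = fit_seed)
  }, numeric(1)))
  expect_equal(res$best_fitness, best)
})

test_that("selected subsets sit inside the ranked prefix", {
  toy <- toy_separable(n = 30, p = 12, informative = 1:2, delta = 3,
                       seed = 77)
  cfg <- swarm_config(max_iterations = 8, population_size = 8,
                      n_divisions = 4, fitness_folds = 5, seed = 2)
  r <- vlpso_run(toy$x, toy$y, cfg)
  # every selected feature is reachable through the ranking
  pos_in_ranking <- match(r$selected_idx, r$ranking)
  expect_true(all(pos_in_ranking <= ncol(toy$x)))
  expect_true(all(!is.na(pos_in_ranking)))
})
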