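test_that("greedy stepwise adds the predictive feature first and improves strictly", {
  withr::local_seed(15)
  y <- rep(c("0", "1"), each = 40)
  tab <- data_table(
    data.frame(signal = ifelse(y == "1", 2, -2) + rnorm(80, sd = 0.3),
               junk1 = rnorm(80), junk2 = rnorm(80), junk3 = rnorm(80)),
    labels = y)
  res <- greedy_stepwise(tab, search_config(seed = 3))
  expect_true(res$best_mask[["signal"]])
  # accepted-step fitness sequence is strictly increasing
  expect_true(all(diff(res$trajectory) > 0) || length(res$trajectory) == 1)
  # the first accepted step is the best singleton, i.e. the signal feature
  f_sig <- subset_fitness(c(TRUE, FALSE, FALSE, FALSE), tab,
                          search_config(seed = 3))
  expect_equal(res$trajectory[1], f_sig)
})

test_that("greedy stepwise on a single-feature table returns that singleton", {
  g <- generate_synthetic(synthetic_spec(
    n_rows = 60, n_informative = 1, n_noise = 1, effect_size = 2, seed = 5))
  tab1 <- subset_table(g$table, cols = 1)
  res <- greedy_stepwise(tab1, search_config(seed = 1))
  expect_equal(unname(res$best_mask), TRUE)
})

test_that("best-first search matches the exhaustive optimum with a generous stall", {
  for (seed in c(4, 22)) {
    g <- generate_synthetic(synthetic_spec(
      n_rows = 100, n_informative = 2, n_noise = 3, effect_size = 1.5,
      seed = seed))
    cfg <- search_config(seed = seed)
    ctx <- fitness_context(g$table, cfg)
    bf <- best_first(g$table, cfg, stall_limit = 50, ctx = ctx)
    ex <- exhaustive_select(g$table, cfg, ctx = ctx)
    expect_identical(bf$best_fitness, ex$best_fitness)
  }
  # stall_limit = 1 stops after the first non-improving expansion
  g <- generate_synthetic(synthetic_spec(
    n_rows = 80, n_informative = 2, n_noise = 3, effect_size = 1, seed = 2))
  quick <- best_first(g$table, search_config(seed = 2), stall_limit = 1)
  full <- best_first(g$table, search_config(seed = 2), stall_limit = 50)
  expect_lte(quick$iterations_run, full$iterations_run)
  # deterministic under a fixed seed
  expect_identical(best_first(g$table, search_config(seed = 2)),
                   best_first(g$table, search_config(seed = 2)))
})

test_that("the genetic search keeps an elitist non-decreasing best", {
  g <- generate_synthetic(synthetic_spec(
    n_rows = 100, n_informative = 2, n_noise = 4, effect_size = 1.5,
    seed = 7))
  res <- genetic_select(g$table, search_config(seed = 7), population = 12,
                        generations = 15)
  expect_true(all(diff(res$trajectory) >= 0))
  expect_true(any(res$best_mask))
  expect_identical(res,
                   genetic_select(g$table, search_config(seed = 7),
                                  population = 12, generations = 15))
})

test_that("without variation operators a uniform population is invariant", {
  g <- generate_synthetic(synthetic_spec(
    n_rows = 60, n_informative = 2, n_noise = 2, effect_size = 1, seed = 9))
  cfg <- search_config(seed = 9)
  ctx <- fitness_context(g$table, cfg)
  base <- genetic_select(g$table, cfg, population = 8, generations = 10,
                         crossover_rate = 0, mutation_rate = 0, ctx = ctx)
  # no crossover, no mutation: the best fitness cannot change after the
  # initial population is evaluated
  expect_equal(base$trajectory, rep(base$trajectory[1], 11))
})

test_that("binary PSO tracks a non-decreasing global best and recovers optima", {
  hits <- 0
  for (seed in c(3, 13, 23, 33, 43)) {
    g <- generate_synthetic(synthetic_spec(
      n_rows = 100, n_informative = 2, n_noise = 3, effect_size = 2,
      seed = seed))
    cfg <- search_config(seed = seed)
    ctx <- fitness_context(g$table, cfg)
    ps <- pso_select(g$table, cfg, swarm = 12, iterations = 25, ctx = ctx)
    expect_true(all(diff(ps$trajectory) >= 0))
    ex <- exhaustive_select(g$table, cfg, ctx = ctx)
    if (identical(ps$best_fitness, ex$best_fitness)) hits <- hits + 1
  }
  expect_gte(hits, 3)  # majority of seeds reach the exhaustive optimum
})

test_that("genetic search finds the exhaustive optimum on easy planted signal", {
  hits <- 0
  for (seed in c(2, 12, 22, 32, 42)) {
    g <- generate_synthetic(synthetic_spec(
      n_rows = 100, n_informative = 2, n_noise = 3, effect_size = 2,
      seed = seed))
    cfg <- search_config(seed = seed)
    ctx <- fitness_context(g$table, cfg)
    ga <- genetic_select(g$table, cfg, population = 16, generations = 25,
                         ctx = ctx)
    ex <- exhaustive_select(g$table, cfg, ctx = ctx)
    if (identical(ga$best_fitness, ex$best_fitness)) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("all methods return valid subsets and share the memoized fitness", {
  g <- generate_synthetic(synthetic_spec(
    n_rows = 80, n_informative = 2, n_noise = 3, effect_size = 1.5,
    seed = 31))
  cfg <- search_config(seed = 31, restarts = 2, max_iter = 40)
  ctx <- fitness_context(g$table, cfg)
  results <- list(
    mmas_select(g$table, cfg, ctx = ctx),
    greedy_stepwise(g$table, cfg, ctx = ctx),
    best_first(g$table, cfg, ctx = ctx),
    genetic_select(g$table, cfg, population = 10, generations = 10,
                   ctx = ctx),
    pso_select(g$table, cfg, swarm = 10, iterations = 10, ctx = ctx))
  for (res in results) {
    expect_true(any(res$best_mask))
    # the reported fitness is exactly the shared cache's value for the mask
    expect_identical(res$best_fitness,
                     subset_fitness(unname(res$best_mask), ctx))
  }
})
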