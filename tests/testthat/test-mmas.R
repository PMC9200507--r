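test_that("the neighborhood is all single-bit flips excluding the empty subset", {
  nb <- neighborhood(c(TRUE, FALSE, TRUE))  # mask 101
  expect_equal(nb, list(c(FALSE, FALSE, TRUE),   # 001
                        c(TRUE, TRUE, TRUE),     # 111
                        c(TRUE, FALSE, FALSE)))  # 100
  # singleton in d features: flipping the set bit would empty it
  singleton <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_length(neighborhood(singleton), 4)
  expect_true(all(vapply(neighborhood(singleton), any, logical(1))))
  # full subset: all d removals allowed
  expect_length(neighborhood(rep(TRUE, 6)), 6)
})

test_that("fitness is deterministic, memoized, and penalizes size on constant data", {
  tab <- random_mixed_table(n = 50, seed = 12)
  cfg <- search_config(seed = 5)
  ctx <- fitness_context(tab, cfg)
  mask <- c(TRUE, FALSE, TRUE, FALSE)
  f1 <- subset_fitness(mask, ctx)
  evals_after_first <- ctx$n_evaluations$count
  f2 <- subset_fitness(mask, ctx)
  expect_identical(f1, f2)
  expect_equal(ctx$n_evaluations$count, evals_after_first)  # cache hit
  # a fresh context with the same seed gives the identical value
  expect_identical(subset_fitness(mask, fitness_context(tab, cfg)), f1)
  expect_error(subset_fitness(rep(FALSE, 4), ctx), "empty subset")

  # identical constant features: accuracy equal, parsimony term decides
  const <- data_table(as.data.frame(matrix(1, 40, 3)),
                      labels = rep(c("0", "1"), 20))
  cctx <- fitness_context(const, search_config(seed = 2, lambda = 0.05))
  f_single <- subset_fitness(c(TRUE, FALSE, FALSE), cctx)
  f_pair <- subset_fitness(c(TRUE, TRUE, FALSE), cctx)
  f_all <- subset_fitness(c(TRUE, TRUE, TRUE), cctx)
  expect_gt(f_single, f_pair)
  expect_gt(f_pair, f_all)
})

test_that("planted informative subsets outscore equal-size noise subsets", {
  wins <- 0
  for (seed in 1:10) {
    g <- generate_synthetic(synthetic_spec(
      n_rows = 200, n_informative = 3, n_noise = 3, effect_size = 1.5,
      seed = seed))
    ctx <- fitness_context(g$table, search_config(seed = seed))
    inf_mask <- seq_len(6) %in% g$informative
    noise_mask <- seq_len(6) %in% g$noise
    if (subset_fitness(inf_mask, ctx) > subset_fitness(noise_mask, ctx))
      wins <- wins + 1
  }
  expect_gt(wins, 5)
})

test_that("the walk honors memory, aspiration, and monotone global best", {
  g <- generate_synthetic(synthetic_spec(
    n_rows = 120, n_informative = 2, n_noise = 4, effect_size = 1, seed = 3))
  cfg <- search_config(seed = 9, restarts = 2, max_iter = 80, tenure = 8)
  res <- mmas_select(g$table, cfg)
  for (traj in res$trajectory) {
    expect_true(all(diff(traj[, "best"]) >= 0))
    expect_true(all(traj[, "best"] >= traj[, "current"] - 1e-12))
  }
  # every tabu move must be an aspiration or a forced deadlock move
  for (run in res$moves)
    for (mv in run)
      if (mv$tabu) expect_true(mv$aspirated || mv$forced)
  # determinism: identical inputs -> identical result
  res2 <- mmas_select(g$table, cfg)
  expect_identical(res$best_mask, res2$best_mask)
  expect_identical(res$best_fitness, res2$best_fitness)
  expect_identical(res$trajectory, res2$trajectory)
})

test_that("max_iter = 1 returns the initial subset unchanged", {
  tab <- random_mixed_table(n = 40, seed = 6)
  cfg <- search_config(seed = 4, restarts = 1, max_iter = 1)
  res <- mmas_select(tab, cfg)
  expect_equal(res$iterations_run, 1L)
  expect_equal(nrow(res$trajectory[[1]]), 1L)
  # the best subset is the (seeded) random initial subset
  init <- withr::with_seed(cfg$seed, {
    m <- as.logical(stats::rbinom(4, 1, 0.5))
    while (!any(m)) m <- as.logical(stats::rbinom(4, 1, 0.5))
    m
  })
  expect_equal(unname(res$best_mask), init)
})

test_that("search matches the exhaustive oracle on small problems", {
  for (seed in c(5, 17)) {
    g <- generate_synthetic(synthetic_spec(
      n_rows = 120, n_informative = 2, n_noise = 4, effect_size = 1.5,
      seed = seed))
    cfg <- search_config(seed = seed, restarts = 3, max_iter = 100)
    ctx <- fitness_context(g$table, cfg)
    mm <- mmas_select(g$table, cfg, ctx = ctx)
    ex <- exhaustive_select(g$table, cfg, ctx = ctx)
    expect_identical(mm$best_fitness, ex$best_fitness)
    expect_gte(ex$best_fitness, mm$best_fitness)  # oracle dominance
  }
})

test_that("exhaustive search enumerates exactly 2^d - 1 subsets", {
  tab <- random_mixed_table(n = 30, seed = 2)
  tab3 <- subset_table(tab, cols = 1:3)
  cfg <- search_config(seed = 1)
  ex <- exhaustive_select(tab3, cfg)
  expect_equal(ex$n_evaluations, 7L)
  big <- as.data.frame(matrix(rnorm(30 * 21), 30, 21))
  toobig <- data_table(big, labels = rep(c("0", "1"), 15))
  expect_error(exhaustive_select(toobig, cfg), "20 features")
})

test_that("a perfectly predictive feature wins as a singleton under parsimony", {
  withr::local_seed(44)
  y <- rep(c("0", "1"), each = 30)
  tab <- data_table(
    data.frame(oracle_col = ifelse(y == "1", 1, 0) + rnorm(60, sd = 1e-3),
               junk = rnorm(60)),
    labels = y)
  cfg <- search_config(seed = 2, lambda = 0.01)
  ex <- exhaustive_select(tab, cfg)
  expect_equal(unname(ex$best_mask), c(TRUE, FALSE))
})

test_that("relevance scores are selection frequencies on a 0-10 scale", {
  g <- generate_synthetic(synthetic_spec(
    n_rows = 250, n_informative = 2, n_noise = 4, effect_size = 3,
    seed = 29))
  rs <- relevance_scores(g$table, search_config(seed = 8, restarts = 6))
  expect_true(all(rs$scores >= 0 & rs$scores <= 10))
  # frequencies are multiples of 10/restarts
  expect_true(all(abs(rs$scores * 6 / 10 - round(rs$scores * 6 / 10)) < 1e-9))
  # strong planted signal: informative features selected in every restart
  expect_equal(unname(rs$scores[g$informative]), c(10, 10))
  expect_false(any(rs$low_relevance[g$informative]))
  expect_error(relevance_scores(g$table, search_config(restarts = 1)),
               "restarts >= 2")
})

test_that("the memory buffer never exceeds its capacity and evicts FIFO", {
  # tiny tenure forces evictions; replay the walk's buffer from the move log
  g <- generate_synthetic(synthetic_spec(
    n_rows = 100, n_informative = 2, n_noise = 3, effect_size = 1, seed = 2))
  cfg <- search_config(seed = 3, restarts = 1, max_iter = 60, tenure = 3)
  res <- mmas_select(g$table, cfg)
  moves <- res$moves[[1]]
  buffer <- character(1)  # the initial subset occupies one slot
  buffer[1] <- "init"
  for (mv in moves) {
    buffer <- c(buffer, mv$key)
    if (length(buffer) > cfg$tenure) buffer <- buffer[-1]
    expect_lte(length(buffer), cfg$tenure)
  }
})
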