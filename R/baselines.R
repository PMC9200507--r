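#' Greedy stepwise (forward) selection
#'
#' Starts from the empty set and repeatedly adds the feature with the
#' largest fitness gain, stopping when no addition strictly improves the
#' current fitness. The accepted-step fitness sequence is therefore strictly
#' increasing; if no second feature ever helps, the best singleton is
#' returned. Shares [subset_fitness()] with every other method.
#'
#' @param table An imputed [data_table()].
#' @param config A [search_config()] (only `lambda`, `inner_folds`, `seed`,
#'   `alpha`, `var_floor` matter here).
#' @param ctx Optional shared [fitness_context()].
#' @return A `selection_result` with `method = "greedy_stepwise"`.
#' @export
greedy_stepwise <- function(table, config = search_config(), ctx = NULL) {
  stopifnot(inherits(table, "data_table"), inherits(config, "search_config"))
  if (n_features(table) < 1L) stop("need at least one feature")
  if (is.null(ctx)) ctx <- fitness_context(table, config)
  d <- ctx$d
  current <- rep(FALSE, d)
  cur_fit <- -Inf
  accepted <- numeric(0)
  repeat {
    cand_idx <- which(!current)
    if (!length(cand_idx)) break
    best_j <- NA_integer_
    best_fit <- -Inf
    best_mask <- current
    for (j in cand_idx) {
      m <- current
      m[j] <- TRUE
      f <- subset_fitness(m, ctx)
      if (is.na(best_j) || .better_subset(f, m, best_fit, best_mask)) {
        best_j <- j
        best_fit <- f
        best_mask <- m
      }
    }
    if (best_fit <= cur_fit) break
    current <- best_mask
    cur_fit <- best_fit
    accepted <- c(accepted, cur_fit)
  }
  .new_selection_result("greedy_stepwise", current, cur_fit,
                        trajectory = accepted,
                        iterations = length(accepted),
                        n_evals = ctx$n_evaluations$count %||% 0L,
                        feature_names = names(table$features))
}

#' Best-first subset search
#'
#' Priority-ordered forward search: subsets are expanded best-fitness-first,
#' each expansion scoring all one-feature additions of the most promising
#' unexpanded subset. Stops after `stall_limit` consecutive expansions
#' without improving the global best (or when the open list empties).
#' Deterministic: ties in the open list break by the subset order rule.
#'
#' @inheritParams greedy_stepwise
#' @param stall_limit Consecutive non-improving expansions allowed
#'   (default 5).
#' @return A `selection_result` with `method = "best_first"`.
#' @export
best_first <- function(table, config = search_config(), stall_limit = 5L,
                       ctx = NULL) {
  stopifnot(inherits(table, "data_table"), inherits(config, "search_config"),
            stall_limit >= 1L)
  if (n_features(table) < 1L) stop("need at least one feature")
  if (is.null(ctx)) ctx <- fitness_context(table, config)
  d <- ctx$d
  open_masks <- list()
  open_fits <- numeric(0)
  seen <- new.env(parent = emptyenv())
  add_open <- function(mask) {
    key <- .mask_key(mask)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    open_masks[[length(open_masks) + 1L]] <<- mask
    open_fits[length(open_fits) + 1L] <<- subset_fitness(mask, ctx)
  }
  for (j in seq_len(d)) {
    m <- rep(FALSE, d)
    m[j] <- TRUE
    add_open(m)
  }
  pick_best_open <- function() {
    pick <- 1L
    for (i in seq_along(open_masks)[-1L])
      if (.better_subset(open_fits[i], open_masks[[i]],
                         open_fits[pick], open_masks[[pick]]))
        pick <- i
    pick
  }
  best <- open_masks[[pick_best_open()]]
  best_fit <- subset_fitness(best, ctx)
  stall <- 0L
  expansions <- 0L
  while (length(open_masks) && stall < stall_limit) {
    i <- pick_best_open()
    node <- open_masks[[i]]
    node_fit <- open_fits[i]
    open_masks[[i]] <- NULL
    open_fits <- open_fits[-i]
    expansions <- expansions + 1L
    if (.better_subset(node_fit, node, best_fit, best)) {
      best <- node
      best_fit <- node_fit
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    for (j in which(!node)) {
      m <- node
      m[j] <- TRUE
      add_open(m)
    }
  }
  .new_selection_result("best_first", best, best_fit, trajectory = NULL,
                        iterations = expansions,
                        n_evals = ctx$n_evaluations$count %||% 0L,
                        feature_names = names(table$features))
}

# set one random bit in an all-FALSE mask
.repair_empty <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1L)] <- TRUE
  mask
}

#' Genetic-algorithm subset selection
#'
#' Canonical binary GA: tournament selection of size 2, uniform crossover,
#' independent bit-flip mutation, elitism of one, fixed population and
#' generation counts. Empty offspring are repaired by setting one random
#' bit. Returns the best individual ever evaluated.
#'
#' @inheritParams greedy_stepwise
#' @param population Population size (default 20).
#' @param generations Generations (default 50).
#' @param crossover_rate Per-pair uniform-crossover probability
#'   (default 0.6).
#' @param mutation_rate Per-bit flip probability; default `1 / d`.
#' @return A `selection_result` with `method = "genetic"`; `trajectory` is
#'   the per-generation best fitness (non-decreasing under elitism).
#' @export
genetic_select <- function(table, config = search_config(), population = 20L,
                           generations = 50L, crossover_rate = 0.6,
                           mutation_rate = NULL, ctx = NULL) {
  stopifnot(inherits(table, "data_table"), inherits(config, "search_config"),
            population >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1)
  if (is.null(ctx)) ctx <- fitness_context(table, config)
  d <- ctx$d
  if (is.null(mutation_rate)) mutation_rate <- 1 / d
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  withr::with_seed(config$seed, {
    pop <- lapply(seq_len(population), function(i)
      .repair_empty(as.logical(stats::rbinom(d, 1L, 0.5))))
    fits <- vapply(pop, subset_fitness, numeric(1), ctx = ctx)
    gbest_i <- which.max(fits)
    best <- pop[[gbest_i]]
    best_fit <- fits[gbest_i]
    traj <- best_fit
    for (g in seq_len(generations)) {
      tournament <- function() {
        ij <- sample.int(population, 2L)
        if (fits[ij[1L]] >= fits[ij[2L]]) pop[[ij[1L]]] else pop[[ij[2L]]]
      }
      nextgen <- list(best)  # elitism of 1
      while (length(nextgen) < population) {
        p1 <- tournament()
        p2 <- tournament()
        if (stats::runif(1) < crossover_rate) {
          swap <- stats::runif(d) < 0.5
          child <- ifelse(swap, p2, p1)
        } else {
          child <- p1
        }
        flip <- stats::runif(d) < mutation_rate
        child <- xor(child, flip)
        nextgen[[length(nextgen) + 1L]] <- .repair_empty(child)
      }
      pop <- nextgen
      fits <- vapply(pop, subset_fitness, numeric(1), ctx = ctx)
      for (i in seq_along(pop))
        if (.better_subset(fits[i], pop[[i]], best_fit, best)) {
          best <- pop[[i]]
          best_fit <- fits[i]
        }
      traj <- c(traj, best_fit)
    }
    .new_selection_result("genetic", best, best_fit, trajectory = traj,
                          iterations = generations,
                          n_evals = ctx$n_evaluations$count %||% 0L,
                          feature_names = names(table$features))
  })
}

#' Binary particle-swarm subset selection
#'
#' Canonical binary PSO: real-valued velocities updated with inertia `w` and
#' cognitive/social pulls `c1`, `c2`, clamped to \[-6, 6\] so the sigmoid
#' transfer never saturates; bits resampled as Bernoulli(sigmoid(v)). Empty
#' masks are repaired by setting one random bit. Returns the global-best
#' mask ever evaluated.
#'
#' @inheritParams greedy_stepwise
#' @param swarm Swarm size (default 20).
#' @param iterations Iterations (default 50).
#' @param w Inertia weight (default 0.7).
#' @param c1,c2 Cognitive and social coefficients (default 1.5 each).
#' @param v_clamp Velocity clamp (default 6).
#' @return A `selection_result` with `method = "pso"`; `trajectory` is the
#'   per-iteration global-best fitness.
#' @export
pso_select <- function(table, config = search_config(), swarm = 20L,
                       iterations = 50L, w = 0.7, c1 = 1.5, c2 = 1.5,
                       v_clamp = 6, ctx = NULL) {
  stopifnot(inherits(table, "data_table"), inherits(config, "search_config"),
            swarm >= 2L, iterations >= 1L, v_clamp > 0)
  if (is.null(ctx)) ctx <- fitness_context(table, config)
  d <- ctx$d
  sigmoid <- function(v) 1 / (1 + exp(-v))
  withr::with_seed(config$seed, {
    X <- lapply(seq_len(swarm), function(i)
      .repair_empty(as.logical(stats::rbinom(d, 1L, 0.5))))
    V <- lapply(seq_len(swarm), function(i) stats::runif(d, -1, 1))
    fits <- vapply(X, subset_fitness, numeric(1), ctx = ctx)
    pbest <- X
    pbest_fit <- fits
    g <- which.max(fits)
    gbest <- X[[g]]
    gbest_fit <- fits[g]
    traj <- gbest_fit
    for (it in seq_len(iterations)) {
      for (i in seq_len(swarm)) {
        r1 <- stats::runif(d)
        r2 <- stats::runif(d)
        V[[i]] <- w * V[[i]] +
          c1 * r1 * (as.numeric(pbest[[i]]) - as.numeric(X[[i]])) +
          c2 * r2 * (as.numeric(gbest) - as.numeric(X[[i]]))
        V[[i]] <- pmin(pmax(V[[i]], -v_clamp), v_clamp)
        X[[i]] <- .repair_empty(stats::runif(d) < sigmoid(V[[i]]))
        fits[i] <- subset_fitness(X[[i]], ctx)
        if (.better_subset(fits[i], X[[i]], pbest_fit[i], pbest[[i]])) {
          pbest[[i]] <- X[[i]]
          pbest_fit[i] <- fits[i]
        }
        if (.better_subset(fits[i], X[[i]], gbest_fit, gbest)) {
          gbest <- X[[i]]
          gbest_fit <- fits[i]
        }
      }
      traj <- c(traj, gbest_fit)
    }
    .new_selection_result("pso", gbest, gbest_fit, trajectory = traj,
                          iterations = iterations,
                          n_evals = ctx$n_evaluations$count %||% 0L,
                          feature_names = names(table$features))
  })
}
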