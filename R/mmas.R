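#' Search configuration for subset selection
#'
#' Shared by the memory-based search, the exhaustive oracle and every
#' baseline heuristic, so all of them optimize the identical fitness
#' function.
#'
#' @param max_iter Maximum walk iterations per restart (default 100).
#' @param stall_limit Consecutive iterations without global improvement
#'   before stopping (default 20).
#' @param tenure Capacity of the FIFO memory buffer of visited subsets
#'   (default 10).
#' @param fitness_threshold Optional early-stop fitness; search halts once
#'   the global best reaches it. `NULL` (default) disables it.
#' @param lambda Parsimony weight: fitness is inner-CV accuracy minus
#'   `lambda * |subset| / n_features`. The default 0.01 lets accuracy
#'   dominate and only breaks near-ties towards smaller subsets; 0 gives a
#'   pure wrapper.
#' @param inner_folds Folds of the inner stratified CV inside the fitness
#'   (default 5).
#' @param seed Seed controlling the inner folds and all search randomness.
#' @param restarts Independent restarts (default 5); the best result across
#'   restarts is returned, and relevance scoring counts selection frequency
#'   across them.
#' @param alpha,var_floor Naive Bayes hyperparameters used inside the
#'   fitness.
#' @return An object of class `search_config`.
#' @export
search_config <- function(max_iter = 100L, stall_limit = 20L, tenure = 10L,
                          fitness_threshold = NULL, lambda = 0.01,
                          inner_folds = 5L, seed = 1L, restarts = 5L,
                          alpha = 1, var_floor = 1e-9) {
  stopifnot(max_iter >= 1L, stall_limit >= 1L, tenure >= 1L, lambda >= 0,
            inner_folds >= 2L, restarts >= 1L)
  structure(list(max_iter = as.integer(max_iter),
                 stall_limit = as.integer(stall_limit),
                 tenure = as.integer(tenure),
                 fitness_threshold = fitness_threshold,
                 lambda = lambda, inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 alpha = alpha, var_floor = var_floor),
            class = "search_config")
}

#' Build a reusable fitness context
#'
#' Precomputes everything the subset fitness needs — encoded matrices,
#' stratified inner folds (fixed by `config$seed`, so every subset is scored
#' against the same folds), per-fold per-class sufficient statistics, and a
#' memoization cache — making repeated fitness queries cheap and exactly
#' reproducible.
#'
#' @param table An imputed [data_table()].
#' @param config A [search_config()].
#' @return An object of class `fitness_context`.
#' @export
fitness_context <- function(table, config) {
  stopifnot(inherits(table, "data_table"), inherits(config, "search_config"))
  if (anyNA(table$features)) stop("impute missing values before searching")
  enc <- .nb_encode(table)
  y <- match(table$labels, table$class_names)
  folds <- stratified_folds(table$labels, config$inner_folds, config$seed)
  d <- n_features(table)
  # feature j -> column in Xnum or Xcat
  num_of <- match(seq_len(d), enc$num_cols)
  cat_of <- match(seq_len(d), enc$cat_cols)
  fold_stats <- lapply(folds, function(test_idx) {
    tr <- setdiff(seq_along(y), test_idx)
    ytr <- y[tr]
    counts <- tabulate(ytr, nbins = 2L)
    s1 <- s2 <- matrix(0, 2L, ncol(enc$Xnum))
    for (c in 1:2) {
      Xc <- enc$Xnum[tr[ytr == c], , drop = FALSE]
      if (ncol(Xc)) {
        s1[c, ] <- colSums(Xc)
        s2[c, ] <- colSums(Xc^2)
      }
    }
    cat_counts <- lapply(seq_len(ncol(enc$Xcat)), function(i) {
      L <- length(enc$cat_levels[[i]])
      vapply(1:2, function(c)
        tabulate(enc$Xcat[tr[ytr == c], i], nbins = L), numeric(L))
    })
    list(test = test_idx, counts = counts, s1 = s1, s2 = s2,
         cat_counts = cat_counts,
         Xnum_test = enc$Xnum[test_idx, , drop = FALSE],
         Xnum_test2 = enc$Xnum[test_idx, , drop = FALSE]^2,
         Xcat_test = enc$Xcat[test_idx, , drop = FALSE],
         y_test = y[test_idx])
  })
  structure(
    list(table = table, config = config, d = d,
         num_of = num_of, cat_of = cat_of,
         cat_levels = enc$cat_levels, fold_stats = fold_stats,
         cache = new.env(parent = emptyenv()),
         n_evaluations = new.env(parent = emptyenv())),
    class = "fitness_context")
}

.mask_key <- function(mask) paste(which(mask), collapse = ",")

#' Fitness of a feature subset
#'
#' Mean stratified inner-CV Naive Bayes accuracy on the subset's columns,
#' minus `lambda * |subset| / n_features`. Deterministic given the context
#' (folds are fixed at context construction) and memoized per subset mask.
#'
#' @param mask Logical inclusion vector over features (at least one `TRUE`).
#' @param ctx A [fitness_context()]; alternatively pass a [data_table()]
#'   together with `config` for one-off scoring.
#' @param config A [search_config()], only needed when `ctx` is a table.
#' @return A single fitness value.
#' @export
subset_fitness <- function(mask, ctx, config = NULL) {
  if (inherits(ctx, "data_table")) {
    if (is.null(config)) config <- search_config()
    ctx <- fitness_context(ctx, config)
  }
  stopifnot(inherits(ctx, "fitness_context"))
  mask <- as.logical(mask)
  if (length(mask) != ctx$d) stop("mask length must equal the feature count")
  if (!any(mask)) stop("the empty subset has no fitness")
  key <- .mask_key(mask)
  cached <- ctx$cache[[key]]
  if (!is.null(cached)) return(cached)
  cfg <- ctx$config
  sel_num <- ctx$num_of[mask]
  sel_num <- sel_num[!is.na(sel_num)]
  sel_cat <- ctx$cat_of[mask]
  sel_cat <- sel_cat[!is.na(sel_cat)]
  acc <- 0
  for (fs in ctx$fold_stats) {
    nc <- fs$counts
    ll <- matrix(rep(log(nc / sum(nc)), each = length(fs$y_test)),
                 length(fs$y_test), 2L)
    for (c in 1:2) {
      if (length(sel_num)) {
        m <- fs$s1[c, sel_num] / nc[c]
        v <- pmax(fs$s2[c, sel_num] / nc[c] - m^2, cfg$var_floor)
        Xt <- fs$Xnum_test[, sel_num, drop = FALSE]
        Xt2 <- fs$Xnum_test2[, sel_num, drop = FALSE]
        ll[, c] <- ll[, c] - 0.5 * sum(log(2 * pi * v)) -
          0.5 * (Xt2 %*% (1 / v) - 2 * (Xt %*% (m / v)) + sum(m^2 / v))
      }
      for (i in sel_cat) {
        L <- length(ctx$cat_levels[[i]])
        p <- (fs$cat_counts[[i]][, c] + cfg$alpha) / (nc[c] + cfg$alpha * L)
        ll[, c] <- ll[, c] + log(p)[fs$Xcat_test[, i]]
      }
    }
    pred <- .nb_argmax(ll, nc / sum(nc))
    acc <- acc + mean(pred == fs$y_test)
  }
  fit <- acc / length(ctx$fold_stats) - cfg$lambda * sum(mask) / ctx$d
  ctx$cache[[key]] <- fit
  ctx$n_evaluations$count <- (ctx$n_evaluations$count %||% 0L) + 1L
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hamming-distance-1 neighborhood of a subset
#'
#' Every subset obtained by flipping a single bit, in ascending flip-index
#' order, excluding the empty subset.
#'
#' @param mask Logical inclusion vector.
#' @return A list of logical masks.
#' @export
neighborhood <- function(mask) {
  mask <- as.logical(mask)
  out <- list()
  for (j in seq_along(mask)) {
    nb <- mask
    nb[j] <- !nb[j]
    if (any(nb)) out[[length(out) + 1L]] <- nb
  }
  out
}

# total order: higher fitness, then smaller subset, then lexicographically
# smallest mask (a 0 at the first differing position wins)
.better_subset <- function(fit_a, mask_a, fit_b, mask_b) {
  if (fit_a != fit_b) return(fit_a > fit_b)
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na != nb) return(na < nb)
  diff <- which(mask_a != mask_b)
  if (!length(diff)) return(FALSE)
  !mask_a[diff[1L]]
}

.new_selection_result <- function(method, mask, fitness, trajectory,
                                  iterations, n_evals, feature_names,
                                  moves = NULL) {
  structure(
    list(method = method,
         best_mask = stats::setNames(mask, feature_names),
         best_features = feature_names[mask],
         best_fitness = fitness,
         trajectory = trajectory,
         iterations_run = iterations,
         n_evaluations = n_evals,
         moves = moves),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method %s: %d/%d features, fitness %.4f (%d iterations, %d fitness evaluations)\n",
              x$method, sum(x$best_mask), length(x$best_mask),
              x$best_fitness, x$iterations_run, x$n_evaluations))
  cat("  selected:", paste(x$best_features, collapse = ", "), "\n")
  invisible(x)
}

# one tabu walk; ctx is shared (cache persists across restarts)
.mmas_walk <- function(ctx, config, seed) {
  d <- ctx$d
  current <- withr::with_seed(seed, {
    m <- as.logical(stats::rbinom(d, 1L, 0.5))
    while (!any(m)) m <- as.logical(stats::rbinom(d, 1L, 0.5))
    m
  })
  cur_fit <- subset_fitness(current, ctx)
  best <- current
  best_fit <- cur_fit
  meta <- .mask_key(current)           # FIFO buffer of visited subsets
  trajectory <- matrix(c(cur_fit, best_fit), 1L, 2L,
                       dimnames = list(NULL, c("current", "best")))
  moves <- list()
  stall <- 0L
  iters <- 1L
  threshold_hit <- function()
    !is.null(config$fitness_threshold) &&
      best_fit >= config$fitness_threshold
  while (iters < config$max_iter && stall < config$stall_limit &&
         !threshold_hit()) {
    nbs <- neighborhood(current)
    keys <- vapply(nbs, .mask_key, character(1))
    fits <- vapply(nbs, subset_fitness, numeric(1), ctx = ctx)
    tabu <- keys %in% meta
    aspirated <- tabu & fits > best_fit
    admissible <- !tabu | aspirated
    if (any(admissible)) {
      cand <- which(admissible)
      pick <- cand[1L]
      for (i in cand[-1L])
        if (.better_subset(fits[i], nbs[[i]], fits[pick], nbs[[pick]]))
          pick <- i
      forced <- FALSE
    } else {
      # deadlock: every neighbor is tabu and none aspirates; move to the
      # neighbor whose buffer entry is oldest
      pick <- which.min(match(keys, meta))
      forced <- TRUE
    }
    current <- nbs[[pick]]
    cur_fit <- fits[pick]
    meta <- c(meta, keys[pick])
    if (length(meta) > config$tenure) meta <- meta[-1L]
    improved <- .better_subset(cur_fit, current, best_fit, best)
    if (improved) {
      best <- current
      best_fit <- cur_fit
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    iters <- iters + 1L
    trajectory <- rbind(trajectory, c(cur_fit, best_fit))
    moves[[length(moves) + 1L]] <- list(
      iteration = iters, key = keys[pick], tabu = tabu[pick],
      aspirated = aspirated[pick], forced = forced, improved = improved)
  }
  list(best = best, best_fit = best_fit, trajectory = trajectory,
       iterations = iters, moves = moves)
}

#' Memory-based metaheuristic attribute selection
#'
#' Tabu-style local search over feature subsets. Each restart starts from a
#' random subset (every bit set with probability 1/2, rerolled if empty),
#' then repeatedly moves to the best admissible Hamming-1 neighbor — even a
#' worsening one, which is how the walk escapes local optima. Subsets held
#' in the fixed-capacity FIFO memory buffer are inadmissible unless they
#' would beat the global best (aspiration); if every neighbor is tabu and
#' none aspirates, the walk is forced to the neighbor with the oldest buffer
#' entry. Stops at `max_iter`, after `stall_limit` non-improving iterations,
#' or when `fitness_threshold` is reached. The best subset over all restarts
#' is returned; ties break towards higher fitness, then smaller subsets,
#' then the lexicographically smallest mask.
#'
#' @param table An imputed [data_table()] with at least two features.
#' @param config A [search_config()].
#' @param ctx Optional pre-built [fitness_context()] (it must match
#'   `table`/`config`); shared caching across calls.
#' @return A `selection_result`: best mask/features/fitness, per-iteration
#'   `trajectory` (current and running-best fitness, one matrix per
#'   restart), the move log, and evaluation counts.
#' @export
mmas_select <- function(table, config = search_config(), ctx = NULL) {
  stopifnot(inherits(table, "data_table"), inherits(config, "search_config"))
  if (n_features(table) < 2L) stop("need at least two features to search")
  if (is.null(ctx)) ctx <- fitness_context(table, config)
  runs <- lapply(seq_len(config$restarts), function(r)
    .mmas_walk(ctx, config, seed = config$seed + r - 1L))
  pick <- 1L
  for (i in seq_along(runs)[-1L])
    if (.better_subset(runs[[i]]$best_fit, runs[[i]]$best,
                       runs[[pick]]$best_fit, runs[[pick]]$best))
      pick <- i
  res <- .new_selection_result(
    method = "mmas",
    mask = runs[[pick]]$best,
    fitness = runs[[pick]]$best_fit,
    trajectory = lapply(runs, `[[`, "trajectory"),
    iterations = sum(vapply(runs, `[[`, integer(1), "iterations")),
    n_evals = ctx$n_evaluations$count %||% 0L,
    feature_names = names(table$features),
    moves = lapply(runs, `[[`, "moves"))
  res$restart_masks <- lapply(runs, `[[`, "best")
  res
}

#' Exhaustive subset-selection oracle
#'
#' Evaluates the fitness of every non-empty subset (2^d - 1 evaluations) and
#' returns the argmax under the same tie-break rule as [mmas_select()].
#' Guarded to d <= 20 features; intended as the ground-truth oracle for
#' validating the heuristics on small problems.
#'
#' @inheritParams mmas_select
#' @export
exhaustive_select <- function(table, config = search_config(), ctx = NULL) {
  stopifnot(inherits(table, "data_table"), inherits(config, "search_config"))
  d <- n_features(table)
  if (d > 20L) stop("exhaustive search is guarded to at most 20 features")
  if (d < 1L) stop("need at least one feature")
  if (is.null(ctx)) ctx <- fitness_context(table, config)
  best <- NULL
  best_fit <- -Inf
  n_eval <- 0L
  for (code in seq_len(2^d - 1L)) {
    mask <- bitwAnd(code, as.integer(2^(seq_len(d) - 1L))) > 0L
    fit <- subset_fitness(mask, ctx)
    n_eval <- n_eval + 1L
    if (is.null(best) || .better_subset(fit, mask, best_fit, best)) {
      best <- mask
      best_fit <- fit
    }
  }
  .new_selection_result("exhaustive", best, best_fit, trajectory = NULL,
                        iterations = n_eval, n_evals = n_eval,
                        feature_names = names(table$features))
}

#' Per-feature relevance scores on a 0-10 scale
#'
#' Runs `config$restarts` independent single-restart searches (seeds
#' `config$seed`, `config$seed + 1`, ...) and scores each feature as 10
#' times its selection frequency across the restart winners. Features
#' scoring below `drop_threshold` are flagged low-relevance, the candidates
#' to drop from the attribute set.
#'
#' @param table An imputed [data_table()].
#' @param config A [search_config()] with `restarts >= 2`.
#' @param drop_threshold Scores strictly below it are flagged (default 3).
#' @return An object of class `relevance_scores`: named numeric `scores` in
#'   \[0, 10\], logical `low_relevance`, and the per-restart masks.
#' @export
relevance_scores <- function(table, config = search_config(),
                             drop_threshold = 3) {
  stopifnot(inherits(table, "data_table"), inherits(config, "search_config"))
  if (config$restarts < 2L) stop("relevance scoring needs restarts >= 2")
  masks <- lapply(seq_len(config$restarts), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    cfg$restarts <- 1L
    mmas_select(table, cfg)$best_mask
  })
  freq <- Reduce(`+`, lapply(masks, as.numeric)) / length(masks)
  scores <- stats::setNames(10 * freq, names(table$features))
  structure(list(scores = scores,
                 low_relevance = scores < drop_threshold,
                 drop_threshold = drop_threshold,
                 restart_masks = masks),
            class = "relevance_scores")
}

#' @export
print.relevance_scores <- function(x, ...) {
  cat("<relevance_scores> attribute ranking on a 0-10 scale:\n")
  ord <- order(x$scores, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-20s %5.1f%s\n", names(x$scores)[i], x$scores[i],
                if (x$low_relevance[i]) "  (low relevance)" else ""))
  invisible(x)
}
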