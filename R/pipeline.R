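#' End-to-end pipeline configuration
#'
#' Controls the full flow: imputation, min-max normalization, memory-based
#' attribute selection, K-means outlier filtering, and stratified k-fold
#' Naive Bayes evaluation. The selection and clustering stages can each be
#' toggled off for ablation runs, and their order swapped: the default runs
#' selection before clustering (`order = "select-first"`);
#' `"cluster-first"` removes outlier records before searching.
#'
#' @param use_mmas Run the attribute-selection stage (default `TRUE`).
#' @param use_clustering Run the K-means outlier-filtering stage
#'   (default `TRUE`).
#' @param order `"select-first"` (default) or `"cluster-first"`.
#' @param impute,normalize Preprocessing toggles (default `TRUE`). The
#'   normalizer is fitted once on the full table before any later stage;
#'   set `refit_per_fold = TRUE` for the leakage-free variant that refits
#'   min-max scaling inside each evaluation training fold.
#' @param refit_per_fold See above (default `FALSE`).
#' @param search A [search_config()] for the selection stage; its seed is
#'   overridden by `seed`.
#' @param kmeans_k,z_cut,max_drop_frac,kmeans_max_iter Clustering-stage
#'   parameters (defaults: 2 clusters, 3-sigma cut, at most 10% of rows
#'   dropped, 300 Lloyd iterations).
#' @param outlier_axis `"rows"` (default) drops non-complying records;
#'   `"columns"` instead drops features uncorrelated with the 2-cluster
#'   structure (see [noncomplying_features()]).
#' @param cv_k Evaluation folds (default 10).
#' @param stratified Stratified evaluation folds (default `TRUE`).
#' @param alpha,var_floor Naive Bayes hyperparameters.
#' @param seed Global seed; stage seeds are derived from it (`seed` for
#'   selection and folds, `seed + 1` for the clustering initialization).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(use_mmas = TRUE, use_clustering = TRUE,
                            order = c("select-first", "cluster-first"),
                            impute = TRUE, normalize = TRUE,
                            refit_per_fold = FALSE,
                            search = search_config(),
                            kmeans_k = 2L, z_cut = 3, max_drop_frac = 0.1,
                            kmeans_max_iter = 300L,
                            outlier_axis = c("rows", "columns"),
                            cv_k = 10L, stratified = TRUE,
                            alpha = 1, var_floor = 1e-9, seed = 1L) {
  order <- match.arg(order)
  outlier_axis <- match.arg(outlier_axis)
  stopifnot(inherits(search, "search_config"))
  search$seed <- as.integer(seed)
  search$alpha <- alpha
  search$var_floor <- var_floor
  structure(list(use_mmas = use_mmas, use_clustering = use_clustering,
                 order = order, impute = impute, normalize = normalize,
                 refit_per_fold = refit_per_fold, search = search,
                 kmeans_k = as.integer(kmeans_k), z_cut = z_cut,
                 max_drop_frac = max_drop_frac,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 outlier_axis = outlier_axis,
                 cv_k = as.integer(cv_k), stratified = stratified,
                 alpha = alpha, var_floor = var_floor,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.cluster_stage <- function(table, config) {
  enc <- encode_features(table)
  model <- fit_kmeans(enc, k = config$kmeans_k, seed = config$seed + 1L,
                      max_iter = config$kmeans_max_iter)
  if (config$outlier_axis == "rows") {
    res <- remove_outliers(table, model, outlier_rule(config$z_cut),
                           max_drop_frac = config$max_drop_frac)
    list(table = res$table, dropped_rows = res$dropped,
         dropped_features = integer(0), model = model)
  } else {
    bad <- noncomplying_features(table, model)
    out <- if (length(bad)) subset_table(table, cols = -bad) else table
    list(table = out, dropped_rows = integer(0),
         dropped_features = bad, model = model)
  }
}

#' Run the full risk-assessment pipeline
#'
#' Executes the enabled stages in the configured order and evaluates the
#' resulting table with stratified k-fold Naive Bayes cross-validation.
#' With every optional stage disabled the result is identical to calling
#' [cross_validate()] on the input. The returned report carries per-stage
#' provenance (what was dropped and why), all metrics, the latency, and an
#' echo of the configuration and seed, so the run can be reproduced
#' exactly.
#'
#' @param table A [data_table()].
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`.
#' @export
run_pipeline <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "data_table"), inherits(config, "pipeline_config"))
  n_initial_rows <- n_rows(table)
  n_initial_features <- n_features(table)
  if (config$impute) table <- impute_missing(table)
  if (config$normalize && !config$refit_per_fold)
    table <- apply_normalizer(table, fit_normalizer(table))
  selection <- NULL
  cluster_info <- NULL
  stages <- if (config$order == "select-first") c("select", "cluster")
            else c("cluster", "select")
  for (stage in stages) {
    if (stage == "select" && config$use_mmas) {
      selection <- mmas_select(table, config$search)
      table <- subset_table(table, cols = selection$best_mask)
    }
    if (stage == "cluster" && config$use_clustering) {
      cluster_info <- .cluster_stage(table, config)
      table <- cluster_info$table
      if (n_rows(table) == 0L)
        stop("all rows were removed as outliers; relax z_cut")
    }
  }
  cv <- cross_validate(table, k = config$cv_k, seed = config$seed,
                       alpha = config$alpha, var_floor = config$var_floor,
                       stratified = config$stratified,
                       refit_normalizer = config$normalize &&
                         config$refit_per_fold)
  structure(
    list(config = config, seed = config$seed,
         n_initial_rows = n_initial_rows,
         n_initial_features = n_initial_features,
         selected_features = if (is.null(selection)) names(table$features)
                             else selection$best_features,
         selection = selection,
         dropped_rows = if (is.null(cluster_info)) integer(0)
                        else cluster_info$dropped_rows,
         dropped_features = if (is.null(cluster_info)) integer(0)
                            else cluster_info$dropped_features,
         n_final_rows = n_rows(table), n_final_features = n_features(table),
         cv = cv, metrics = cv$metrics, latency_s = latency(cv)),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d rows x %d features -> %d rows x %d features\n",
              x$n_initial_rows, x$n_initial_features,
              x$n_final_rows, x$n_final_features))
  if (!is.null(x$selection))
    cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  if (length(x$dropped_rows))
    cat("  outlier rows dropped:", length(x$dropped_rows), "\n")
  print(x$cv)
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report A [run_pipeline()] result.
#' @param path Output path.
#' @export
write_pipeline_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- list(
    seed = report$seed,
    config = report$config[c("use_mmas", "use_clustering", "order",
                             "impute", "normalize", "refit_per_fold",
                             "kmeans_k", "z_cut", "cv_k", "alpha", "seed")],
    selected_features = report$selected_features,
    dropped_rows = report$dropped_rows,
    n_final_rows = report$n_final_rows,
    fold_accuracies = report$cv$fold_accuracies,
    mean_accuracy = report$cv$mean_accuracy,
    metrics = report$metrics,
    latency_s = report$latency_s)
  write_report(out, path)
}

#' Compare selection heuristics on one table
#'
#' Runs each requested method with the shared fitness, evaluates the
#' reduced table by cross-validation, and returns one row per method with
#' instance/attribute counts and the full metric suite — the standard
#' side-by-side comparison layout. `"none"` evaluates the full attribute
#' set without selection.
#'
#' @param table A [data_table()] (imputed/normalized as desired, or use
#'   [run_pipeline()] for the full flow).
#' @param methods Subset of `"mmas"`, `"greedy_stepwise"`, `"best_first"`,
#'   `"genetic"`, `"pso"`, `"exhaustive"`, `"none"`.
#' @param config A [search_config()] shared by all methods.
#' @param cv_k Evaluation folds (default 10).
#' @return A data frame: method, n_instances, n_initial, n_selected,
#'   fitness, accuracy, precision, recall, f_score, mcc, latency_s.
#' @export
run_compare <- function(table,
                        methods = c("mmas", "greedy_stepwise", "best_first",
                                    "genetic", "pso"),
                        config = search_config(), cv_k = 10L) {
  stopifnot(inherits(table, "data_table"), length(methods) >= 1L)
  known <- c("mmas", "greedy_stepwise", "best_first", "genetic", "pso",
             "exhaustive", "none")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method name: ", paste(bad, collapse = ", "))
  ctx <- fitness_context(table, config)
  rows <- lapply(methods, function(m) {
    sel <- switch(m,
      mmas = mmas_select(table, config, ctx = ctx),
      greedy_stepwise = greedy_stepwise(table, config, ctx = ctx),
      best_first = best_first(table, config, ctx = ctx),
      genetic = genetic_select(table, config, ctx = ctx),
      pso = pso_select(table, config, ctx = ctx),
      exhaustive = exhaustive_select(table, config, ctx = ctx),
      none = NULL)
    reduced <- if (is.null(sel)) table
               else subset_table(table, cols = sel$best_mask)
    cv <- cross_validate(reduced, k = cv_k, seed = config$seed,
                         alpha = config$alpha,
                         var_floor = config$var_floor)
    data.frame(method = m,
               n_instances = n_rows(table),
               n_initial = n_features(table),
               n_selected = n_features(reduced),
               fitness = if (is.null(sel)) NA_real_ else sel$best_fitness,
               accuracy = cv$metrics$accuracy,
               precision = cv$metrics$precision,
               recall = cv$metrics$recall,
               f_score = cv$metrics$f_score,
               mcc = cv$metrics$mcc,
               latency_s = latency(cv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published benchmark metrics for the four UCI chronic-disease datasets
#'
#' Precision, recall and F-score (percent) reported for Naive Bayes with
#' and without memory-based attribute selection on the diabetes, breast
#' cancer, heart disease and hepatitis benchmark datasets, shipped for
#' consistency checking of the metric identities.
#'
#' @return A data frame with columns `dataset`, `condition`, `precision`,
#'   `recall`, `f_score`.
#' @export
published_metrics <- function() {
  path <- system.file("extdata", "published_metrics.csv",
                      package = "mmaselect", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
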