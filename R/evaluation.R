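#' Stratified k-fold partition
#'
#' Shuffles each class independently (reproducibly by `seed`) and deals its
#' members round-robin across folds, so per-class counts differ by at most
#' one between folds and the folds partition all row indices.
#'
#' @param labels Per-row class tokens.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of `k` integer index vectors.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs at least k = ", k, " members; smallest has ",
         min(counts))
  folds <- vector("list", k)
  withr::with_seed(seed, {
    # random fold offset per class so the remainder rows do not pile up in
    # the first folds
    for (cls in names(counts)) {
      idx <- sample(which(labels == cls))
      start <- sample.int(k, 1L)
      fold_of <- ((seq_along(idx) - 1L + start) %% k) + 1L
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[fold_of == f])
    }
  })
  lapply(folds, sort)
}

#' Unstratified k-fold partition
#'
#' Plain random split: all indices shuffled once and dealt round-robin.
#'
#' @inheritParams stratified_folds
#' @export
plain_folds <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  n <- length(labels)
  if (n < k) stop("need at least k rows")
  idx <- withr::with_seed(seed, sample.int(n))
  fold_of <- ((seq_len(n) - 1L) %% k) + 1L
  lapply(seq_len(k), function(f) sort(idx[fold_of == f]))
}

#' Tally a binary confusion matrix
#'
#' @param truth,predicted Class tokens.
#' @param positive The token counted as the positive class.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  tp <- truth == positive
  pp <- predicted == positive
  structure(list(TP = sum(tp & pp), TN = sum(!tp & !pp),
                 FP = sum(!tp & pp), FN = sum(tp & !pp)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Metric suite from confusion counts
#'
#' Accuracy (TP+TN)/total, precision TP/(TP+FP), recall TP/(TP+FN), F-score
#' 2TP/(2TP+FP+FN) (the harmonic mean of precision and recall), and the
#' Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric with a zero denominator is reported as 0 with a warning.
#'
#' @param c A [confusion_counts()] object.
#' @return A named list: `accuracy`, `precision`, `recall`, `f_score`, `mcc`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- c$TP; tn <- c$TN; fp <- c$FP; fn <- c$FN
  total <- tp + tn + fp + fn
  if (total == 0L) stop("confusion counts are empty")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " has a zero denominator; reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f_score <- safe(2 * tp, 2 * tp + fp + fn, "F-score")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "MCC")
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f_score = f_score, mcc = mcc)
}

#' F-score from a precision/recall pair
#'
#' The harmonic-mean identity 2PR/(P+R), algebraically equal to
#' 2TP/(2TP+FP+FN) whenever P+R > 0. Inputs and output share the same scale
#' (fractions or percentages).
#'
#' @param precision,recall Non-negative numbers (vectorized).
#' @export
f_score_from_pr <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Cross-validate the Naive Bayes classifier
#'
#' For each of `k` folds the classifier is fitted on the remaining folds and
#' evaluated on the held-out one. Reports per-fold accuracies, their mean,
#' the confusion counts pooled over all held-out predictions, the metric
#' suite on the pooled counts, and accumulated wall-clock train/test times.
#'
#' @param table An imputed [data_table()].
#' @param k Number of folds (default 10).
#' @param seed Fold seed.
#' @param alpha,var_floor Passed to [fit_nb()].
#' @param stratified Use [stratified_folds()] (default) or [plain_folds()].
#' @param refit_normalizer Refit min-max normalization on each training fold
#'   and apply it to the held-out fold (leakage-free mode); default `FALSE`,
#'   i.e. the table is used exactly as given.
#' @return An object of class `cv_result`.
#' @export
cross_validate <- function(table, k = 10L, seed = 1L, alpha = 1,
                           var_floor = 1e-9, stratified = TRUE,
                           refit_normalizer = FALSE) {
  stopifnot(inherits(table, "data_table"))
  folds <- if (stratified) stratified_folds(table$labels, k, seed)
           else plain_folds(table$labels, k, seed)
  fold_acc <- numeric(length(folds))
  truth_all <- pred_all <- character(0)
  t_train <- t_test <- 0
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train <- subset_table(table, rows = -test_idx)
    test <- subset_table(table, rows = test_idx)
    if (refit_normalizer) {
      params <- fit_normalizer(train)
      train <- apply_normalizer(train, params)
      test <- apply_normalizer(test, params)
    }
    t0 <- proc.time()[["elapsed"]]
    model <- fit_nb(train, alpha = alpha, var_floor = var_floor)
    t1 <- proc.time()[["elapsed"]]
    pred <- predict(model, test)
    t2 <- proc.time()[["elapsed"]]
    t_train <- t_train + (t1 - t0)
    t_test <- t_test + (t2 - t1)
    fold_acc[f] <- mean(pred == test$labels)
    truth_all <- c(truth_all, test$labels)
    pred_all <- c(pred_all, pred)
  }
  pooled <- confusion_counts(truth_all, pred_all, table$positive_class)
  structure(
    list(fold_accuracies = fold_acc, mean_accuracy = mean(fold_acc),
         pooled_confusion = pooled, metrics = compute_metrics(pooled),
         train_time_s = t_train, test_time_s = t_test,
         k = length(folds), seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold, mean accuracy %.4f (folds %.3f-%.3f)\n",
              x$k, x$mean_accuracy, min(x$fold_accuracies),
              max(x$fold_accuracies)))
  m <- x$metrics
  cat(sprintf("  precision %.4f, recall %.4f, F %.4f, MCC %.4f; latency %.3fs\n",
              m$precision, m$recall, m$f_score, m$mcc, latency(x)))
  invisible(x)
}

#' Latency of a cross-validation run
#'
#' Model training time plus model testing time, in seconds. Hardware
#' dependent; reported, never asserted.
#'
#' @param result A [cross_validate()] result.
#' @export
latency <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  if (result$train_time_s < 0 || result$test_time_s < 0)
    stop("recorded times must be non-negative")
  result$train_time_s + result$test_time_s
}
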