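#' Fit a mixed Gaussian/categorical Naive Bayes classifier
#'
#' Class priors are the training class frequencies. Each numeric feature gets
#' a per-class Gaussian with maximum-likelihood mean and variance (variance
#' floored at `var_floor` so constant columns never divide by zero); each
#' categorical feature gets per-class Laplace-smoothed level frequencies,
#' (count + alpha) / (n_class + alpha * n_levels), over the levels observed
#' in the training table.
#'
#' @param table An imputed [data_table()]; both classes must be present.
#' @param alpha Laplace smoothing constant (default 1).
#' @param var_floor Variance floor (default 1e-9, scaled for min-max
#'   normalized features).
#' @return An object of class `nb_model`.
#' @export
fit_nb <- function(table, alpha = 1, var_floor = 1e-9) {
  stopifnot(inherits(table, "data_table"), alpha >= 0, var_floor > 0)
  if (anyNA(table$features)) stop("impute missing values before fitting")
  enc <- .nb_encode(table)
  y <- match(table$labels, table$class_names)
  if (length(unique(y)) < 2L)
    stop("both classes must appear in the training rows")
  core <- .nb_fit_core(enc$Xnum, enc$Xcat, enc$cat_levels, y, alpha, var_floor)
  structure(
    c(core,
      list(feature_names = names(table$features),
           column_kinds = table$column_kinds,
           cat_levels = enc$cat_levels,
           num_cols = enc$num_cols, cat_cols = enc$cat_cols,
           class_names = table$class_names,
           alpha = alpha, var_floor = var_floor)),
    class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> classes %s/%s, priors %.3f/%.3f, %d numeric + %d categorical features\n",
              x$class_names[1], x$class_names[2], x$priors[1], x$priors[2],
              length(x$num_cols), length(x$cat_cols)))
  invisible(x)
}

# split features into numeric matrix + integer-coded categorical matrix
.nb_encode <- function(table, levels = NULL) {
  .nb_encode_frame(table$features, table$column_kinds, levels)
}

.nb_encode_frame <- function(features, kinds, levels = NULL) {
  num_cols <- which(kinds == "numeric")
  cat_cols <- which(kinds == "categorical")
  Xnum <- if (length(num_cols))
    as.matrix(as.data.frame(lapply(features[num_cols], as.numeric)))
  else matrix(0, nrow(features), 0L)
  cat_levels <- vector("list", length(cat_cols))
  Xcat <- matrix(0L, nrow(features), length(cat_cols))
  for (i in seq_along(cat_cols)) {
    col <- as.character(features[[cat_cols[i]]])
    levs <- if (is.null(levels)) sort(unique(col)) else levels[[i]]
    cat_levels[[i]] <- levs
    code <- match(col, levs)
    code[is.na(code)] <- length(levs) + 1L  # unseen level sentinel
    Xcat[, i] <- code
  }
  list(Xnum = Xnum, Xcat = Xcat, cat_levels = cat_levels,
       num_cols = num_cols, cat_cols = cat_cols)
}

# core estimator on encoded matrices; y in {1, 2}
.nb_fit_core <- function(Xnum, Xcat, cat_levels, y, alpha, var_floor) {
  n <- length(y)
  counts <- tabulate(y, nbins = 2L)
  priors <- counts / n
  means <- vars <- matrix(0, 2L, ncol(Xnum))
  for (c in 1:2) {
    idx <- y == c
    if (ncol(Xnum)) {
      Xc <- Xnum[idx, , drop = FALSE]
      means[c, ] <- colMeans(Xc)
      vars[c, ] <- pmax(colMeans(Xc^2) - means[c, ]^2, var_floor)
    }
  }
  cat_logprob <- vector("list", ncol(Xcat))
  for (i in seq_len(ncol(Xcat))) {
    L <- length(cat_levels[[i]])
    pm <- matrix(0, L + 1L, 2L)  # last row: unseen-level smoothing mass
    for (c in 1:2) {
      cnt <- tabulate(Xcat[y == c, i], nbins = L)
      pm[, c] <- c((cnt + alpha) / (counts[c] + alpha * L),
                   alpha / (counts[c] + alpha * L))
    }
    cat_logprob[[i]] <- log(pm)
  }
  list(priors = priors, means = means, vars = vars,
       cat_logprob = cat_logprob)
}

# per-class log-joint for encoded rows; returns n x 2 matrix
.nb_logjoint <- function(core, Xnum, Xcat) {
  n <- max(nrow(Xnum), nrow(Xcat), 1L)
  ll <- matrix(rep(log(core$priors), each = n), n, 2L)
  for (c in 1:2) {
    if (ncol(Xnum)) {
      v <- core$vars[c, ]
      m <- core$means[c, ]
      ll[, c] <- ll[, c] -
        0.5 * sum(log(2 * pi * v)) -
        0.5 * ((Xnum^2) %*% (1 / v) - 2 * (Xnum %*% (m / v)) + sum(m^2 / v))
    }
    for (i in seq_len(ncol(Xcat)))
      ll[, c] <- ll[, c] + core$cat_logprob[[i]][Xcat[, i], c]
  }
  ll
}

# argmax with ties to the larger prior, then to the lower class index
.nb_argmax <- function(ll, priors) {
  pred <- ifelse(ll[, 2L] > ll[, 1L], 2L, 1L)
  tie <- ll[, 1L] == ll[, 2L]
  if (any(tie)) pred[tie] <- if (priors[2L] > priors[1L]) 2L else 1L
  pred
}

.nb_newdata <- function(object, newdata) {
  if (inherits(newdata, "data_table")) newdata <- newdata$features
  stopifnot(is.data.frame(newdata))
  if (!all(object$feature_names %in% names(newdata)))
    stop("newdata lacks model features")
  newdata <- newdata[object$feature_names]
  if (anyNA(newdata)) stop("impute missing values before predicting")
  kinds <- vapply(newdata, function(col)
    if (is.numeric(col)) "numeric" else "categorical", character(1))
  if (!identical(unname(kinds), unname(object$column_kinds)))
    stop("newdata column kinds differ from the training table")
  .nb_encode_frame(newdata, kinds, levels = object$cat_levels)
}

#' Posterior class probabilities and class predictions
#'
#' Posteriors are prior times the product of per-feature likelihoods,
#' evaluated in log space and normalized to sum to one. An unseen categorical
#' level receives the Laplace smoothing mass alpha / (n_class + alpha *
#' n_levels), never zero. Ties in `type = "class"` go to the class with the
#' larger prior, then to the lower class index.
#'
#' @param object An [fit_nb()] model.
#' @param newdata A data frame or [data_table()] with the model's features.
#' @param type `"class"` for labels, `"prob"` for the posterior matrix.
#' @param ... Unused.
#' @return A character vector of labels, or an n x 2 matrix of posteriors
#'   with columns named by the class tokens.
#' @export
predict.nb_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  enc <- .nb_newdata(object, newdata)
  ll <- .nb_logjoint(object, enc$Xnum, enc$Xcat)
  if (type == "class")
    return(object$class_names[.nb_argmax(ll, object$priors)])
  mx <- pmax(ll[, 1L], ll[, 2L])
  p <- exp(ll - mx)
  p <- p / rowSums(p)
  colnames(p) <- object$class_names
  p
}
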