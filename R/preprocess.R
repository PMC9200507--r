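#' Impute missing cells
#'
#' Numeric missing cells are replaced by the column mean of the observed
#' values; categorical missing cells by the column mode (most frequent level,
#' ties broken towards the lexicographically smallest). Idempotent.
#'
#' @param table A [data_table()].
#' @return A `data_table` with no missing cells.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "data_table"))
  feats <- table$features
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss))
      stop("column '", names(feats)[j], "' is fully missing")
    if (table$column_kinds[j] == "numeric") {
      col[miss] <- mean(col[!miss])
    } else {
      tab <- table(col[!miss])
      top <- names(tab)[tab == max(tab)]
      col[miss] <- sort(top)[1L]
    }
    feats[[j]] <- col
  }
  out <- table
  out$features <- feats
  out
}

#' Fit a min-max normalizer
#'
#' Records the observed minimum and maximum of every numeric column, the
#' parameters of the rescaling p' = (p - min_p) / (max_p - min_p) that maps
#' each attribute onto \[0, 1\].
#'
#' @param table A [data_table()] (impute first: `NA` cells are not allowed).
#' @return An object of class `normalization_params`: named lists `min_p`
#'   and `max_p` over the numeric columns.
#' @export
fit_normalizer <- function(table) {
  stopifnot(inherits(table, "data_table"))
  if (nrow(table$features) == 0L) stop("cannot fit a normalizer on 0 rows")
  num <- which(table$column_kinds == "numeric")
  if (anyNA(table$features[num])) stop("impute missing values before fitting")
  mins <- lapply(table$features[num], min)
  maxs <- lapply(table$features[num], max)
  structure(list(min_p = mins, max_p = maxs,
                 columns = names(table$features)[num]),
            class = "normalization_params")
}

#' Apply a fitted min-max normalizer
#'
#' Maps every numeric cell p to (p - min_p) / (max_p - min_p). A constant
#' column (max_p == min_p) maps to 0 everywhere, keeping the output inside
#' \[0, 1\] where the rescaling itself is undefined. Categorical columns pass
#' through unchanged (they are one-hot expanded only where a Euclidean
#' representation is needed, see [encode_features()]).
#'
#' @param table A [data_table()] with the same numeric columns the params
#'   were fitted on.
#' @param params A [fit_normalizer()] result.
#' @return The normalized `data_table`.
#' @export
apply_normalizer <- function(table, params) {
  stopifnot(inherits(table, "data_table"),
            inherits(params, "normalization_params"))
  num <- names(table$features)[table$column_kinds == "numeric"]
  if (!setequal(num, params$columns))
    stop("normalizer was fitted on different columns")
  feats <- table$features
  for (nm in params$columns) {
    lo <- params$min_p[[nm]]
    hi <- params$max_p[[nm]]
    feats[[nm]] <- if (hi > lo) (feats[[nm]] - lo) / (hi - lo)
                   else rep(0, length(feats[[nm]]))
  }
  out <- table
  out$features <- feats
  out
}

#' Numeric (one-hot) encoding of a data table
#'
#' Builds the real-vector representation used by Euclidean-distance K-means:
#' numeric columns pass through; each categorical column expands to one 0/1
#' indicator column per observed level (levels sorted). Column names are
#' `feature` or `feature=level`.
#'
#' @param table An imputed [data_table()].
#' @return A numeric matrix with `n_rows` rows; attribute `feature_of` maps
#'   each matrix column back to the originating feature index.
#' @export
encode_features <- function(table) {
  stopifnot(inherits(table, "data_table"))
  if (anyNA(table$features)) stop("impute missing values before encoding")
  cols <- list()
  owner <- integer(0)
  for (j in seq_along(table$features)) {
    nm <- names(table$features)[j]
    col <- table$features[[j]]
    if (table$column_kinds[j] == "numeric") {
      cols[[nm]] <- as.numeric(col)
      owner <- c(owner, j)
    } else {
      for (lev in sort(unique(col))) {
        cols[[paste0(nm, "=", lev)]] <- as.numeric(col == lev)
        owner <- c(owner, j)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  attr(m, "feature_of") <- owner
  m
}
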