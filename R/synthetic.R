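#' Specification of a synthetic clinical-style dataset
#'
#' Describes a tabular binary-class dataset with planted ground truth:
#' class-informative features (shifted-mean Gaussians, or categoricals with
#' class-biased level odds), redundant affine copies, pure-noise features,
#' optional missing cells and planted extreme-distance outlier rows. The
#' defaults mirror a mid-sized clinical screening table: 768 records (the
#' size of the classic PIMA diabetes file), 3 informative and 5 noise
#' features, a within-class-standard-deviation class separation of 1.5 per
#' informative feature, and balanced classes.
#'
#' @param n_rows Number of records (default 768).
#' @param n_informative,n_redundant,n_noise Feature counts by role
#'   (defaults 3, 0, 5; at least 2 features in total).
#' @param effect_size Class separation delta per informative feature, in
#'   within-class standard deviations (default 1.5).
#' @param categorical_fraction Probability that an informative or noise
#'   feature is generated as a 3-level categorical instead of a Gaussian
#'   (default 0).
#' @param missing_rate Fraction of feature cells blanked to `NA`
#'   (default 0).
#' @param class_balance P(class "1") (default 0.5).
#' @param outlier_rows Rows planted at extreme centroid distance
#'   (default 0).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows = 768L, n_informative = 3L,
                           n_redundant = 0L, n_noise = 5L,
                           effect_size = 1.5, categorical_fraction = 0,
                           missing_rate = 0, class_balance = 0.5,
                           outlier_rows = 0L, seed = 1L) {
  stopifnot(n_rows >= 4L, n_informative >= 0L, n_redundant >= 0L,
            n_noise >= 0L, n_informative + n_redundant + n_noise >= 2L,
            effect_size >= 0, categorical_fraction >= 0,
            categorical_fraction <= 1, missing_rate >= 0, missing_rate < 1,
            class_balance > 0, class_balance < 1, outlier_rows >= 0L)
  if (n_redundant > 0L && n_informative == 0L)
    stop("redundant features need at least one informative source")
  structure(list(n_rows = as.integer(n_rows),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 effect_size = effect_size,
                 categorical_fraction = categorical_fraction,
                 missing_rate = missing_rate,
                 class_balance = class_balance,
                 outlier_rows = as.integer(outlier_rows),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# per-class level odds for a 3-level informative categorical: logits
# +/- effect_size/4 on the outer levels, mirrored between classes
.cat_class_probs <- function(effect_size) {
  logit <- c(1, 0, -1) * effect_size / 4
  p0 <- exp(logit) / sum(exp(logit))
  p1 <- exp(-logit) / sum(exp(-logit))
  rbind(p0, p1)
}

#' Generate a synthetic clinical-style table with known ground truth
#'
#' Numeric informative features are drawn Normal(-delta/2, 1) for class "0"
#' and Normal(+delta/2, 1) for class "1"; categorical informatives use
#' mirrored class-biased level odds (see details in the methods vignette).
#' Redundant features are affine copies of informative ones plus
#' Normal(0, 0.05) noise; noise features are class-independent. The
#' Bayes-optimal accuracy of the numeric-Gaussian part is computed in closed
#' form from the Mahalanobis separation delta * sqrt(F) and the class
#' priors.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `table` (a [data_table()]), index vectors `informative`,
#'   `redundant`, `noise`, planted `outlier_indices`, and `bayes_accuracy`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_rows
  withr::with_seed(spec$seed, {
    y <- stats::rbinom(n, 1L, spec$class_balance)
    # degenerate draw guard: both classes must exist
    if (all(y == y[1L])) y[1:2] <- c(0L, 1L)
    feats <- list()
    kinds <- character(0)
    role <- character(0)
    delta <- spec$effect_size
    cat_p <- .cat_class_probs(delta)
    levels3 <- c("a", "b", "c")
    num_informative_sources <- list()
    for (j in seq_len(spec$n_informative)) {
      nm <- sprintf("inf_%02d", j)
      if (stats::runif(1) < spec$categorical_fraction) {
        col <- character(n)
        for (c in 0:1) {
          idx <- y == c
          col[idx] <- sample(levels3, sum(idx), replace = TRUE,
                             prob = cat_p[c + 1L, ])
        }
        feats[[nm]] <- col
        kinds <- c(kinds, "categorical")
      } else {
        col <- stats::rnorm(n, mean = ifelse(y == 1L, delta / 2, -delta / 2))
        feats[[nm]] <- col
        kinds <- c(kinds, "numeric")
        num_informative_sources[[length(num_informative_sources) + 1L]] <- col
      }
      role <- c(role, "informative")
    }
    numeric_inf_count <- length(num_informative_sources)
    for (j in seq_len(spec$n_redundant)) {
      nm <- sprintf("red_%02d", j)
      src_j <- ((j - 1L) %% spec$n_informative) + 1L
      src <- feats[[sprintf("inf_%02d", src_j)]]
      if (is.numeric(src)) {
        a <- stats::runif(1, 0.5, 2)
        b <- stats::runif(1, -1, 1)
        feats[[nm]] <- a * src + b + stats::rnorm(n, sd = 0.05)
        kinds <- c(kinds, "numeric")
      } else {
        # redundant copy of a categorical: same levels with 5% relabel noise
        col <- src
        flip <- stats::runif(n) < 0.05
        col[flip] <- sample(levels3, sum(flip), replace = TRUE)
        feats[[nm]] <- col
        kinds <- c(kinds, "categorical")
      }
      role <- c(role, "redundant")
    }
    for (j in seq_len(spec$n_noise)) {
      nm <- sprintf("noi_%02d", j)
      if (stats::runif(1) < spec$categorical_fraction) {
        feats[[nm]] <- sample(levels3, n, replace = TRUE)
        kinds <- c(kinds, "categorical")
      } else {
        feats[[nm]] <- stats::rnorm(n)
        kinds <- c(kinds, "numeric")
      }
      role <- c(role, "noise")
    }
    df <- as.data.frame(feats, stringsAsFactors = FALSE)
    if (spec$missing_rate > 0) {
      for (j in seq_along(df)) {
        blank <- stats::runif(n) < spec$missing_rate
        # never blank a full column
        if (all(blank)) blank[sample.int(n, 1L)] <- FALSE
        df[[j]][blank] <- NA
      }
    }
    tab <- data_table(df, labels = as.character(y),
                      class_names = c("0", "1"), positive_class = "1")
    out_idx <- integer(0)
    if (spec$outlier_rows > 0L) {
      planted <- plant_outliers(tab, count = spec$outlier_rows,
                                magnitude = 100,
                                seed = spec$seed + 1L)
      tab <- planted$table
      out_idx <- planted$indices
    }
    pi1 <- spec$class_balance
    sep <- delta * sqrt(numeric_inf_count)
    bayes <- if (sep > 0) {
      cutoff <- log((1 - pi1) / pi1) / sep
      pi1 * stats::pnorm(sep / 2 - cutoff) +
        (1 - pi1) * stats::pnorm(sep / 2 + cutoff)
    } else {
      max(pi1, 1 - pi1)
    }
    list(table = tab,
         informative = which(role == "informative"),
         redundant = which(role == "redundant"),
         noise = which(role == "noise"),
         outlier_indices = out_idx,
         bayes_accuracy = bayes)
  })
}

#' Plant extreme-distance outlier rows
#'
#' Appends `count` rows whose numeric coordinates sit at `magnitude` times
#' the data's radius (the maximum distance of any row from the numeric
#' centroid) from that centroid, in independent random directions.
#' Categorical cells and labels of the planted rows are sampled uniformly
#' from the observed values. The planted rows are by construction the
#' `count` largest centroid distances in the augmented table.
#'
#' @param table A [data_table()] with at least one numeric feature and no
#'   missing numeric cells.
#' @param count Number of rows to plant (0 returns the table unchanged).
#' @param magnitude Distance multiple of the data radius; must exceed 1.
#' @param seed Integer seed.
#' @return A list: `table` (augmented) and `indices` of the planted rows.
#' @export
plant_outliers <- function(table, count, magnitude = 100, seed = 1L) {
  stopifnot(inherits(table, "data_table"), count >= 0L)
  if (magnitude <= 1) stop("magnitude must exceed 1")
  if (count == 0L) return(list(table = table, indices = integer(0)))
  num <- which(table$column_kinds == "numeric")
  if (!length(num)) stop("need at least one numeric feature to plant outliers")
  X <- as.matrix(as.data.frame(lapply(table$features[num], as.numeric)))
  if (anyNA(X)) stop("impute missing numeric values before planting outliers")
  center <- colMeans(X)
  radius <- max(sqrt(rowSums(sweep(X, 2L, center)^2)))
  if (radius == 0) radius <- 1
  withr::with_seed(seed, {
    new_rows <- table$features[sample.int(n_rows(table), count,
                                          replace = TRUE), , drop = FALSE]
    rownames(new_rows) <- NULL
    for (i in seq_len(count)) {
      dir <- stats::rnorm(length(num))
      dir <- dir / sqrt(sum(dir^2))
      new_rows[i, num] <- as.list(center + magnitude * radius * dir)
    }
    new_labels <- sample(table$labels, count, replace = TRUE)
  })
  feats <- rbind(table$features, new_rows)
  rownames(feats) <- NULL
  aug <- data_table(feats, labels = c(table$labels, new_labels),
                    class_names = table$class_names,
                    positive_class = table$positive_class)
  list(table = aug, indices = n_rows(table) + seq_len(count))
}
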