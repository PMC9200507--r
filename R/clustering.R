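#' Euclidean distance between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return The square root of the summed squared coordinate differences.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  sqrt(sum((a - b)^2))
}

# n x k matrix of squared distances from rows of X to each centroid
.sqdist_to_centroids <- function(X, centroids) {
  xx <- rowSums(X^2)
  cc <- rowSums(centroids^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(centroids)
  d2[d2 < 0] <- 0  # numerical guard
  d2
}

#' Fit K-means by Lloyd iteration
#'
#' Centroids are initialized at k distinct rows drawn uniformly by `seed`
#' (Forgy initialization; `init = "kmeans++"` uses distance-weighted seeding
#' instead). Rows are assigned to the nearest centroid (ties to the lowest
#' cluster index), centroids recomputed as cluster means, until assignments
#' stop changing or `max_iter` is reached. An emptied cluster is reseeded at
#' the row currently farthest from its own centroid.
#'
#' @param rows Numeric matrix, one observation per row (see
#'   [encode_features()]).
#' @param k Number of clusters (default 2, the usual setting for separating
#'   presence/absence structure in clinical tables).
#' @param seed Integer seed; the fit is fully reproducible.
#' @param max_iter Iteration cap.
#' @param init `"forgy"` or `"kmeans++"`.
#' @return An object of class `cluster_model`: `centroids` (k x p),
#'   `assignments` (1-based), `inertia`, `k`, `n_iterations`, and
#'   `inertia_trace`, the within-cluster sum of squares after every update
#'   (non-increasing by construction of the Lloyd step).
#' @export
fit_kmeans <- function(rows, k = 2L, seed = 1L, max_iter = 300L,
                       init = c("forgy", "kmeans++")) {
  init <- match.arg(init)
  X <- as.matrix(rows)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k < 1L) stop("k must be at least 1")
  if (n < k) stop("need at least k rows (", k, "), got ", n)
  centroids <- withr::with_seed(seed, {
    if (init == "forgy") {
      X[sample.int(n, k), , drop = FALSE]
    } else {
      idx <- sample.int(n, 1L)
      for (j in seq_len(k - 1L)) {
        d2 <- .sqdist_to_centroids(X, X[idx, , drop = FALSE])
        mind2 <- apply(d2, 1L, min)
        mind2[idx] <- 0
        p <- if (sum(mind2) > 0) mind2 / sum(mind2) else rep(1 / n, n)
        idx <- c(idx, sample.int(n, 1L, prob = p))
      }
      X[idx, , drop = FALSE]
    }
  })
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- .sqdist_to_centroids(X, centroids)
    assignments <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed at the row farthest from its centroid
    for (c in seq_len(k)) {
      if (!any(assignments == c)) {
        cur <- d2[cbind(seq_len(n), assignments)]
        far <- which.max(cur)
        centroids[c, ] <- X[far, ]
        d2 <- .sqdist_to_centroids(X, centroids)
        assignments <- max.col(-d2, ties.method = "first")
      }
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), assignments)]))
    if (identical(assignments, assign_old) || iter >= max_iter) break
    assign_old <- assignments
    for (c in seq_len(k))
      centroids[c, ] <- colMeans(X[assignments == c, , drop = FALSE])
  }
  d2 <- .sqdist_to_centroids(X, centroids)
  structure(
    list(centroids = centroids, assignments = assignments,
         inertia = sum(d2[cbind(seq_len(n), assignments)]),
         k = k, n_iterations = iter, inertia_trace = trace,
         distances = sqrt(d2[cbind(seq_len(n), assignments)]),
         data = X),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, %d rows, inertia %.4g (%d iterations)\n",
              x$k, length(x$assignments), x$inertia, x$n_iterations))
  invisible(x)
}

#' Distance-based outlier rule
#'
#' @param z_cut Positive number of within-cluster standard deviations beyond
#'   the cluster's mean centroid distance at which a record is an outlier.
#' @export
outlier_rule <- function(z_cut = 3) {
  if (!is.numeric(z_cut) || length(z_cut) != 1L || z_cut <= 0)
    stop("z_cut must be a single positive number")
  structure(list(z_cut = z_cut), class = "outlier_rule")
}

#' Remove records that do not comply with their cluster
#'
#' A record is dropped when its distance to its assigned centroid exceeds
#' that cluster's mean distance plus `z_cut` standard deviations of the
#' within-cluster distances. Because the inertia-optimal fit tends to
#' isolate extreme records into a tiny cluster of their own — where they
#' would trivially "comply" — clusters holding fewer than
#' `min_cluster_frac` of the rows are treated as non-representative: their
#' members are scored against the nearest representative cluster instead,
#' using that cluster's own threshold. A degenerate representative cluster
#' (zero spread, or a single member) never flags anything. At most
#' `max_drop_frac` of the rows are ever removed; if more are flagged, only
#' the most extreme are dropped (with a warning), guarding against a
#' degenerate fit discarding real records.
#'
#' @param table The [data_table()] the model was fitted on (same row order).
#' @param model A [fit_kmeans()] result fitted on the table's numeric
#'   encoding.
#' @param rule An [outlier_rule()].
#' @param max_drop_frac Upper bound on the dropped fraction (default 0.1).
#' @param min_cluster_frac Minimum fraction of rows for a cluster to count
#'   as representative (default 0.05). If no cluster qualifies, all are
#'   treated as representative.
#' @return A list: `table` (filtered), `dropped` (row indices removed),
#'   `distances` (per original row, to the centroid it was scored against).
#' @export
remove_outliers <- function(table, model, rule = outlier_rule(),
                            max_drop_frac = 0.1, min_cluster_frac = 0.05) {
  stopifnot(inherits(table, "data_table"), inherits(model, "cluster_model"),
            inherits(rule, "outlier_rule"))
  n <- n_rows(table)
  if (length(model$assignments) != n)
    stop("model was fitted on a different number of rows")
  sizes <- tabulate(model$assignments, nbins = model$k)
  representative <- sizes >= min_cluster_frac * n & sizes > 0L
  if (!any(representative)) representative <- sizes > 0L
  assignments <- model$assignments
  d <- model$distances
  if (!all(representative[assignments])) {
    # re-score members of non-representative clusters against the nearest
    # representative centroid
    X <- model$data
    if (is.null(X))
      stop("model lacks the fitted data needed to re-score tiny clusters")
    rep_idx <- which(representative)
    d2 <- .sqdist_to_centroids(X, model$centroids[rep_idx, , drop = FALSE])
    nearest <- max.col(-d2, ties.method = "first")
    move <- !representative[assignments]
    assignments[move] <- rep_idx[nearest[move]]
    d[move] <- sqrt(d2[cbind(which(move), nearest[move])])
  }
  flagged <- logical(n)
  for (c in which(representative)) {
    members <- which(model$assignments == c)  # threshold from own members
    scored <- which(assignments == c)
    if (length(members) < 2L) next
    mu <- mean(d[members])
    s <- stats::sd(d[members])
    if (!is.finite(s) || s == 0) next
    flagged[scored] <- d[scored] > mu + rule$z_cut * s
  }
  drop_idx <- which(flagged)
  cap <- floor(max_drop_frac * n)
  if (length(drop_idx) > cap) {
    warning("outlier rule flagged ", length(drop_idx), " rows; dropping only ",
            "the ", cap, " most extreme (max_drop_frac = ", max_drop_frac, ")")
    drop_idx <- drop_idx[order(d[drop_idx], decreasing = TRUE)][seq_len(cap)]
    drop_idx <- sort(drop_idx)
  }
  out <- if (length(drop_idx)) subset_table(table, rows = -drop_idx) else table
  list(table = out, dropped = drop_idx, distances = d)
}

#' Flag features uncorrelated with the cluster structure
#'
#' Column-wise reading of outlier filtering: a feature is low-relevance when
#' no encoded column derived from it has point-biserial correlation with the
#' 2-cluster assignment above `r_min` in absolute value.
#'
#' @param table An imputed [data_table()].
#' @param model A [fit_kmeans()] result with `k = 2` fitted on
#'   `encode_features(table)`.
#' @param r_min Absolute-correlation threshold (default 0.1).
#' @return Integer indices of the non-complying features.
#' @export
noncomplying_features <- function(table, model, r_min = 0.1) {
  stopifnot(inherits(table, "data_table"), inherits(model, "cluster_model"))
  if (model$k != 2L) stop("column mode is defined for k = 2")
  enc <- encode_features(table)
  g <- as.numeric(model$assignments == 2L)
  owner <- attr(enc, "feature_of")
  r <- vapply(seq_len(ncol(enc)), function(j) {
    x <- enc[, j]
    if (stats::sd(x) == 0 || stats::sd(g) == 0) return(0)
    abs(stats::cor(x, g))
  }, numeric(1))
  keep_feature <- tapply(r, owner, max) >= r_min
  which(!keep_feature[as.character(seq_len(n_features(table)))])
}
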