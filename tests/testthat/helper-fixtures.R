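# Fixtures are generated in code; nothing is read from disk.

# two compact uniform-ball clusters separated along the first axis
make_ball_blobs <- function(n_per = 100L, d = 4L, sep = 8, seed = 1L) {
  withr::with_seed(seed, {
    ball <- function(n) {
      z <- matrix(stats::rnorm(n * d), n, d)
      z <- z / sqrt(rowSums(z^2))
      z * stats::runif(n)^(1 / d)
    }
    A <- ball(n_per)
    B <- ball(n_per)
    B[, 1] <- B[, 1] + sep
    df <- as.data.frame(rbind(A, B))
    names(df) <- paste0("x", seq_len(d))
    data_table(df, labels = rep(c("0", "1"), each = n_per))
  })
}

# a table Naive Bayes separates perfectly: huge class separation
make_separable_table <- function(n = 200L, d = 2L, seed = 1L) {
  g <- generate_synthetic(synthetic_spec(
    n_rows = n, n_informative = d, n_noise = 0L,
    # keep the total feature count >= 2
    n_redundant = if (d < 2L) 1L else 0L,
    effect_size = 12, seed = seed))
  g$table
}

# small handmade mixed-type table
tiny_mixed_table <- function() {
  data_table(
    data.frame(age = c(34, 51, 46, 29, 60, 42),
               bp = c(80, 95, 90, 75, 99, 85),
               smoker = c("no", "yes", "yes", "no", "yes", "no"),
               stringsAsFactors = FALSE),
    labels = c("live", "die", "die", "live", "die", "live"))
}

# independent brute-force Naive Bayes posterior: direct probability
# products, no logs; same estimator conventions as the contract (ML
# variance with floor, Laplace-smoothed level frequencies)
nb_oracle_posterior <- function(table, row, alpha = 1, var_floor = 1e-9) {
  classes <- table$class_names
  n <- nrow(table$features)
  post <- numeric(2)
  for (c in 1:2) {
    idx <- table$labels == classes[c]
    p <- sum(idx) / n
    for (j in seq_along(table$features)) {
      col <- table$features[[j]][idx]
      x <- row[[names(table$features)[j]]]
      if (table$column_kinds[j] == "numeric") {
        mu <- mean(col)
        v <- max(mean(col^2) - mu^2, var_floor)
        p <- p * stats::dnorm(x, mu, sqrt(v))
      } else {
        levs <- sort(unique(table$features[[j]]))
        cnt <- sum(col == x)
        p <- p * (cnt + alpha) / (sum(idx) + alpha * length(levs))
      }
    }
    post[c] <- p
  }
  post / sum(post)
}

# random mixed table for property tests
random_mixed_table <- function(n = 40L, seed = 1L) {
  withr::with_seed(seed, {
    df <- data.frame(
      a = stats::rnorm(n),
      b = stats::runif(n, 0, 10),
      c = sample(c("lo", "mid", "hi"), n, replace = TRUE),
      d = sample(c("y", "n"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    labels <- sample(c("neg", "pos"), n, replace = TRUE)
    while (length(unique(labels)) < 2L)
      labels <- sample(c("neg", "pos"), n, replace = TRUE)
    data_table(df, labels)
  })
}
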