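test_that("priors are class frequencies and smoothing follows the Laplace rule", {
  tab <- data_table(
    data.frame(s = c("yes", "yes", "yes", "no", "yes", "no"),
               stringsAsFactors = FALSE),
    labels = c("A", "A", "A", "B", "B", "B"))
  m <- fit_nb(tab, alpha = 1)
  expect_equal(m$priors, c(0.5, 0.5))
  # class A: 3 rows all "yes", 2 levels -> P(yes|A) = (3+1)/(3+2) = 0.8
  p_yes_A <- exp(m$cat_logprob[[1]][2, 1])  # levels sorted: no, yes
  expect_equal(p_yes_A, 0.8)
  expect_equal(exp(m$cat_logprob[[1]][1, 1]), 0.2)  # P(no|A) = (0+1)/5
  # per (class, feature) level probabilities sum to 1 (excluding the
  # unseen-level smoothing sentinel)
  expect_equal(colSums(exp(m$cat_logprob[[1]][1:2, ])), c(1, 1))
})

test_that("constant numeric features hit the variance floor, not a zero division", {
  tab <- data_table(data.frame(x = rep(2.5, 8), y = rnorm(8)),
                    labels = rep(c("0", "1"), 4))
  m <- fit_nb(tab, var_floor = 1e-9)
  expect_equal(unname(m$vars[, 1]), c(1e-9, 1e-9))
  p <- predict(m, tab, type = "prob")
  expect_true(all(is.finite(p)))
})

test_that("posteriors normalize, respect symmetry, and match a hand computation", {
  # symmetric model: equal priors, mirrored likelihoods; midpoint row -> 0.5
  sym <- data_table(data.frame(x = c(-2, -1, 1, 2)),
                    labels = c("0", "0", "1", "1"))
  m <- fit_nb(sym)
  p_mid <- predict(m, data.frame(x = 0), type = "prob")
  expect_equal(as.numeric(p_mid), c(0.5, 0.5), tolerance = 1e-12)

  # hand evaluation: priors (0.6, 0.4), P(level|c1)=0.8, P(level|c2)=0.3
  # -> posterior c1 = 0.48 / (0.48 + 0.12) = 0.8. Constructed model object.
  hand <- structure(list(
    priors = c(0.6, 0.4),
    means = matrix(0, 2, 0), vars = matrix(0, 2, 0),
    cat_logprob = list(log(rbind(c(0.8, 0.3), c(0.2, 0.7), c(0.5, 0.5)))),
    feature_names = "f", column_kinds = "categorical",
    cat_levels = list(c("hit", "miss")),
    num_cols = integer(0), cat_cols = 1L,
    class_names = c("c1", "c2"), alpha = 1, var_floor = 1e-9),
    class = "nb_model")
  p <- predict(hand, data.frame(f = "hit", stringsAsFactors = FALSE),
               type = "prob")
  expect_equal(as.numeric(p), c(0.8, 0.2), tolerance = 1e-12)

  # normalization property on random rows
  tab <- random_mixed_table(n = 60, seed = 9)
  m2 <- fit_nb(tab)
  probs <- predict(m2, tab, type = "prob")
  expect_equal(rowSums(probs), rep(1, 60), tolerance = 1e-12)
})

test_that("prediction ties go to the larger prior, then the lower class index", {
  base <- list(
    means = matrix(0, 2, 0), vars = matrix(0, 2, 0),
    cat_logprob = list(log(rbind(c(0.5, 0.5), c(0.5, 0.5)))),
    feature_names = "f", column_kinds = "categorical",
    cat_levels = list(c("u", "v")),
    num_cols = integer(0), cat_cols = 1L,
    class_names = c("c1", "c2"), alpha = 1, var_floor = 1e-9)
  equal_priors <- structure(c(list(priors = c(0.5, 0.5)), base),
                            class = "nb_model")
  # likelihood ratio exactly cancels the prior ratio: a true posterior tie
  skewed <- structure(c(list(priors = c(0.3, 0.7)), base),
                      class = "nb_model")
  skewed$cat_logprob <- list(log(rbind(c(0.7, 0.3), c(0.3, 0.7))))
  row <- data.frame(f = "u", stringsAsFactors = FALSE)
  # likelihoods identical; with equal priors the posterior ties -> class 1
  expect_equal(predict(equal_priors, row), "c1")
  expect_equal(predict(skewed, row), "c2")
})

test_that("log-space evaluation survives 1000-feature rows", {
  n <- 30
  d <- 1000
  withr::local_seed(3)
  df <- as.data.frame(matrix(rnorm(n * d), n, d))
  tab <- data_table(df, labels = rep(c("0", "1"), length.out = n))
  m <- fit_nb(tab)
  p <- predict(m, tab, type = "prob")
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, n), tolerance = 1e-9)
})

test_that("posteriors agree with a brute-force product-form oracle to 1e-9", {
  for (seed in 1:5) {
    tab <- random_mixed_table(n = 30, seed = seed)
    m <- fit_nb(tab)
    probs <- predict(m, tab, type = "prob")
    for (i in c(1, 7, 19)) {
      oracle <- nb_oracle_posterior(tab, tab$features[i, , drop = FALSE])
      expect_equal(as.numeric(probs[i, ]), oracle, tolerance = 1e-9)
    }
  }
})

test_that("class predictions agree with an independent reference implementation", {
  tab <- make_separable_table(n = 120, d = 3, seed = 21)
  m <- fit_nb(tab)
  df <- tab$features
  df$cls <- factor(tab$labels)
  ref <- e1071::naiveBayes(cls ~ ., data = df)
  expect_equal(predict(m, tab),
               as.character(predict(ref, tab$features)))
})

test_that("unseen categorical levels get smoothing mass, never zero probability", {
  tab <- data_table(
    data.frame(s = c("a", "a", "b", "b"), stringsAsFactors = FALSE),
    labels = c("0", "0", "1", "1"))
  m <- fit_nb(tab)
  p <- predict(m, data.frame(s = "zzz", stringsAsFactors = FALSE),
               type = "prob")
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("training requires both classes and complete data", {
  ok <- random_mixed_table(n = 20, seed = 1)
  missing_class <- ok
  missing_class$labels <- rep(ok$class_names[1], 20)
  expect_error(data_table(ok$features, missing_class$labels), "two distinct")
  with_na <- ok
  with_na$features$a[1] <- NA
  expect_error(fit_nb(with_na), "impute")
})
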