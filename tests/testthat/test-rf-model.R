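# Correlation pruning, shadow-feature selection and the Random Forest.

test_that("correlation pruning removes exactly one of a redundant pair", {
  set.seed(51)
  a <- rnorm(300)
  tab <- data.frame(a = a, b = a, c = rnorm(300))
  sel <- prune_correlated(tab)
  expect_length(sel$kept, 2)
  expect_true("c" %in% sel$kept)
  expect_true(sum(c("a", "b") %in% sel$kept) == 1)
  expect_equal(nrow(sel$pruned_pairs), 1)
  expect_equal(abs(sel$pruned_pairs$r), 1)
})

test_that("independent noise columns survive pruning", {
  set.seed(53)
  tab <- as.data.frame(matrix(rnorm(1000 * 8), ncol = 8))
  sel <- prune_correlated(tab)
  expect_setequal(sel$kept, names(tab))
  # constant columns correlate with nothing by convention
  tab$const <- 1
  expect_true("const" %in% prune_correlated(tab)$kept)
})

test_that("pruning drops the more redundant member of a correlated pair", {
  set.seed(57)
  a <- rnorm(800)
  b <- a + rnorm(800, 0, 0.45)        # r(a, b) ~ 0.9
  c <- rnorm(800)                      # independent of both
  sel <- prune_correlated(data.frame(a = a, b = b, c = c))
  expect_true("c" %in% sel$kept)
  expect_length(sel$kept, 2)
  # no remaining pair above the threshold
  cm <- abs(cor(data.frame(a = a, b = b, c = c)[, sel$kept]))
  diag(cm) <- 0
  expect_lt(max(cm), 0.75)
})

test_that("shadow selection confirms a planted signal and rejects noise", {
  set.seed(61)
  n <- 500
  x <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n), n4 = rnorm(n), n5 = rnorm(n))
  labels <- factor(ifelse(x$signal > 0, "MVPA", "Sedentary"))
  sel <- shadow_select(x, labels, seed = 9, max_runs = 25, num_trees = 60)
  expect_true("signal" %in% sel$confirmed)
  expect_lt(length(setdiff(sel$confirmed, "signal")), 2)
  expect_error(shadow_select(x, factor(rep("MVPA", n)), seed = 1), "classes")
})

test_that("pure-noise features are confirmed at most at the alpha level", {
  set.seed(63)
  n <- 300
  p <- 40
  x <- as.data.frame(matrix(rnorm(n * p), ncol = p))
  labels <- factor(sample(c("LIPA", "MVPA"), n, replace = TRUE))
  sel <- shadow_select(x, labels, seed = 17, max_runs = 20, num_trees = 60)
  expect_lte(length(sel$confirmed), ceiling(0.05 * p))
})

test_that("shadow selection is reproducible for a fixed seed", {
  set.seed(67)
  x <- data.frame(s = rnorm(200), a = rnorm(200), b = rnorm(200))
  labels <- factor(ifelse(x$s + rnorm(200, 0, 0.3) > 0, "MVPA", "LIPA"))
  s1 <- shadow_select(x, labels, seed = 5, max_runs = 15, num_trees = 50)
  s2 <- shadow_select(x, labels, seed = 5, max_runs = 15, num_trees = 50)
  expect_identical(s1$confirmed, s2$confirmed)
  expect_identical(s1$hits, s2$hits)
})

make_class_table <- function(n, seed) {
  set.seed(seed)
  cls <- sample(intensity_levels(), n, replace = TRUE)
  mu <- c(Sedentary = 0, Standing = 2, LIPA = 4, MVPA = 6)
  data.frame(f1 = mu[cls] + rnorm(n, 0, 0.8),
             f2 = rnorm(n),
             f3 = mu[cls] * 0.5 + rnorm(n, 0, 1.5),
             class = factor(cls, levels = intensity_levels()))
}

test_that("the forest reproduces unique continuous training rows perfectly", {
  tab <- make_class_table(800, 71)
  fit <- train_forest(tab[1:3], tab$class, n_trees = 100, seed = 3)
  pred <- predict_forest(fit, tab[1:3])
  perf <- training_sample_check(pred, tab$class)
  expect_true(all(perf$balanced_accuracy == 100))
  expect_length(fit$oob_error_curve, 100)
})

test_that("out-of-bag error improves with ensemble size", {
  tab <- make_class_table(600, 73)
  fit <- train_forest(tab[1:3], tab$class, n_trees = 100, seed = 5)
  expect_lte(fit$oob_error_curve[100], fit$oob_error_curve[5])
})

test_that("forest predictions respect schema, order and class space", {
  tab <- make_class_table(400, 79)
  fit <- train_forest(tab[1:3], tab$class, n_trees = 60, seed = 7)
  pred <- predict_forest(fit, tab[1:3])
  expect_true(all(as.character(pred) %in% intensity_levels()))
  expect_length(predict_forest(fit, tab[0, 1:3]), 0)
  idx <- sample(nrow(tab))
  expect_identical(as.character(predict_forest(fit, tab[idx, 1:3])),
                   as.character(pred)[idx])
  expect_error(predict_forest(fit, tab[, c("f1", "f2")]), "f3")
  expect_error(train_forest(tab[1:10, 1:3], tab$class[1:9]), "align")
})

test_that("training twice with one seed gives identical forests", {
  tab <- make_class_table(300, 83)
  f1 <- train_forest(tab[1:3], tab$class, n_trees = 50, seed = 11)
  f2 <- train_forest(tab[1:3], tab$class, n_trees = 50, seed = 11)
  expect_identical(as.character(predict_forest(f1, tab[1:3])),
                   as.character(predict_forest(f2, tab[1:3])))
  expect_identical(f1$oob_error_curve, f2$oob_error_curve)
})
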