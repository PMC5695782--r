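# Confusion matrices, one-vs-rest statistics, benchmarking, corrections,
# robustness and reliability.

test_that("LOSO folds hold every participant out exactly once", {
  ids <- sprintf("P%02d", 1:5)
  folds <- loso_split(ids)
  expect_length(folds, 5)
  expect_setequal(vapply(folds, `[[`, "", "test"), ids)
  for (f in folds) {
    expect_setequal(c(f$train, f$test), ids)
    expect_length(intersect(f$train, f$test), 0)
  }
  folds2 <- loso_split(c("A", "B"))
  expect_equal(folds2[[1]]$train, "B")
  expect_error(loso_split(c("A", "A")), "duplicate")
  expect_error(loso_split("A"), "at least 2")
})

test_that("confusion matrices count, sum and validate", {
  lv <- intensity_levels()
  perfect <- confusion(lv, lv)
  expect_equal(diag(unclass(perfect)), setNames(rep(1L, 4), lv))
  expect_equal(sum(perfect), 4L)

  set.seed(91)
  p1 <- sample(lv, 50, replace = TRUE)
  r1 <- sample(lv, 50, replace = TRUE)
  p2 <- sample(lv, 30, replace = TRUE)
  r2 <- sample(lv, 30, replace = TRUE)
  summed <- sum_confusions(list(confusion(p1, r1, "A"), confusion(p2, r2, "B")))
  pooled <- confusion(c(p1, p2), c(r1, r2))
  expect_equal(unclass(summed), unclass(pooled), ignore_attr = TRUE)
  expect_error(confusion(c("MVPA", "jogging"), c("MVPA", "MVPA")), "jogging")
  expect_error(confusion(p1, r1[-1]), "equal length")
})

test_that("one-vs-rest statistics come from the matrix margins", {
  m <- as_confusion(rbind(c(50, 0, 0, 0),
                          c(0, 30, 10, 0),
                          c(0, 10, 30, 5),
                          c(0, 0, 10, 55)))
  perf <- class_performance(m)
  expect_equal(perf$sensitivity[perf$class == "Sedentary"], 100)
  # LIPA: TP 30, ref total 50, FP 15, TN 200 - 50 - 15 = 135
  lipa <- perf[perf$class == "LIPA", ]
  expect_equal(lipa$sensitivity, 100 * 30 / 50)
  expect_equal(lipa$specificity, 100 * 135 / 150)
  expect_equal(lipa$balanced_accuracy,
               (lipa$sensitivity + lipa$specificity) / 2)
  perfect <- confusion(intensity_levels(), intensity_levels())
  expect_true(all(class_performance(perfect)$balanced_accuracy == 100))
  empty_ref <- as_confusion(rbind(c(5, 0, 0, 1), c(0, 5, 0, 0),
                                  c(0, 0, 0, 0), c(0, 0, 0, 9)))
  expect_error(class_performance(empty_ref, "LIPA"), "undefined")
})

test_that("benchmark counts acceptable participants inclusively", {
  expect_equal(benchmark(c(85, 75, 90, 80)), 75)
  expect_equal(benchmark(rep(100, 10)), 100)
  # monotone non-increasing in the threshold
  ba <- c(62, 71, 80, 85, 99)
  shares <- vapply(seq(50, 100, 5), function(th) benchmark(ba, th), 0)
  expect_true(all(diff(shares) <= 0))
})

test_that("Bonferroni and Sidak follow their closed forms", {
  expect_equal(adjust_p(0.01, 3, "bonferroni"), 0.03)
  expect_equal(adjust_p(0.01, 3, "sidak"), 1 - 0.99^3)
  expect_equal(adjust_p(0.01, 3, "sidak"), 0.029701)
  expect_equal(adjust_p(0.5, 3, "bonferroni"), 1) # capped
  expect_true(all(adjust_p(c(0.2, 0.8), 4, "sidak") >= c(0.2, 0.8)))
  expect_error(adjust_p(1.2, 3), "0, 1")
  expect_error(adjust_p(0.1, 0), "k")
})

test_that("coefficients of variation and their summaries", {
  x <- c(9.56, 10, 10.44) # mean 10, sd 0.44
  expect_equal(reliability_cv(x), 4.4)
  expect_equal(reliability_cv(rep(7, 5)), 0)
  expect_error(reliability_cv(c(-1, 1)), "zero mean")
  expect_error(reliability_cv(5), "at least 2")
  set.seed(95)
  cvs <- abs(rnorm(40, 4.4, 1))
  sm <- summarise_cvs(cvs)
  expect_true(sm$summary %in% c("mean", "median"))
  expect_true(sm$ci[1] <= sm$centre && sm$centre <= sm$ci[2])
  expect_equal(sm$acceptable, 100 * mean(cvs < 10))
})

test_that("robustness picks the right test and finds planted effects", {
  set.seed(97)
  n <- 30
  base <- data.frame(participant_id = sprintf("P%02d", 1:n),
                     body_height = exp(rnorm(n, 0.5, 0.2)), # skewed
                     sex = rep(c("female", "male"), n / 2))
  ba <- setNames(60 + 25 * rank(base$body_height) / n + rnorm(n, 0, 2),
                 base$participant_id)
  res <- robustness(ba, base, characteristics = c("body_height", "sex"))
  h <- res[res$characteristic == "body_height", ]
  expect_equal(h$test, "Spearman rho") # non-normal height gates Spearman
  expect_lt(h$p_adjusted, 0.05)
  expect_true(all(res$p_adjusted >= res$p, na.rm = TRUE))
  expect_equal(unique(res$k), 2)
})

test_that("robustness holds its level under independence", {
  set.seed(98)
  n <- 24
  hits <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    base <- data.frame(participant_id = sprintf("P%02d", 1:n),
                       age = rnorm(n, 73.5, 6.3))
    ba <- setNames(rnorm(n, 90, 4), base$participant_id)
    res <- robustness(ba, base, characteristics = "age")
    hits <- hits + (res$p_adjusted < 0.05)
  }
  expect_lte(hits / reps, 0.15) # ~alpha with Monte-Carlo slack
  expect_error(robustness(c(a = 1, b = 2),
                          data.frame(participant_id = c("a", "b"), age = 1:2)),
               "at least 3")
})

test_that("algorithm comparison gates parametric vs rank tests", {
  set.seed(99)
  n <- 20
  ba <- cbind(svm = rnorm(n, 85, 3), ima = rnorm(n, 85, 3),
              tm = rnorm(n, 78, 3))
  out <- compare_algorithms(ba)
  expect_true(out$omnibus$test %in% c("repeated-measures ANOVA", "Friedman"))
  expect_equal(nrow(out$pairwise), 3)
  tm_rows <- grepl("tm", out$pairwise$pair)
  expect_lt(min(out$pairwise$p_adjusted[tm_rows]), 0.05)
})
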