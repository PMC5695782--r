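# Window metrics, posture detection, trend-line calibration and
# cut-point classification.

test_that("SVM sums per-sample vector magnitudes", {
  expect_equal(compute_svm(const_mat(0.1, 0, 0)), 60)
  expect_equal(compute_svm(const_mat(0, 0, 0)), 0)
  expect_equal(compute_svm(const_mat(0.3, 0.4, 0)), 300) # 3-4-5 triple
  expect_error(compute_svm(const_mat(0, 0, 0, n = 599)), "600")
})

test_that("IMA integrates the absolute signal per axis", {
  expect_equal(compute_ima(const_mat(0.1, 0.1, 0.1)), 3)
  expect_equal(compute_ima(const_mat(0, 0, 0)), 0)
  t <- (0:599) / 60
  w <- cbind(x = sin(2 * pi * 1 * t), y = rep(0, 600), z = rep(0, 600))
  # mean of |sin| is 2/pi; rectangle quadrature error is O(dt)
  expect_equal(compute_ima(w), 10 * 2 / pi, tolerance = 1e-3)
  expect_equal(compute_ima(w, method = "trapezoid"), 10 * 2 / pi,
               tolerance = 2e-3)
})

test_that("TM is the norm of the per-axis dynamic SDs", {
  expect_equal(compute_tm(const_mat(0.5, -0.2, 0.1)), 0)
  A <- 0.25
  w <- cbind(x = rep(c(A, -A), 300), y = rep(0, 600), z = rep(0, 600))
  expect_equal(compute_tm(w), A * sqrt(600 / 599))
  set.seed(13)
  dyn <- matrix(rnorm(1800, 0, 0.3), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  wf <- mk_window(const_mat(0, 1, 0), dyn)
  expect_equal(compute_tm(wf), window_features(wf)[["dynamic_resultant_sd"]])
})

test_that("metrics are axis-permutation invariant and scale linearly", {
  set.seed(19)
  dyn <- matrix(rnorm(1800, 0, 0.3), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  perm <- dyn[, c(3, 1, 2)]
  colnames(perm) <- c("x", "y", "z")
  expect_equal(compute_svm(perm), compute_svm(dyn))
  expect_equal(compute_ima(perm), compute_ima(dyn))
  expect_equal(compute_tm(perm), compute_tm(dyn))
  for (c_scale in c(0.5, 2, 7)) {
    expect_equal(compute_svm(c_scale * dyn), c_scale * compute_svm(dyn))
    expect_equal(compute_ima(c_scale * dyn), c_scale * compute_ima(dyn))
    expect_equal(compute_tm(c_scale * dyn), c_scale * compute_tm(dyn))
  }
})

test_that("posture detection thresholds |static Y| strictly", {
  expect_equal(detect_posture(0.98), "upright")
  expect_equal(detect_posture(0.05), "not_upright")
  expect_equal(detect_posture(0.5), "not_upright") # boundary: strict >
  expect_equal(detect_posture(-0.9), "upright") # flipped device
  expect_equal(detect_posture(c(0.9, 0.1)), c("upright", "not_upright"))
})

test_that("noiseless linear calibration inverts exactly", {
  metric <- seq(0, 500, length.out = 400)
  met <- 0.9 + 0.01 * metric
  m <- calibrate_cutpoints(metric, met, "svm")
  expect_equal(m$trend_family, "linear") # R^2 tie broken to fewer terms
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$cutoff_lipa, 60, tolerance = 1e-6)
  expect_equal(m$cutoff_mvpa, 210, tolerance = 1e-6)
})

test_that("noisy calibration recovers the analytic cut-offs", {
  set.seed(2024)
  metric <- runif(4000, 0, 500)
  met <- 0.9 + 0.01 * metric + rnorm(4000, 0, 0.1)
  m <- calibrate_cutpoints(metric, met, "svm")
  expect_lt(abs(m$cutoff_lipa - 60) / 60, 0.05)
  expect_lt(abs(m$cutoff_mvpa - 210) / 210, 0.05)
  expect_gt(m$r_squared, 0.95)
})

test_that("the best-R-squared family is selected", {
  metric <- seq(1, 3000, length.out = 500)
  met <- exp(0.001 * metric)
  m <- calibrate_cutpoints(metric, met)
  expect_equal(m$trend_family, "exponential")
  expect_equal(m$cutoff_lipa, log(1.5) / 0.001, tolerance = 1e-4)
  expect_equal(m$cutoff_mvpa, log(3) / 0.001, tolerance = 1e-4)
})

test_that("calibration guards its preconditions", {
  expect_error(calibrate_cutpoints(rep(1, 10), rep(2, 10)), "distinct")
  expect_error(calibrate_cutpoints(1:10, seq(2, 2.9, length.out = 10)),
               "span")
  # no metric in range maps to MET 3 -> explicit error
  metric <- seq(0, 100, length.out = 50)
  met <- 0.9 + 0.01 * metric # tops out below MET 3... but spans? max 1.9
  expect_error(calibrate_cutpoints(metric, met), "span")
})

test_that("cut-point classification mirrors the MET rule set in metric space", {
  metric <- seq(0, 500, length.out = 400)
  met <- 0.9 + 0.01 * metric
  m <- calibrate_cutpoints(metric, met)
  # below the 1.5-MET cut-off the posture gate decides
  expect_equal(as.character(classify_cutpoint(30, 0.9, m)), "Standing")
  expect_equal(as.character(classify_cutpoint(30, 0.1, m)), "Sedentary")
  expect_equal(as.character(classify_cutpoint(150, 0.1, m)), "LIPA")
  expect_equal(as.character(classify_cutpoint(150, 0.9, m)), "LIPA")
  expect_equal(as.character(classify_cutpoint(m$cutoff_mvpa, 0.1, m)),
               "MVPA") # >= boundary mirrors MET >= 3
  expect_error(classify_cutpoint(1, 0.5, list()), "cutpoint_model")
})

test_that("cut-point models serialize to JSON and back", {
  metric <- seq(0, 500, length.out = 400)
  m <- calibrate_cutpoints(metric, 0.9 + 0.01 * metric, "ima")
  path <- withr::local_tempfile(fileext = ".json")
  write_cutpoint_model(m, path)
  m2 <- read_cutpoint_model(path)
  expect_equal(m2$cutoff_lipa, m$cutoff_lipa)
  expect_equal(m2$cutoff_mvpa, m$cutoff_mvpa)
  expect_equal(m2$trend_family, m$trend_family)
  expect_equal(as.character(classify_cutpoint(c(30, 150, 400), c(0.9, 0, 0), m2)),
               c("Standing", "LIPA", "MVPA"))
})
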