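# Window feature definitions against enumeration and closed-form oracles.

test_that("time-domain features of a constant window", {
  f <- time_domain_features(rep(0.5, 600))
  expect_equal(f[["mean"]], 0.5)
  expect_equal(f[["sd"]], 0)
  expect_equal(f[["rms"]], 0.5)
  expect_equal(f[["peak_to_peak"]], 0)
  expect_equal(f[["zero_crossings"]], 0)
  expect_equal(f[["skewness"]], 0) # convention on constant windows
  expect_equal(f[["kurtosis"]], 0)
})

test_that("time-domain features of an alternating series match enumeration", {
  A <- 0.4
  x <- rep(c(A, -A), 300)
  f <- time_domain_features(x)
  expect_equal(f[["mean"]], 0)
  expect_equal(f[["rms"]], A)
  expect_equal(f[["sd"]], A * sqrt(600 / 599))
  expect_equal(f[["peak_to_peak"]], 2 * A)
  expect_equal(f[["zero_crossings"]], 599)
  expect_error(time_domain_features(c(x[-1], Inf)), "finite")
  expect_error(time_domain_features(x[1:599]), "600")
})

test_that("sinusoid features match closed forms", {
  t <- (0:599) / 60
  x <- sin(2 * pi * 2 * t) # 20 exact periods in the window
  f <- time_domain_features(x)
  expect_equal(f[["rms"]], 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(f[["lag1_autocorrelation"]], cos(2 * pi * 2 / 60),
               tolerance = 1e-3)
  g <- frequency_domain_features(x)
  expect_equal(g[["dominant_frequency"]], 2.0) # on-bin for 0.1 Hz bins
  expect_equal(g[["dominant_frequency_amplitude"]], 1, tolerance = 0.01)
  expect_lt(g[["spectral_entropy"]], 0.2)
})

test_that("spectral entropy spans the noise/tone range", {
  set.seed(3)
  g <- frequency_domain_features(rnorm(600))
  expect_gt(g[["spectral_entropy"]], 0.9)
  expect_true(g[["spectral_entropy"]] <= 1)
  z <- frequency_domain_features(rep(0, 600))
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("orientation angles follow the arctangent convention", {
  up <- orientation_angles(const_mat(0, 1, 0))
  expect_equal(up[["pitch"]], 90)
  expect_equal(up[["roll"]], 0)
  flat <- orientation_angles(const_mat(0, 0, 1))
  expect_equal(flat[["pitch"]], 0)
  expect_equal(flat[["yaw"]], 90)
  # ratios only: scaling the gravity vector changes nothing
  v <- const_mat(0.2, 0.7, 0.5)
  expect_equal(orientation_angles(v), orientation_angles(2 * v))
  expect_error(orientation_angles(const_mat(0, 0, 0)), "free-fall")
})

test_that("cross-correlations hit the exact and null cases", {
  set.seed(11)
  x <- rnorm(600)
  w <- cbind(x = x, y = x, z = -x)
  cc <- cross_correlations(w)
  expect_equal(cc[["cross_correlation_xy"]], 1)
  expect_equal(cc[["cross_correlation_xz"]], -1)
  ind <- cbind(x = rnorm(600), y = rnorm(600), z = rep(1, 600))
  cc <- cross_correlations(ind)
  expect_lt(abs(cc[["cross_correlation_xy"]]), 0.15)
  expect_equal(cc[["cross_correlation_xz"]], 0) # constant axis convention
})

test_that("rms, mean and sd satisfy the moment identity on random windows", {
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(600, mean = runif(1, -1, 1), sd = runif(1, 0, 2))
    f <- time_domain_features(x)
    expect_equal(f[["rms"]]^2, f[["mean"]]^2 + f[["sd"]]^2 * 599 / 600,
                 tolerance = 1e-9)
  }
})

test_that("axis permutation permutes features and fixes the resultants", {
  set.seed(31)
  stat <- const_mat(0.1, 0.9, 0.3) + matrix(rnorm(1800, 0, 0.01), ncol = 3)
  dyn <- matrix(rnorm(1800, 0, 0.2), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  colnames(stat) <- c("x", "y", "z")
  w1 <- mk_window(stat, dyn)
  perm <- c("y", "z", "x")
  w2 <- mk_window(stat[, perm], dyn[, perm])
  colnames(w2$static) <- colnames(w2$dynamic) <- c("x", "y", "z")
  f1 <- window_features(w1)
  f2 <- window_features(w2)
  expect_equal(f2[["dynamic_x_sd"]], f1[["dynamic_y_sd"]])
  expect_equal(f2[["static_z_mean"]], f1[["static_x_mean"]])
  expect_equal(f2[["dynamic_resultant_sd"]], f1[["dynamic_resultant_sd"]])
  expect_equal(f2[["static_resultant_mean"]], f1[["static_resultant_mean"]])
})

test_that("the feature matrix follows the declared schema with no gaps", {
  win <- tiny_windows()
  schema <- feature_schema()
  expect_equal(nrow(schema), 109)
  expect_true(all(schema$column %in% names(win)))
  expect_false(anyNA(win[, schema$column]))
  expect_equal(nrow(win), 4 * 120) # 120 windows per participant
  # TM is by definition the dynamic resultant SD
  expect_equal(win$tm, win$dynamic_resultant_sd, tolerance = 1e-12)
  expect_error(build_feature_matrix(list()), "empty")
})

test_that("feature extraction is deterministic", {
  set.seed(7)
  stat <- const_mat(0, 1, 0) + matrix(rnorm(1800, 0, 0.01), ncol = 3)
  dyn <- matrix(rnorm(1800, 0, 0.1), ncol = 3)
  colnames(stat) <- colnames(dyn) <- c("x", "y", "z")
  w <- mk_window(stat, dyn)
  expect_identical(window_features(w), window_features(w))
})
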