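test_that("fisher_z matches closed-form values, is odd, and never infinite", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.54931, tolerance = 1e-5)
  cc <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-cc), -fisher_z(cc))
  expect_true(all(diff(fisher_z(cc)) > 0))
  expect_true(all(is.finite(fisher_z(c(-1, 1, -2, 2)))))
})

test_that("exponential weights follow the taper formula", {
  w <- exponential_weights(3, theta = 1)
  expect_equal(w, c(exp(-2), exp(-1), 1) / sum(c(exp(-2), exp(-1), 1)))
  expect_equal(w, c(0.0900, 0.2447, 0.6652), tolerance = 1e-3)
  # theta -> Inf limit: rectangular window
  w_flat <- exponential_weights(window_spec(20, decay_theta = 1e9))
  expect_equal(w_flat, rep(1 / 20, 20), tolerance = 1e-6)
  # normalisation, positivity, monotonicity for arbitrary specs
  for (L in c(10, 15, 40)) {
    w <- exponential_weights(window_spec(L, L / 3))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
    expect_true(all(diff(w) > 0))
  }
})

test_that("weighted Pearson: affine invariance, uniform reduction, oracle", {
  set.seed(11)
  x <- rnorm(30)
  w <- runif(30, 0.1, 1)
  expect_equal(weighted_pearson(x, 2 * x + 3, w), 1, tolerance = 1e-12)
  y <- rnorm(30)
  expect_equal(weighted_pearson(x, y, rep(1, 30)), cor(x, y),
               tolerance = 1e-12)
  # against the brute-force loop oracle
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20); w <- runif(20, 0.05, 1)
    expect_equal(weighted_pearson(x, y, w), brute_weighted_pearson(x, y, w),
                 tolerance = 1e-12)
  }
  expect_error(weighted_pearson(rep(1, 10), rnorm(10), runif(10, 0.1, 1),
                                window = 7),
               "window 7")
})

test_that("window counts obey floor((T - L)/step) + 1", {
  set.seed(2)
  for (case in list(c(201, 20, 1, 182), c(20, 20, 1, 1), c(100, 10, 3, 31),
                    c(57, 12, 5, 10))) {
    X <- matrix(rnorm(case[1] * 4), ncol = 4)
    w <- sliding_window_correlations(X, window_spec(case[2], step = case[3]))
    expect_identical(nrow(w$z6), as.integer(case[4]))
    expect_identical(floor((case[1] - case[2]) / case[3]) + 1, case[4])
    # trailing-edge centers
    expect_identical(w$centers[1], as.integer(case[2]))
    expect_identical(w$centers[length(w$centers)] <= case[1], TRUE)
  }
  expect_error(sliding_window_correlations(matrix(rnorm(40), ncol = 4),
                                           window_spec(20)),
               "too short")
})

test_that("windowed correlations are valid and track the generating state", {
  s <- make_state_covariance(0.5, -0.5)
  co <- cohort_spec("G", 1, list(s), p_self = 0.9, T = 500, seed = 3)
  ts <- simulate_subject(co, 99)
  w <- sliding_window_correlations(ts, window_spec(20))
  # each corr matrix symmetric, unit diagonal, in [-1, 1]
  for (i in c(1, 100, nrow(w$z6))) {
    R <- w$corr[, , i]
    expect_equal(R, t(R))
    expect_equal(diag(R), setNames(rep(1, 4), tn_networks))
    expect_true(all(abs(R) <= 1))
  }
  # K = 1: window-averaged correlations near the generating matrix
  mean_corr <- apply(w$corr, c(1, 2), mean)
  expect_lt(max(abs(mean_corr - s$covariance)), 0.1)
})

test_that("theta -> Inf pipeline equals a rectangular-window oracle", {
  set.seed(4)
  X <- matrix(rnorm(120 * 4), ncol = 4)
  w <- sliding_window_correlations(X, window_spec(15, decay_theta = 1e12))
  for (i in c(1, 50, 106)) {
    R_plain <- cor(X[i:(i + 14), ])
    expect_equal(unname(w$corr[, , i]), unname(R_plain), tolerance = 1e-6)
  }
})
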