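test_that("nii_window arithmetic, symmetry and antisymmetry", {
  z <- c(0.5493, 0.5493, -0.5493, 0, 0, 0)
  expect_equal(nii_window(z), 1.0986, tolerance = 1e-10)
  expect_equal(nii_window(rep(0.7, 6)), 0)
  # swapping L and R FPN leaves NII unchanged
  z2 <- c(0.2, 0.9, -0.3, 0.1, 0.4, -0.2)
  expect_equal(nii_window(z2), nii_window(z2[c(2, 1, 3, 4, 5, 6)]))
  # exchanging the FPN pair with the DMN entry flips the sign (L = R case)
  z3 <- c(0.4, 0.4, -0.6, 0, 0, 0)
  z3_swap <- c(-0.6, -0.6, 0.4, 0, 0, 0)
  expect_equal(nii_window(z3_swap), -nii_window(z3))
  # matrix form vectorises over rows
  m <- rbind(z, z2)
  expect_equal(unname(nii_window(m)), c(nii_window(z), nii_window(z2)))
})

test_that("subject_nii_summary: pooled and state-level conventions", {
  nii <- c(1, 1, 3, 3)
  labels <- c(1, 1, 2, 2)
  pooled <- subject_nii_summary(nii, labels, mode = "pooled")
  expect_equal(pooled$nii_mean, 2)
  expect_equal(pooled$nii_sd, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(pooled$nii_sd, 1.1547, tolerance = 1e-4)
  expect_equal(unname(pooled$state_means), c(1, 3))
  statew <- subject_nii_summary(nii, labels, mode = "state")
  expect_equal(statew$nii_sd, sqrt(2), tolerance = 1e-12)
  # constant series
  const <- subject_nii_summary(rep(0.7, 5), rep(1, 5))
  expect_equal(const$nii_mean, 0.7)
  expect_equal(const$nii_sd, 0)
  # k = 1 state-level SD is undefined
  expect_warning(s1 <- subject_nii_summary(1:4, rep(1, 4), mode = "state"),
                 "single state")
  expect_true(is.na(s1$nii_sd))
  # order invariance
  set.seed(31)
  nii <- rnorm(50); labels <- sample(1:3, 50, replace = TRUE)
  perm <- sample(50)
  a <- subject_nii_summary(nii, labels)
  b <- subject_nii_summary(nii[perm], labels[perm])
  expect_equal(a$nii_mean, b$nii_mean)
  expect_equal(a$nii_sd, b$nii_sd)
  expect_equal(a$state_means, b$state_means)
})

test_that("pooled mean equals the dwell-weighted average of state means", {
  set.seed(32)
  for (i in 1:10) {
    nii <- rnorm(80)
    labels <- sample(1:3, 80, replace = TRUE)
    s <- subject_nii_summary(nii, labels)
    wts <- table(labels) / length(labels)
    expect_equal(s$nii_mean,
                 sum(s$state_means * as.vector(wts)), tolerance = 1e-12)
  }
})

test_that("static NII is consistent with the generator and the window form", {
  s <- make_state_covariance(0.5, -0.5)
  co <- cohort_spec("G", 1, list(s), p_self = 0.9, T = 2000, seed = 6)
  ts <- simulate_subject(co, 13)
  expect_lt(abs(static_nii(ts) - s$true_nii), 0.1)
  # identical FPN and DMN couplings cancel
  set.seed(33)
  base <- rnorm(100)
  X <- cbind(rnorm(100), base + rnorm(100, sd = 1e-3), base, base)
  expect_lt(abs(static_nii(X)), 0.05)
  # reduces to nii_window on one full-length uniform window
  Y <- matrix(rnorm(400), ncol = 4)
  w <- sliding_window_correlations(Y, window_spec(100, decay_theta = 1e12))
  expect_equal(static_nii(Y), nii_window(w$z6[1, ]), tolerance = 1e-6)
  # zero-variance component errors
  Z <- Y; Z[, 2] <- 1
  expect_error(static_nii(Z), "zero-variance")
})

test_that("template goodness of fit and component selection", {
  mask <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2))
  map <- array(c(1, 1, 0, 0), dim = c(2, 2))
  expect_equal(template_goodness_of_fit(map, mask)$goodness_of_fit, 1)
  expect_equal(template_goodness_of_fit(array(3, dim = c(2, 2)),
                                        mask)$goodness_of_fit, 0)
  expect_error(template_goodness_of_fit(map, array(TRUE, dim = c(2, 2))),
               "degenerate")
  maps <- list(A = array(c(0.4, 0.4, 0, 0), dim = c(2, 2)),
               B = array(c(0.9, 0.9, 0, 0), dim = c(2, 2)),
               C = array(c(0.9, 0.9, 0, 0), dim = c(2, 2)))
  sel <- select_component(maps, mask)
  expect_identical(sel$name, "B")   # ties break to the lowest index
  expect_equal(unname(sel$gof), c(0.4, 0.9, 0.9))
})

test_that("subject_metrics assembles a coherent row", {
  co <- cohort_spec("G", 1, sep_states2(), p_self = 0.9, T = 150, seed = 7)
  ts <- simulate_subject(co, 21)
  w <- sliding_window_correlations(ts, window_spec(10, 10 / 3))
  labels <- rep(1:2, length.out = nrow(w$z6))
  row <- subject_metrics(ts, w, labels)
  expect_identical(nrow(row), 1L)
  expect_gte(row$nii_sd, 0)
  expect_equal(row$mean_dwell_s, row$mean_dwell_windows * 2.3)
  expect_identical(row$k_visited, 2L)
})
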