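test_that("make_state_covariance hits its analytic NII", {
  s <- make_state_covariance(0.5, -0.5, background = 0)
  expect_equal(s$true_nii, 0.5 * log(3) - 0.5 * log(1 / 3),
               tolerance = 1e-10)
  expect_equal(s$true_nii, 1.0986, tolerance = 1e-4)
  expect_equal(make_state_covariance(0, 0)$true_nii, 0)
  expect_equal(make_state_covariance(0.3, 0.3)$true_nii, 0, tolerance = 1e-12)
  # symmetric, unit diagonal, positive definite
  R <- s$covariance
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(make_state_covariance(1, 0), "in \\(-1, 1\\)")
})

test_that("indefinite target matrices are repaired or rejected", {
  # near-contradictory targets force eigenvalue flooring
  s <- make_state_covariance(c(0.9, -0.9), 0.9, background = 0.9,
                             lfpn_rfpn = 0.9)
  ev <- eigen(s$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(unname(diag(s$covariance)), rep(1, 4))
  # true_nii recomputed from the repaired matrix (invariant over the repair)
  R <- s$covariance
  expect_equal(s$true_nii,
               mean(fisher_z(c(R[1, 2], R[1, 3]))) - fisher_z(R[1, 4]))
})

test_that("simulate_subject: sample covariance, dwell law, determinism", {
  s <- make_state_covariance(0.5, -0.5)
  co1 <- cohort_spec("G", 1, list(s), p_self = 0.9, T = 10000, seed = 1)
  ts <- simulate_subject(co1, 7)
  expect_lt(max(abs(cor(unclass(ts)) - s$covariance)), 0.05)

  co3 <- cohort_spec("G", 1, sep_states3(), p_self = 0.95, T = 10000,
                     seed = 1)
  ts3 <- simulate_subject(co3, 8)
  runs <- rle(attr(ts3, "state_seq"))
  expect_lt(abs(mean(runs$lengths) - 20) / 20, 0.15)

  expect_identical(unclass(simulate_subject(co3, 123)),
                   unclass(simulate_subject(co3, 123)))
})

test_that("Markov occupancy is uniform under symmetric transitions", {
  co <- cohort_spec("G", 1, sep_states3(), p_self = 0.9, T = 30000, seed = 2)
  s <- attr(simulate_subject(co, 5), "state_seq")
  # the chain is autocorrelated, so test the occupancy fractions directly
  expect_lt(max(abs(table(s) / length(s) - 1 / 3)), 0.02)
  # and the chi-square on a thinned (near-independent) subsample
  thin <- s[seq(1, length(s), by = 50)]
  expect_gt(chisq.test(table(thin))$p.value, 0.001)
})

test_that("per-state covariance is recoverable from truly assigned windows", {
  states <- sep_states2()
  co <- cohort_spec("G", 1, states, p_self = 0.98, T = 8000, seed = 3,
                    emission_noise_sd = 0)
  ts <- simulate_subject(co, 11)
  seq_ <- attr(ts, "state_seq")
  for (k in 1:2) {
    emp <- cor(unclass(ts)[seq_ == k, ])
    expect_lt(norm(emp - states[[k]]$covariance, "F"), 0.1)
  }
})

test_that("simulate_behavior recovers planted slopes", {
  metrics <- data.frame(subject_id = sprintf("s%02d", 1:30),
                        nii_sd = runif(30, 0.2, 0.8),
                        mean_dwell_s = runif(30, 20, 60))
  # noiseless: regression recovers the slope exactly
  beh0 <- simulate_behavior(metrics,
                            behavior_spec(intercept = 2,
                                          slope_on_nii_sd = -26.57,
                                          noise_sd = 0),
                            seed = 1)
  fit0 <- lm(beh0$cpt_composite_change ~ metrics$nii_sd)
  expect_equal(unname(coef(fit0)), c(2, -26.57), tolerance = 1e-8)
  # zero slope: |t| > 2 in roughly <= 5% of seeds
  hits <- 0L
  for (s in 1:60) {
    beh <- simulate_behavior(metrics,
                             behavior_spec(slope_on_nii_sd = 0,
                                           noise_sd = 4),
                             seed = s)
    tv <- summary(lm(beh$cpt_composite_change ~ metrics$nii_sd))$
      coefficients[2, "t value"]
    hits <- hits + (abs(tv) > 2)
  }
  expect_lte(hits / 60, 0.15)
  # Conners T-scores stay on the normed scale
  beh <- simulate_behavior(metrics, behavior_spec(), seed = 9)
  expect_true(all(beh$conners_inattention >= 30 &
                    beh$conners_inattention <= 100))
  expect_true(all(beh$conners_hyperactivity >= 30 &
                    beh$conners_hyperactivity <= 100))
})

test_that("cohort plumbing: transition rows, seeds, dwell expectation", {
  co <- cohort_spec("G", 4, sep_states3(), p_self = 0.8, T = 120, seed = 42)
  P <- trinetdyn:::tn_transition_matrix(co$n_states, co$p_self)
  expect_equal(rowSums(P), rep(1, 3))
  expect_equal(1 / (1 - co$p_self), 5)
  subs <- simulate_cohort(co)
  expect_length(subs, 4)
  expect_identical(unclass(simulate_cohort(co)[[2]]), unclass(subs[[2]]))
})
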