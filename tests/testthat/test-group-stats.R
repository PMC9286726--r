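test_that("paired t: d = t/sqrt(n) identity and error paths", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    cmp <- paired_t(a, b, m_family = 3)
    expect_equal(cmp$d, cmp$t / sqrt(n), tolerance = 1e-12)
    expect_identical(cmp$df, n - 1)
    expect_equal(cmp$p_bonferroni, min(1, 3 * cmp$p_raw))
    # subject-order invariance of the p value
    perm <- sample(n)
    expect_equal(paired_t(a[perm], b[perm])$p_raw, cmp$p_raw)
  }
  a <- rnorm(10)
  expect_error(paired_t(a, a + 2), "zero-variance")
})

test_that("Welch t: equal-n reduction, calibration, separation", {
  set.seed(42)
  # equal n: Welch statistic coincides with Student's t
  x <- rnorm(15); y <- rnorm(15, sd = 3)
  w <- welch_t(x, y)
  st <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$t, unname(st$statistic), tolerance = 1e-9)
  # separation
  expect_lt(welch_t(x, x + 10 + rnorm(15, sd = 1e-3))$p_raw, 1e-10)
  # type-I error near nominal under the null (unequal variances and n)
  hits <- 0L
  for (i in 1:400) {
    p <- welch_t(rnorm(12, sd = 3), rnorm(30))$p_raw
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / 400, 0.01)
  expect_lt(hits / 400, 0.10)
  # both d conventions reported
  expect_true(is.finite(w$d) && is.finite(w$d_welch))
  expect_error(welch_t(rep(1, 5), rep(2, 6)), "zero variance")
})

test_that("bonferroni caps at 1 and enforces the family size", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(1 / 3, 3), 1)
  expect_equal(bonferroni(c(0.01, 0.2), 5), c(0.05, 1))
  expect_error(bonferroni(c(0.1, 0.1, 0.1), 2))
})

test_that("CPT composite is the mean of the four standardised scores", {
  set.seed(43)
  cpt <- data.frame(om = rnorm(20, 50, 10), co = rnorm(20, 50, 10),
                    rt = rnorm(20, 50, 10), rtsd = rnorm(20, 50, 10))
  comp <- cpt_composite(cpt)
  manual <- rowMeans(sapply(cpt, function(x) (x - mean(x)) / sd(x)))
  expect_equal(comp, manual, tolerance = 1e-12)
})

test_that("brain-behavior correlations recover planted structure", {
  set.seed(44)
  n <- 40
  dwell <- runif(n, 10, 60)
  dat <- data.frame(mean_dwell_s = dwell,
                    nii_mean = rnorm(n), nii_sd = runif(n, 0.2, 0.6),
                    conners_inattention = 40 + 0.8 * dwell + rnorm(n, sd = 4),
                    conners_hyperactivity = rnorm(n, 50, 8))
  res <- brain_behavior_correlations(dat)
  expect_identical(nrow(res), 6L)
  r_dwell <- res$r[res$metric == "mean_dwell_s" &
                     res$clinical == "conners_inattention"]
  expect_gt(r_dwell, 0.5)
  expect_true(all(res$p_bonferroni >= res$p_raw - 1e-15))
  expect_true(all(res$p_bonferroni <= 1))
  # a perfectly linear pair gives r = 1
  dat$conners_inattention <- 30 + 0.5 * dwell
  res2 <- brain_behavior_correlations(dat)
  expect_equal(res2$r[res2$metric == "mean_dwell_s" &
                        res2$clinical == "conners_inattention"], 1,
               tolerance = 1e-12)
  expect_error(brain_behavior_correlations(dat[1:5, ]), "complete cases")
})

test_that("treatment-response regression is exact when noiseless", {
  set.seed(45)
  n <- 30
  dat <- data.frame(nii_mean = rnorm(n), nii_sd = runif(n, 0.1, 0.9),
                    age = runif(n, 7, 16), fsiq = runif(n, 80, 120),
                    mean_fd = runif(n, 0.03, 0.15))
  dat$cpt_composite_change <- 1.5 - 26.57 * dat$nii_sd + 0.2 * dat$age
  # base R warns about the (intentionally) perfect fit
  model <- suppressWarnings(predict_treatment_response(dat))
  co <- model$coefficients
  expect_equal(co$estimate[co$term == "nii_sd"], -26.57, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "(Intercept)"], 1.5, tolerance = 1e-8)
  expect_equal(model$r_squared, 1, tolerance = 1e-10)
  # rank deficiency names the collinear column
  dat$fsiq <- 2 * dat$age
  expect_error(predict_treatment_response(dat), "collinear.*fsiq")
})
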