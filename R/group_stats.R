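#' Cohen's d for a paired contrast from its t statistic
#'
#' The paired-design identity `d = t / sqrt(n)` (equivalently
#' `mean(diff) / sd(diff)`).
#'
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return Cohen's d.
#' @export
paired_d_from_t <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

#' Paired t-test with effect size and Bonferroni correction
#'
#' Two-tailed paired t-test on `a - b` with `df = n - 1`, Cohen's d for the
#' paired design (`mean(diff)/sd(diff) = t/sqrt(n)`), and the
#' Bonferroni-corrected p for a declared family of `m_family` tests.
#'
#' @param a,b paired numeric vectors in matched subject order (n >= 3).
#' @param contrast label stored on the result.
#' @param m_family Bonferroni family size.
#' @return object of class `tn_group_comparison`.
#' @export
paired_t <- function(a, b, contrast = "paired", m_family = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired t undefined for '", contrast, "'")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(contrast = contrast,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_bonferroni = min(1, m_family * tt$p.value),
                 d = mean(d) / stats::sd(d),
                 n = length(a), type = "paired"),
            class = "tn_group_comparison")
}

#' Welch two-sample t-test with effect sizes
#'
#' Two-tailed Welch t-test (Satterthwaite df). Because no single two-sample
#' Cohen's d convention exists, two are reported: `d` uses the classical
#' pooled SD (n1 + n2 - 2 denominator) and `d_welch` uses the
#' variance-average SD `sqrt((s1^2 + s2^2)/2)` consistent with the Welch
#' statistic.
#'
#' @param x,y numeric group samples (each n >= 3).
#' @param contrast label stored on the result.
#' @param m_family Bonferroni family size.
#' @return object of class `tn_group_comparison` with fields `d` (pooled
#'   convention) and `d_welch`.
#' @export
welch_t <- function(x, y, contrast = "welch", m_family = 1L) {
  stopifnot(length(x) >= 3L, length(y) >= 3L)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    stop("zero variance in both groups: Welch t undefined for '",
         contrast, "'")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  sp <- sqrt(((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2))
  structure(list(contrast = contrast,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_bonferroni = min(1, m_family * tt$p.value),
                 d = (mean(x) - mean(y)) / sp,
                 d_welch = (mean(x) - mean(y)) / sqrt((vx + vy) / 2),
                 n = c(n1, n2), type = "welch"),
            class = "tn_group_comparison")
}

#' @export
print.tn_group_comparison <- function(x, ...) {
  cat(sprintf("%s: t(%.4g) = %.3f, p = %.4g (Bonferroni %.4g), d = %.3f\n",
              x$contrast, x$df, x$t, x$p_raw, x$p_bonferroni, x$d))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p_raw vector of raw p values.
#' @param m declared family size (must be at least `length(p_raw)`).
#' @return `pmin(1, m * p_raw)`.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= length(p_raw), all(p_raw >= 0 & p_raw <= 1))
  pmin(1, m * p_raw)
}

#' Composite CPT performance score
#'
#' Averages the z-scores (standardised across the analysis sample) of the
#' four continuous-performance-task measures — omission errors, commission
#' errors, mean RT, RT SD — so that lower values reflect better sustained
#' attention.
#'
#' @param cpt data frame/matrix with the four CPT T-score columns.
#' @return numeric composite per row.
#' @export
cpt_composite <- function(cpt) {
  cpt <- as.matrix(cpt)
  stopifnot(ncol(cpt) == 4L, nrow(cpt) >= 2L)
  rowMeans(scale(cpt))
}

#' Brain-behavior Pearson correlations
#'
#' Correlates each dynamic-connectivity metric with each clinical measure
#' over the pooled sample (complete cases only), Bonferroni-correcting each
#' metric's p values for the number of clinical measures tested.
#'
#' @param data data frame holding all columns.
#' @param metrics character vector of metric column names.
#' @param clinical character vector of clinical measure column names.
#' @return data frame: `metric`, `clinical`, `n`, `r`, `p_raw`,
#'   `p_bonferroni`.
#' @export
brain_behavior_correlations <- function(data,
                                        metrics = c("mean_dwell_s",
                                                    "nii_mean", "nii_sd"),
                                        clinical = c("conners_inattention",
                                                     "conners_hyperactivity")) {
  stopifnot(all(c(metrics, clinical) %in% names(data)))
  m_fam <- length(clinical)
  out <- expand.grid(metric = metrics, clinical = clinical,
                     stringsAsFactors = FALSE)[, 2:1]
  out <- out[order(match(out$metric, metrics)), c("metric", "clinical")]
  rows <- lapply(seq_len(nrow(out)), function(i) {
    x <- data[[out$metric[i]]]
    y <- data[[out$clinical[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 10L) {
      stop("fewer than 10 complete cases for ", out$metric[i], " vs ",
           out$clinical[i])
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(metric = out$metric[i], clinical = out$clinical[i],
               n = sum(ok), r = unname(ct$estimate), p_raw = ct$p.value,
               p_bonferroni = min(1, m_fam * ct$p.value))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Predict treatment-induced attention change from placebo NII dynamics
#'
#' Ordinary least squares with the change in composite CPT score as outcome
#' and the placebo-condition NII mean and variability as predictors, with
#' age, FSIQ and mean framewise displacement as confound covariates.
#' Per-coefficient two-tailed t tests are reported.
#'
#' @param data data frame with outcome, predictor and covariate columns.
#' @param outcome outcome column name.
#' @param predictors predictor column names.
#' @param covariates confound column names.
#' @return object of class `tn_prediction_model`: `coefficients` (data
#'   frame: term, estimate, se, t, p), `r_squared`, `confint` (95%), `n`,
#'   and the underlying `lm` fit.
#' @export
predict_treatment_response <- function(data,
                                       outcome = "cpt_composite_change",
                                       predictors = c("nii_mean", "nii_sd"),
                                       covariates = c("age", "fsiq",
                                                      "mean_fd")) {
  cols <- c(outcome, predictors, covariates)
  stopifnot(all(cols %in% names(data)))
  df <- data[stats::complete.cases(data[cols]), cols]
  n <- nrow(df)
  p_terms <- length(predictors) + length(covariates)
  if (n <= p_terms + 2L) {
    stop("need n > number of predictors + 2 (n = ", n, ")")
  }
  mm <- stats::model.matrix(
    ~ ., data = df[, c(predictors, covariates), drop = FALSE])
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fm <- stats::as.formula(paste(outcome, "~",
                                paste(c(predictors, covariates),
                                      collapse = " + ")))
  fit <- stats::lm(fm, data = df)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  structure(list(coefficients = co, r_squared = sm$r.squared,
                 confint = stats::confint(fit), n = n, fit = fit),
            class = "tn_prediction_model")
}

#' @export
print.tn_prediction_model <- function(x, ...) {
  cat(sprintf("<tn_prediction_model> n = %d, R^2 = %.3f\n", x$n,
              x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}
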