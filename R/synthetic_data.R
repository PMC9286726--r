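#' Per-subject network time series container
#'
#' A T x 4 numeric matrix (columns SN, LFPN, RFPN, DMN) with a group label,
#' the repetition time in seconds, and — for synthetic subjects — the hidden
#' state sequence that generated each timepoint.
#'
#' @param x T x 4 numeric matrix.
#' @param group group label, e.g. `"ADHD-MPH"`, `"ADHD-Placebo"`, `"TD"`.
#' @param TR repetition time in seconds.
#' @param state_seq optional integer vector of length T of generating states.
#' @return object of class `tn_network_ts` (a matrix with attributes).
#' @export
network_ts <- function(x, group = NA_character_, TR = 2.3, state_seq = NULL) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), ncol(x) == 4L, TR > 0)
  colnames(x) <- tn_networks
  if (!is.null(state_seq)) stopifnot(length(state_seq) == nrow(x))
  structure(x, group = group, TR = TR, state_seq = state_seq,
            class = c("tn_network_ts", class(x)))
}

#' Construct a latent brain state with analytically known NII
#'
#' Builds a 4 x 4 correlation-scale covariance over (SN, LFPN, RFPN, DMN)
#' from target SN-FPN and SN-DMN couplings plus a background level for the
#' remaining pairs. The implied Network Interaction Index is known in closed
#' form: `true_nii = mean(fisher_z(sn_fpn)) - fisher_z(sn_dmn)`.
#'
#' If the assembled matrix is not positive definite it is repaired once by
#' flooring eigenvalues at `1e-6` and rescaling back to unit diagonal; a
#' matrix that is still indefinite after repair is rejected.
#'
#' @param target_sn_fpn SN-FPN correlation; length 1 (used for both L and R)
#'   or length 2 `(SN-LFPN, SN-RFPN)`. All targets must lie in (-1, 1).
#' @param target_sn_dmn SN-DMN correlation.
#' @param background correlation used for the LFPN-DMN and RFPN-DMN pairs.
#' @param lfpn_rfpn correlation between the two FPN components; homotopic
#'   networks couple strongly, so the default is 0.5.
#' @param state_id integer label stored on the state.
#' @return object of class `tn_state_spec`: list with `state_id`,
#'   `covariance` (4 x 4, unit diagonal) and `true_nii` (Fisher-z units,
#'   recomputed from the final, possibly repaired, matrix).
#' @examples
#' s <- make_state_covariance(0.5, -0.5)
#' s$true_nii  # 1.0986 = atanh(0.5) - atanh(-0.5)
#' @export
make_state_covariance <- function(target_sn_fpn, target_sn_dmn,
                                  background = 0, lfpn_rfpn = 0.5,
                                  state_id = 1L) {
  fpn <- rep_len(as.numeric(target_sn_fpn), 2L)
  vals <- c(fpn, target_sn_dmn, background, lfpn_rfpn)
  if (any(abs(vals) >= 1)) stop("all target correlations must lie in (-1, 1)")
  R <- diag(4)
  dimnames(R) <- list(tn_networks, tn_networks)
  R[1, 2] <- R[2, 1] <- fpn[1]
  R[1, 3] <- R[3, 1] <- fpn[2]
  R[1, 4] <- R[4, 1] <- target_sn_dmn
  R[2, 3] <- R[3, 2] <- lfpn_rfpn
  R[2, 4] <- R[4, 2] <- background
  R[3, 4] <- R[4, 3] <- background
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    lam <- pmax(e$values, 1e-6)
    R <- e$vectors %*% (lam * t(e$vectors))
    R <- stats::cov2cor(R)
    dimnames(R) <- list(tn_networks, tn_networks)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
      stop(sprintf(paste0("non-repairable indefinite covariance for targets ",
                          "sn_fpn = (%s), sn_dmn = %.3g, background = %.3g"),
                   paste(signif(fpn, 3), collapse = ", "),
                   target_sn_dmn, background))
    }
  }
  true_nii <- mean(fisher_z(c(R[1, 2], R[1, 3]))) - fisher_z(R[1, 4])
  structure(list(state_id = as.integer(state_id), covariance = R,
                 true_nii = true_nii),
            class = "tn_state_spec")
}

#' Cohort specification for the synthetic generator
#'
#' Describes one group of subjects whose time series arise from a hidden
#' Markov chain over `length(states)` latent brain states with
#' self-transition probability `p_self` (off-state transitions uniform, so
#' the expected dwell time is `1 / (1 - p_self)` timepoints), Gaussian
#' emissions with the active state's covariance, optional isotropic emission
#' noise, and an optional AR(1) temporal smoothness flag (default off).
#'
#' @param group_name one of `"ADHD-MPH"`, `"ADHD-Placebo"`, `"TD"` (free-form
#'   labels are allowed).
#' @param n_subjects number of subjects.
#' @param states list of [make_state_covariance()] objects.
#' @param p_self self-transition probability in (0, 1).
#' @param T timepoints per subject (>= 50).
#' @param TR repetition time, seconds.
#' @param emission_noise_sd isotropic Gaussian noise sd added to emissions.
#' @param ar_phi AR(1) coefficient in `[0, 1)`; 0 (default) gives i.i.d.
#'   emissions given the state. When positive, innovations are scaled by
#'   `sqrt(1 - ar_phi^2)` so the stationary covariance within a state is
#'   unchanged.
#' @param seed cohort-level seed; per-subject seeds are split from it.
#' @return object of class `tn_cohort_spec`.
#' @export
cohort_spec <- function(group_name, n_subjects, states, p_self,
                        T = 201L, TR = 2.3, emission_noise_sd = 0,
                        ar_phi = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, T >= 50L, TR > 0,
            p_self > 0, p_self < 1, emission_noise_sd >= 0,
            ar_phi >= 0, ar_phi < 1,
            length(states) >= 1,
            all(vapply(states, inherits, logical(1), "tn_state_spec")))
  structure(list(group_name = group_name, n_subjects = as.integer(n_subjects),
                 states = states, n_states = length(states),
                 p_self = p_self, T = as.integer(T), TR = TR,
                 emission_noise_sd = emission_noise_sd, ar_phi = ar_phi,
                 seed = as.integer(seed)),
            class = "tn_cohort_spec")
}

## Transition matrix implied by a cohort spec: diagonal p_self, off-diagonal
## (1 - p_self) / (K - 1). For K = 1 the chain is degenerate (always state 1).
tn_transition_matrix <- function(K, p_self) {
  if (K == 1L) return(matrix(1, 1, 1))
  P <- matrix((1 - p_self) / (K - 1), K, K)
  diag(P) <- p_self
  P
}

#' Simulate one subject's network time series
#'
#' Samples a hidden state sequence from the cohort's Markov chain (uniform
#' initial distribution) and emits, at each timepoint, a 4-dimensional
#' Gaussian with the active state's covariance plus isotropic noise.
#' Deterministic given `subject_seed`.
#'
#' @param cohort a [cohort_spec()].
#' @param subject_seed integer seed for this subject.
#' @return a [network_ts()] carrying the true `state_seq` attribute.
#' @export
simulate_subject <- function(cohort, subject_seed) {
  stopifnot(inherits(cohort, "tn_cohort_spec"))
  set.seed(as.integer(subject_seed))
  K <- cohort$n_states
  Tn <- cohort$T
  P <- tn_transition_matrix(K, cohort$p_self)
  s <- integer(Tn)
  s[1] <- sample.int(K, 1L)
  if (Tn > 1L) {
    u <- stats::runif(Tn - 1L)
    for (t in 2:Tn) {
      s[t] <- findInterval(u[t - 1L], cumsum(P[s[t - 1L], ]),
                           rightmost.closed = TRUE) + 1L
    }
  }
  chols <- lapply(cohort$states, function(st) chol(st$covariance))
  X <- matrix(NA_real_, Tn, 4L)
  Z <- matrix(stats::rnorm(Tn * 4L), Tn, 4L)
  for (k in seq_len(K)) {
    idx <- which(s == k)
    if (length(idx)) X[idx, ] <- Z[idx, , drop = FALSE] %*% chols[[k]]
  }
  if (cohort$emission_noise_sd > 0) {
    X <- X + matrix(stats::rnorm(Tn * 4L, sd = cohort$emission_noise_sd),
                    Tn, 4L)
  }
  if (cohort$ar_phi > 0) {
    phi <- cohort$ar_phi
    E <- X * sqrt(1 - phi^2)
    X <- apply(E, 2L, function(e) stats::filter(e, phi, method = "recursive"))
    X <- matrix(as.numeric(X), Tn, 4L)
  }
  network_ts(X, group = cohort$group_name, TR = cohort$TR, state_seq = s)
}

#' Simulate a full cohort
#'
#' Splits per-subject seeds from the cohort seed and simulates each subject.
#'
#' @param cohort a [cohort_spec()].
#' @return named list of [network_ts()] objects (`<group>_01`, ...), with the
#'   per-subject seeds attached as attribute `subject_seeds`.
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "tn_cohort_spec"))
  set.seed(cohort$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, cohort$n_subjects)
  subjects <- lapply(seeds, simulate_subject, cohort = cohort)
  names(subjects) <- sprintf("%s_%02d", cohort$group_name,
                             seq_len(cohort$n_subjects))
  attr(subjects, "subject_seeds") <- seeds
  subjects
}

#' Behavioral coupling specification
#'
#' Coefficients linking synthetic behavioral scores to dynamic-connectivity
#' metrics: the composite CPT change score is linear in the subject's NII
#' variability, and Conners inattention / hyperactivity T-scores are linear
#' in mean dwell time (seconds) and NII variability. Conners scores are
#' clipped to the normed T-score range [30, 100]. Age, FSIQ and mean
#' framewise displacement covariates are drawn uniformly from the recorded
#' ranges.
#'
#' @param intercept,slope_on_nii_sd,noise_sd composite-CPT-change model:
#'   `change = intercept + slope_on_nii_sd * nii_sd + N(0, noise_sd)`.
#' @param conners_inatt,conners_hyper length-4 vectors
#'   `(intercept, slope_dwell, slope_nii_sd, noise_sd)`.
#' @param age_range,fsiq_range,fd_range uniform covariate ranges.
#' @return object of class `tn_behavior_spec`.
#' @export
behavior_spec <- function(intercept = 0, slope_on_nii_sd = -26.57,
                          noise_sd = 5,
                          conners_inatt = c(60, 0.5, -15, 8),
                          conners_hyper = c(58, 0.4, -12, 8),
                          age_range = c(7, 16), fsiq_range = c(80, 120),
                          fd_range = c(0.03, 0.15)) {
  stopifnot(noise_sd >= 0, conners_inatt[4] >= 0, conners_hyper[4] >= 0)
  structure(list(intercept = intercept, slope_on_nii_sd = slope_on_nii_sd,
                 noise_sd = noise_sd, conners_inatt = conners_inatt,
                 conners_hyper = conners_hyper, age_range = age_range,
                 fsiq_range = fsiq_range, fd_range = fd_range),
            class = "tn_behavior_spec")
}

#' Simulate behavioral scores linked to connectivity metrics
#'
#' @param metrics data frame with one row per subject and columns
#'   `subject_id`, `nii_sd` and `mean_dwell_s`.
#' @param spec a [behavior_spec()].
#' @param seed integer seed.
#' @return data frame with `subject_id`, `cpt_composite_change`,
#'   `conners_inattention`, `conners_hyperactivity`, `age`, `fsiq`,
#'   `mean_fd`; covariate ranges are attached as attribute `covariate_ranges`.
#' @export
simulate_behavior <- function(metrics, spec = behavior_spec(), seed = 1L) {
  stopifnot(inherits(spec, "tn_behavior_spec"),
            all(c("subject_id", "nii_sd", "mean_dwell_s") %in% names(metrics)),
            !anyNA(metrics$nii_sd), !anyNA(metrics$mean_dwell_s))
  set.seed(as.integer(seed))
  n <- nrow(metrics)
  clip_t <- function(x) pmin(pmax(x, 30), 100)
  ci <- spec$conners_inatt
  ch <- spec$conners_hyper
  out <- data.frame(
    subject_id = metrics$subject_id,
    cpt_composite_change = spec$intercept +
      spec$slope_on_nii_sd * metrics$nii_sd +
      stats::rnorm(n, sd = spec$noise_sd),
    conners_inattention = clip_t(ci[1] + ci[2] * metrics$mean_dwell_s +
                                   ci[3] * metrics$nii_sd +
                                   stats::rnorm(n, sd = ci[4])),
    conners_hyperactivity = clip_t(ch[1] + ch[2] * metrics$mean_dwell_s +
                                     ch[3] * metrics$nii_sd +
                                     stats::rnorm(n, sd = ch[4])),
    age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    fsiq = stats::runif(n, spec$fsiq_range[1], spec$fsiq_range[2]),
    mean_fd = stats::runif(n, spec$fd_range[1], spec$fd_range[2]),
    stringsAsFactors = FALSE)
  attr(out, "covariate_ranges") <- list(age = spec$age_range,
                                        fsiq = spec$fsiq_range,
                                        fd = spec$fd_range)
  out
}

#' Default three-group study emulation
#'
#' The stated synthetic world mirroring the study design: 27 ADHD subjects
#' scanned under methylphenidate (3 latent states, short dwell) and placebo
#' (2 latent states, long dwell, higher mean / lower spread of state NIIs),
#' and 49 typically-developing subjects (3 states, short dwell); T = 201
#' timepoints at TR = 2.3 s as acquired in the study.
#'
#' @param seed base seed; group seeds are split deterministically from it.
#' @param n_mph,n_placebo,n_td group sizes.
#' @param T timepoints per subject.
#' @return named list of three [cohort_spec()] objects.
#' @export
default_cohorts <- function(seed = 1L, n_mph = 27L, n_placebo = 27L,
                            n_td = 49L, T = 201L) {
  states3 <- list(make_state_covariance(0.5, -0.3, background = 0.1,
                                        state_id = 1L),
                  make_state_covariance(0.1, 0.1, background = 0.1,
                                        state_id = 2L),
                  make_state_covariance(-0.3, 0.4, background = 0.1,
                                        state_id = 3L))
  states2 <- list(make_state_covariance(0.45, -0.05, background = 0.1,
                                        state_id = 1L),
                  make_state_covariance(0.25, 0.1, background = 0.1,
                                        state_id = 2L))
  seed <- as.integer(seed)
  list(
    "ADHD-MPH" = cohort_spec("ADHD-MPH", n_mph, states3, p_self = 0.90,
                             T = T, emission_noise_sd = 0.2,
                             seed = seed),
    "ADHD-Placebo" = cohort_spec("ADHD-Placebo", n_placebo, states2,
                                 p_self = 0.95, T = T,
                                 emission_noise_sd = 0.2,
                                 seed = seed + 1000L),
    "TD" = cohort_spec("TD", n_td, states3, p_self = 0.90, T = T,
                       emission_noise_sd = 0.2, seed = seed + 2000L))
}
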