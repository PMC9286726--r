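# Shared fixtures and independent oracles used across the suite.

# Strongly separated 2- and 3-state worlds: states oppose each other on all
# six network pairs so windows are identifiable; used by the recovery
# experiments.
sep_states2 <- function() {
  list(make_state_covariance(0.6, -0.5, background = -0.4, lfpn_rfpn = 0.7,
                             state_id = 1L),
       make_state_covariance(-0.5, 0.5, background = 0.4, lfpn_rfpn = -0.3,
                             state_id = 2L))
}

sep_states3 <- function() {
  list(make_state_covariance(0.7, -0.5, background = 0, lfpn_rfpn = 0.7,
                             state_id = 1L),
       make_state_covariance(0, 0.6, background = 0.4, lfpn_rfpn = 0.2,
                             state_id = 2L),
       make_state_covariance(-0.5, 0, background = -0.3, lfpn_rfpn = 0.5,
                             state_id = 3L))
}

# Brute-force weighted Pearson correlation: explicit loops, no vector algebra
# shared with the implementation.
brute_weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- 0; my <- 0
  for (i in seq_along(x)) { mx <- mx + w[i] * x[i]; my <- my + w[i] * y[i] }
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + w[i] * (x[i] - mx) * (y[i] - my)
    sxx <- sxx + w[i] * (x[i] - mx)^2
    syy <- syy + w[i] * (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Brute-force dwell statistics: scans the sequence element by element.
brute_dwell <- function(labels) {
  runs <- list()
  cur <- labels[1]; len <- 1L
  if (length(labels) > 1) {
    for (i in 2:length(labels)) {
      if (labels[i] == cur) {
        len <- len + 1L
      } else {
        runs[[length(runs) + 1L]] <- c(cur, len)
        cur <- labels[i]; len <- 1L
      }
    }
  }
  runs[[length(runs) + 1L]] <- c(cur, len)
  states <- sort(unique(vapply(runs, `[`, numeric(1), 1)))
  per_state <- vapply(states, function(s) {
    lens <- vapply(runs[vapply(runs, `[`, numeric(1), 1) == s],
                   `[`, numeric(1), 2)
    mean(lens)
  }, numeric(1))
  list(states = states, mean_runs = per_state,
       subject_mean = mean(per_state),
       total = sum(vapply(runs, `[`, numeric(1), 2)))
}

# Adjusted Rand index (contingency-table closed form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Simulate one group and return windows + per-subject estimated dwell plus
# windowing-blurred truth (state sequence restricted to window centers).
dwell_experiment_group <- function(seed, p_self, n = 20, T = 300, L = 10) {
  co <- cohort_spec("G", n, sep_states2(), p_self = p_self, T = T,
                    seed = seed)
  subs <- simulate_cohort(co)
  spec <- window_spec(L, L / 3)
  wins <- lapply(subs, sliding_window_correlations, spec = spec)
  part <- group_state_partition(wins, k = 2, seed = seed, n_resamples = 30)
  est <- vapply(names(wins), function(id)
    dwell_times(part$labels[[id]])$mean_dwell_windows, numeric(1))
  truth <- vapply(names(subs), function(id) {
    centers <- wins[[id]]$centers
    dwell_times(attr(subs[[id]], "state_seq")[centers])$mean_dwell_windows
  }, numeric(1))
  list(est = est, truth = truth)
}

# Pooled-window NII metrics for a cohort without state labels (mean/SD over
# all windows), used where clustering is not under test.
quick_nii_metrics <- function(states, n, T, seed, group = "G", L = 20) {
  co <- cohort_spec(group, n, states, p_self = 0.9, T = T, seed = seed)
  subs <- simulate_cohort(co)
  spec <- window_spec(L)
  rows <- lapply(names(subs), function(id) {
    nii <- nii_window(sliding_window_correlations(subs[[id]], spec)$z6)
    data.frame(subject_id = id, group = group, nii_mean = mean(nii),
               nii_sd = stats::sd(nii))
  })
  do.call(rbind, rows)
}
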