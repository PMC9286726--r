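#' Pipeline configuration
#'
#' A single serialisable object holding every tunable of the analysis
#' pipeline; [run_pipeline()] writes the resolved configuration alongside
#' its outputs.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_mph,n_placebo,n_td simulated group sizes.
#' @param T timepoints per subject.
#' @param window_length,window_theta,window_step sliding-window parameters
#'   (see [window_spec()]).
#' @param k_range candidate state counts for [select_k()].
#' @param n_resamples,subsample_frac,max_windows consensus-clustering
#'   parameters (see [consensus_kmeans()]).
#' @param nii_mode NII variability convention, `"pooled"` or `"state"`.
#' @param m_family_groups Bonferroni family size for the three group
#'   contrasts.
#' @param m_family_clinical Bonferroni family size for clinical measures.
#' @param cart_cp CART complexity parameter.
#' @param behavior a [behavior_spec()].
#' @return list of class `tn_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_mph = 27L, n_placebo = 27L,
                            n_td = 49L, T = 201L, window_length = 20L,
                            window_theta = window_length / 3,
                            window_step = 1L, k_range = 2:4,
                            n_resamples = 50L, subsample_frac = 0.8,
                            max_windows = 2000L,
                            nii_mode = c("pooled", "state"),
                            m_family_groups = 3L, m_family_clinical = 2L,
                            cart_cp = 0.01, behavior = behavior_spec()) {
  nii_mode <- match.arg(nii_mode)
  structure(list(seed = as.integer(seed), n_mph = n_mph,
                 n_placebo = n_placebo, n_td = n_td, T = T,
                 window_length = window_length, window_theta = window_theta,
                 window_step = window_step, k_range = k_range,
                 n_resamples = n_resamples, subsample_frac = subsample_frac,
                 max_windows = max_windows, nii_mode = nii_mode,
                 m_family_groups = m_family_groups,
                 m_family_clinical = m_family_clinical,
                 cart_cp = cart_cp, behavior = behavior),
            class = "tn_pipeline_config")
}

tn_stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[trinetdyn] %-10s %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  res
}

#' Run the full dynamic triple-network pipeline
#'
#' Simulate (three groups) -> sliding windows -> per-group consensus brain
#' states -> subject metrics -> behavior -> group statistics ->
#' classification -> treatment-response regression. Deterministic given
#' `config$seed`; when `out_dir` is given, every artifact (time series,
#' manifest, ground truth, windowed z matrices, partitions, metrics CSV,
#' comparison CSV, classification and regression JSON, resolved config) is
#' written under it with provenance headers.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param subjects optional named list of groups (each a named list of
#'   [network_ts()]); when supplied, the simulate stage is skipped.
#' @param verbose print per-stage timing messages.
#' @return list with `config`, `metrics`, `behavior`, `partitions`,
#'   `comparisons`, `classification`, `regression`, `correlations`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         subjects = NULL, verbose = interactive()) {
  stopifnot(inherits(config, "tn_pipeline_config"))
  hash <- tn_config_hash(config)
  prov <- list(config_hash = hash, seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_json <- config
    cfg_json$behavior <- unclass(cfg_json$behavior)
    jsonlite::write_json(c(list(config_hash = hash), unclass(cfg_json)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cohorts <- default_cohorts(config$seed, n_mph = config$n_mph,
                             n_placebo = config$n_placebo,
                             n_td = config$n_td, T = config$T)
  if (is.null(subjects)) {
    subjects <- tn_stage("simulate", verbose, {
      lapply(cohorts, simulate_cohort)
    })
    if (!is.null(out_dir)) {
      for (g in names(subjects)) {
        write_cohort(subjects[[g]], cohorts[[g]],
                     file.path(out_dir, "timeseries", g), provenance = prov)
      }
    }
  }
  wspec <- window_spec(config$window_length, config$window_theta,
                       config$window_step)
  windows <- tn_stage("windows", verbose, {
    lapply(subjects, function(grp) lapply(grp, sliding_window_correlations,
                                          spec = wspec))
  })
  if (!is.null(out_dir)) {
    wdir <- file.path(out_dir, "windows")
    dir.create(wdir, showWarnings = FALSE)
    for (g in names(windows)) {
      for (id in names(windows[[g]])) {
        write_windows(windows[[g]][[id]],
                      file.path(wdir, paste0(id, "_z6.tsv")),
                      provenance = prov)
      }
    }
  }
  partitions <- tn_stage("states", verbose, {
    out <- list()
    for (g in names(windows)) {
      out[[g]] <- group_state_partition(
        windows[[g]], k = NULL, k_range = config$k_range,
        n_resamples = config$n_resamples,
        subsample_frac = config$subsample_frac,
        max_windows = config$max_windows,
        seed = config$seed + match(g, names(windows)), group_name = g)
    }
    out
  })
  if (!is.null(out_dir)) {
    for (g in names(partitions)) {
      write_partition(partitions[[g]], file.path(out_dir, "states"),
                      provenance = prov)
    }
  }
  metrics <- tn_stage("metrics", verbose, {
    rows <- list()
    for (g in names(subjects)) {
      for (id in names(subjects[[g]])) {
        row <- tryCatch(
          subject_metrics(subjects[[g]][[id]], windows[[g]][[id]],
                          partitions[[g]]$labels[[id]],
                          mode = config$nii_mode),
          error = function(e) stop(sprintf("subject %s: %s", id,
                                           conditionMessage(e))))
        rows[[id]] <- cbind(data.frame(subject_id = id, group = g), row)
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })
  if (!is.null(out_dir)) {
    tn_write_table(metrics, file.path(out_dir, "metrics.csv"), sep = ",",
                   provenance = prov)
  }
  behavior <- tn_stage("behavior", verbose, {
    simulate_behavior(metrics, config$behavior, seed = config$seed + 500L)
  })
  comparisons <- tn_stage("compare", verbose, {
    tn_group_comparisons(metrics, m_family = config$m_family_groups)
  })
  correlations <- tn_stage("correlate", verbose, {
    pooled <- metrics$group %in% c("ADHD-Placebo", "TD")
    dat <- cbind(metrics[pooled, ],
                 behavior[match(metrics$subject_id[pooled],
                                behavior$subject_id), -1])
    brain_behavior_correlations(dat)
  })
  classification <- tn_stage("classify", verbose, {
    ctl <- cart_control(cp = config$cart_cp)
    pairs <- list(c("ADHD-MPH", "ADHD-Placebo"), c("ADHD-Placebo", "TD"),
                  c("ADHD-MPH", "TD"))
    lapply(pairs, function(p) {
      sel <- metrics$group %in% p
      loocv_accuracy(metrics[sel, c("nii_mean", "nii_sd")],
                     metrics$group[sel], control = ctl,
                     pair = paste(p, collapse = " vs "))
    })
  })
  regression <- tn_stage("predict", verbose, {
    plac <- metrics[metrics$group == "ADHD-Placebo", ]
    dat <- cbind(plac, behavior[match(plac$subject_id,
                                      behavior$subject_id), -1])
    predict_treatment_response(dat)
  })
  if (!is.null(out_dir)) {
    cmp_df <- do.call(rbind, lapply(comparisons, function(x)
      data.frame(contrast = x$contrast, type = x$type, t = x$t, df = x$df,
                 p_raw = x$p_raw, p_bonferroni = x$p_bonferroni, d = x$d)))
    tn_write_table(cmp_df, file.path(out_dir, "comparisons.csv"), sep = ",",
                   provenance = prov)
    tn_write_table(behavior, file.path(out_dir, "behavior.csv"), sep = ",",
                   provenance = prov)
    tn_write_table(correlations, file.path(out_dir, "correlations.csv"),
                   sep = ",", provenance = prov)
    jsonlite::write_json(lapply(classification, function(x)
      list(pair = x$pair, accuracy = x$accuracy, nir = x$nir,
           p_vs_nir = x$p_vs_nir)),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(list(coefficients = regression$coefficients,
                              r_squared = regression$r_squared,
                              n = regression$n),
                         file.path(out_dir, "regression.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(config = config, metrics = metrics, behavior = behavior,
                 partitions = partitions, comparisons = comparisons,
                 correlations = correlations,
                 classification = classification, regression = regression))
}

## The three-contrast family (paired MPH vs Placebo; Welch vs TD) for each
## of the three headline metrics.
tn_group_comparisons <- function(metrics, m_family = 3L) {
  out <- list()
  for (metric in c("mean_dwell_s", "nii_mean", "nii_sd")) {
    mph <- metrics[metrics$group == "ADHD-MPH", metric]
    plc <- metrics[metrics$group == "ADHD-Placebo", metric]
    td <- metrics[metrics$group == "TD", metric]
    nm <- function(a, b) sprintf("%s: %s vs %s", metric, a, b)
    if (length(mph) == length(plc) && length(mph) >= 3L) {
      out[[nm("ADHD-MPH", "ADHD-Placebo")]] <-
        paired_t(mph, plc, contrast = nm("ADHD-MPH", "ADHD-Placebo"),
                 m_family = m_family)
    }
    out[[nm("ADHD-Placebo", "TD")]] <-
      welch_t(plc, td, contrast = nm("ADHD-Placebo", "TD"),
              m_family = m_family)
    out[[nm("ADHD-MPH", "TD")]] <-
      welch_t(mph, td, contrast = nm("ADHD-MPH", "TD"), m_family = m_family)
  }
  out
}
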