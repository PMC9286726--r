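#' Network Interaction Index of one (or many) windows
#'
#' `NII = mean(z(SN,LFPN), z(SN,RFPN)) - z(SN,DMN)` in Fisher-z units: the
#' SN-FPN coupling (left/right averaged) minus the SN-DMN coupling. Larger
#' values mean the salience network is engaged with the frontoparietal
#' system while disengaged from the default mode network.
#'
#' @param z6 a length-6 Fisher-z vector in the package's fixed pair order,
#'   or an `n x 6` matrix of such rows (e.g. `tn_windows$z6`).
#' @return numeric NII value(s).
#' @examples
#' nii_window(c(0.5493, 0.5493, -0.5493, 0, 0, 0))  # 1.0986
#' @export
nii_window <- function(z6) {
  if (is.null(dim(z6))) {
    stopifnot(length(z6) == 6L, all(is.finite(z6)))
    return((z6[[1]] + z6[[2]]) / 2 - z6[[3]])
  }
  z6 <- as.matrix(z6)
  stopifnot(ncol(z6) == 6L, all(is.finite(z6)))
  (z6[, 1] + z6[, 2]) / 2 - z6[, 3]
}

#' Per-subject summary of the time-varying NII
#'
#' Given one subject's per-window NII series and the window state labels,
#' reports per-state mean NIIs and the subject's NII mean and variability
#' (sample SD). Two variability conventions are exposed:
#' `mode = "pooled"` (default) takes mean and SD over all windows, i.e.
#' across all states' windows; `mode = "state"` takes them over the
#' per-state mean NIIs (degenerate at k = 1, where the SD is reported
#' missing with a warning).
#'
#' @param nii numeric per-window NII series.
#' @param labels per-window state labels, same length.
#' @param mode `"pooled"` or `"state"`.
#' @return list with `nii_mean`, `nii_sd`, `state_means` (named by state),
#'   `mode`.
#' @export
subject_nii_summary <- function(nii, labels, mode = c("pooled", "state")) {
  mode <- match.arg(mode)
  stopifnot(length(nii) == length(labels), length(nii) >= 1L)
  states <- sort(unique(labels))
  state_means <- vapply(states, function(s) mean(nii[labels == s]),
                        numeric(1))
  names(state_means) <- states
  if (mode == "pooled") {
    nii_mean <- mean(nii)
    nii_sd <- if (length(nii) > 1L) stats::sd(nii) else NA_real_
  } else {
    nii_mean <- mean(state_means)
    if (length(state_means) < 2L) {
      warning("state-level SD undefined with a single state; reporting NA")
      nii_sd <- NA_real_
    } else {
      nii_sd <- stats::sd(state_means)
    }
  }
  list(nii_mean = nii_mean, nii_sd = nii_sd, state_means = state_means,
       mode = mode)
}

#' Static (full-session) NII
#'
#' The NII formula applied to Pearson correlations computed over the whole
#' time series, the time-averaged counterpart of the windowed NII.
#'
#' @param ts a [network_ts()] or T x 4 numeric matrix (T >= 3).
#' @return static NII in Fisher-z units.
#' @export
static_nii <- function(ts) {
  X <- if (inherits(ts, "tn_network_ts")) unclass(ts) else as.matrix(ts)
  stopifnot(ncol(X) == 4L, nrow(X) >= 3L)
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance component(s): ",
         paste(tn_networks[v == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  z6 <- fisher_z(R[cbind(tn_pair_i, tn_pair_j)])
  nii_window(z6)
}

#' Template-matching goodness of fit
#'
#' Scores how well a spatial component map matches a network template:
#' mean map value inside the template mask minus mean value outside it.
#'
#' @param component_map numeric array of voxel values.
#' @param template_mask logical array of the same shape with at least one
#'   `TRUE` and one `FALSE` voxel.
#' @return list of class `tn_template_match` with `goodness_of_fit`.
#' @export
template_goodness_of_fit <- function(component_map, template_mask) {
  stopifnot(is.numeric(component_map), is.logical(template_mask),
            length(component_map) == length(template_mask))
  if (!any(template_mask) || all(template_mask)) {
    stop("degenerate template mask: needs >= 1 voxel inside and outside")
  }
  gof <- mean(component_map[template_mask]) -
    mean(component_map[!template_mask])
  structure(list(goodness_of_fit = gof), class = "tn_template_match")
}

#' Select the component best matching a template
#'
#' Applies [template_goodness_of_fit()] to each candidate map and returns
#' the argmax, breaking exact ties toward the lowest index.
#'
#' @param maps list of numeric arrays (candidate component maps).
#' @param mask logical template mask shared by all maps.
#' @return list with `index`, `name` (if `maps` is named), and `gof` (vector
#'   of all goodness-of-fit values).
#' @export
select_component <- function(maps, mask) {
  stopifnot(length(maps) >= 1L)
  gof <- vapply(maps, function(m)
    template_goodness_of_fit(m, mask)$goodness_of_fit, numeric(1))
  idx <- which.max(gof)   # which.max already prefers the lowest index on ties
  list(index = idx, name = names(maps)[idx], gof = gof)
}

#' Full per-subject metric row
#'
#' Convenience wrapper producing the analysis features for one subject:
#' windowed NII mean and variability (per `mode`), per-state mean NIIs,
#' mean dwell time, and the static NII.
#'
#' @param ts the subject's [network_ts()].
#' @param windows the subject's [sliding_window_correlations()] output.
#' @param labels per-window state labels for this subject.
#' @param mode NII variability convention, see [subject_nii_summary()].
#' @param TR repetition time in seconds (taken from `ts` when available).
#' @return one-row data frame: `nii_mean`, `nii_sd`, `static_nii`,
#'   `mean_dwell_windows`, `mean_dwell_s`, `k_visited`.
#' @export
subject_metrics <- function(ts, windows, labels, mode = "pooled", TR = NULL) {
  stopifnot(inherits(windows, "tn_windows"),
            length(labels) == nrow(windows$z6))
  if (is.null(TR)) TR <- attr(ts, "TR", exact = TRUE)
  if (is.null(TR)) TR <- 2.3
  nii <- nii_window(windows$z6)
  summ <- subject_nii_summary(nii, labels, mode = mode)
  dw <- dwell_times(labels, TR = TR, step = windows$spec$step)
  data.frame(nii_mean = summ$nii_mean, nii_sd = summ$nii_sd,
             static_nii = static_nii(ts),
             mean_dwell_windows = dw$mean_dwell_windows,
             mean_dwell_s = dw$mean_dwell_s,
             k_visited = length(summ$state_means))
}
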