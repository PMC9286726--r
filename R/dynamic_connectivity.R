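#' Fisher z-transform of a correlation coefficient
#'
#' Computes `f(cc) = 0.5 * log((1 + cc) / (1 - cc))`, the variance-stabilising
#' transform applied to every windowed correlation before clustering and NII
#' computation. Correlations are clipped to `±clip` first so degenerate
#' (perfectly correlated) windows yield large finite values rather than `Inf`.
#'
#' @param cc numeric vector of correlations.
#' @param clip magnitude at which correlations are clipped before the
#'   transform; default `0.999999` (z ~ 7.25).
#' @return numeric vector of Fisher-z values.
#' @examples
#' fisher_z(c(0, 0.5, -0.5))
#' @export
fisher_z <- function(cc, clip = 0.999999) {
  stopifnot(is.numeric(cc), is.numeric(clip), clip > 0, clip < 1)
  atanh(pmin(pmax(cc, -clip), clip))
}

#' Sliding-window specification
#'
#' Defines the tapered window used by [sliding_window_correlations()]:
#' `length_L` samples, an exponential decay constant `decay_theta` (in
#' timepoints; larger = flatter taper) and a step between consecutive window
#' positions. Defaults are 20 TRs (46 s at TR 2.3 s), `theta = L/3`, step 1.
#'
#' @param length_L window length in timepoints (>= 10).
#' @param decay_theta exponential decay constant in timepoints (> 0).
#' @param step window step in timepoints (>= 1).
#' @return an object of class `tn_window_spec`.
#' @export
window_spec <- function(length_L = 20L, decay_theta = length_L / 3, step = 1L) {
  length_L <- as.integer(length_L)
  step <- as.integer(step)
  stopifnot(length_L >= 10L, decay_theta > 0, step >= 1L)
  structure(list(length_L = length_L, decay_theta = decay_theta, step = step),
            class = "tn_window_spec")
}

#' Exponentially decaying window weights
#'
#' Weight `w_t` is proportional to `exp(-(L - 1 - t) / theta)` for
#' `t = 0, ..., L - 1`, so the most recent sample in the (causal) window
#' carries the most weight. Weights are normalised to sum to one; as
#' `theta -> Inf` they approach the uniform (rectangular) window.
#'
#' @param spec a [window_spec()], or a plain window length (with `theta`
#'   supplied) when evaluating the taper formula outside an analysis spec.
#' @param theta decay constant, only used when `spec` is a plain length.
#' @return numeric vector of length `L`, positive, increasing, summing to 1.
#' @export
exponential_weights <- function(spec, theta = NULL) {
  if (inherits(spec, "tn_window_spec")) {
    L <- spec$length_L
    theta <- spec$decay_theta
  } else {
    L <- as.integer(spec)
    stopifnot(L >= 1L, !is.null(theta), theta > 0)
  }
  t <- seq_len(L) - 1
  w <- exp(-(L - 1 - t) / theta)
  w / sum(w)
}

#' Weighted Pearson correlation
#'
#' Correlation under observation weights `w`: weighted covariance divided by
#' the product of weighted standard deviations. With uniform weights this is
#' the plain Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param w positive weights; normalised internally to sum to 1.
#' @param window optional window index, used only to label error messages
#'   raised for zero weighted variance.
#' @return correlation in `[-1, 1]`.
#' @export
weighted_pearson <- function(x, y, w, window = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(w), all(w > 0))
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    where <- if (is.null(window)) "" else sprintf(" in window %s", window)
    stop(sprintf("undefined correlation%s: zero weighted variance", where))
  }
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  min(max(r, -1), 1)
}

## Weighted 4x4 correlation matrix for one window (vectorised form of
## weighted_pearson over all pairs). Raises the same zero-variance error.
tn_weighted_corr_mat <- function(X, w, window = NULL) {
  mu <- colSums(X * w)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc, Xc * w)
  v <- diag(C)
  if (any(v <= 0)) {
    where <- if (is.null(window)) "" else sprintf(" in window %s", window)
    stop(sprintf("undefined correlation%s: zero weighted variance (%s)",
                 where, paste(colnames(X)[v <= 0], collapse = ", ")))
  }
  R <- C / sqrt(outer(v, v))
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

#' Tapered sliding-window correlations for one subject
#'
#' Slides an exponentially tapered window of `spec$length_L` timepoints over
#' the T x 4 component time series and computes, at each position, the
#' weighted Pearson correlation matrix among SN, LFPN, RFPN and DMN, plus the
#' Fisher-z transform of its 6 unique off-diagonal entries in the fixed pair
#' order SN-LFPN, SN-RFPN, SN-DMN, LFPN-RFPN, LFPN-DMN, RFPN-DMN.
#'
#' The window is causal: its recorded center is the index of the *last*
#' sample it covers, and the taper weights recent samples most heavily.
#' The number of windows is `floor((T - L) / step) + 1`.
#'
#' @param ts a [network_ts()] or a plain T x 4 numeric matrix in network
#'   order SN, LFPN, RFPN, DMN.
#' @param spec a [window_spec()].
#' @return an object of class `tn_windows`: list with `centers` (timepoint
#'   index of each window's trailing edge), `corr` (4 x 4 x n_windows array),
#'   `z6` (n_windows x 6 Fisher-z matrix), `spec`, and `TR` when known.
#' @export
sliding_window_correlations <- function(ts, spec = window_spec()) {
  X <- if (inherits(ts, "tn_network_ts")) unclass(ts) else as.matrix(ts)
  stopifnot(is.numeric(X), ncol(X) == 4L)
  if (is.null(colnames(X))) colnames(X) <- tn_networks
  Tn <- nrow(X)
  L <- spec$length_L
  if (Tn < L) {
    stop(sprintf("input too short: T = %d < window length L = %d", Tn, L))
  }
  w <- exponential_weights(spec)
  starts <- seq.int(1L, Tn - L + 1L, by = spec$step)
  nW <- length(starts)
  corr <- array(NA_real_, dim = c(4L, 4L, nW),
                dimnames = list(tn_networks, tn_networks, NULL))
  z6 <- matrix(NA_real_, nW, 6L, dimnames = list(NULL, tn_pairs))
  for (i in seq_len(nW)) {
    R <- tn_weighted_corr_mat(X[starts[i]:(starts[i] + L - 1L), , drop = FALSE],
                              w, window = i)
    corr[, , i] <- R
    z6[i, ] <- fisher_z(R[cbind(tn_pair_i, tn_pair_j)])
  }
  structure(list(centers = starts + L - 1L, corr = corr, z6 = z6, spec = spec,
                 TR = attr(ts, "TR", exact = TRUE)),
            class = "tn_windows")
}

#' @export
print.tn_windows <- function(x, ...) {
  cat(sprintf("<tn_windows> %d windows (L = %d, theta = %.3g, step = %d)\n",
              nrow(x$z6), x$spec$length_L, x$spec$decay_theta, x$spec$step))
  invisible(x)
}
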