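## k-means++ seeding (stats::kmeans has none). Returns a k x p center matrix.
tn_kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
  }
  centers
}

## One k-means run with k-means++ seeding, repeated nstart times, best
## total within-SS kept. Falls back to Lloyd restarts on degenerate draws.
tn_kmeans <- function(X, k, nstart = 5L, iter.max = 50L) {
  best <- NULL
  for (i in seq_len(nstart)) {
    cen <- unique(tn_kmeanspp_centers(X, k))
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = if (nrow(cen) == k) cen
                                     else k, iter.max = iter.max)),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop("k-means failed for k = ", k)
  best
}

#' Consensus k-means clustering of pooled connectivity windows
#'
#' Monti-style consensus clustering at a fixed `k`: `n_resamples` k-means
#' runs, each on a random `subsample_frac` fraction of windows, are
#' aggregated into a consensus matrix of co-assignment frequencies (times
#' co-clustered / times co-sampled). Final labels come from an
#' average-linkage hierarchical cut of `1 - consensus` at `k`; centroids are
#' the mean feature vector per final cluster.
#'
#' For tractability the consensus matrix is built on at most `max_windows`
#' randomly chosen windows; any remaining windows are assigned to the
#' nearest consensus centroid. Deterministic given `seed`.
#'
#' @param windows numeric matrix, one row per window (typically the pooled,
#'   per-group-standardised 6-dim Fisher-z vectors).
#' @param k number of clusters (`2 <= k < nrow(windows)`).
#' @param n_resamples number of subsampled k-means runs.
#' @param subsample_frac fraction of windows per resample, in (0, 1].
#' @param seed integer seed.
#' @param max_windows cap on the consensus-matrix dimension.
#' @param keep_consensus store the consensus matrix in the result (can be
#'   large; kept by default when its dimension is at most 2000).
#' @return object of class `tn_state_partition`: `k`, `labels` (length
#'   `nrow(windows)`, values in `1..k`), `centroids` (k x p), `consensus`
#'   (subset consensus matrix or `NULL`), `consensus_idx` (rows it covers).
#' @export
consensus_kmeans <- function(windows, k, n_resamples = 100L,
                             subsample_frac = 0.8, seed = 1L,
                             max_windows = 2000L, keep_consensus = NULL) {
  X <- as.matrix(windows)
  n <- nrow(X)
  stopifnot(k >= 2L, k < n, n_resamples >= 1L,
            subsample_frac > 0, subsample_frac <= 1)
  set.seed(as.integer(seed))
  sub_idx <- if (n > max_windows) sort(sample.int(n, max_windows)) else
    seq_len(n)
  m <- length(sub_idx)
  Xs <- X[sub_idx, , drop = FALSE]
  co_cluster <- matrix(0, m, m)
  co_sample <- matrix(0, m, m)
  msub <- max(2L, floor(subsample_frac * m))
  for (r in seq_len(n_resamples)) {
    samp <- sample.int(m, msub)
    km <- tn_kmeans(Xs[samp, , drop = FALSE], k, nstart = 1L)
    B <- matrix(0, m, k)
    B[cbind(samp, km$cluster)] <- 1
    co_cluster <- co_cluster + tcrossprod(B)
    s <- numeric(m)
    s[samp] <- 1
    co_sample <- co_sample + tcrossprod(s)
  }
  consensus <- co_cluster / pmax(co_sample, 1)
  diag(consensus) <- 1
  for (attempt in 1:5) {
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    sub_labels <- stats::cutree(hc, k = k)
    if (length(unique(sub_labels)) == k) break
    if (attempt == 5) stop("consensus cut produced an empty cluster")
  }
  centroids <- t(vapply(seq_len(k), function(c)
    colMeans(Xs[sub_labels == c, , drop = FALSE]), numeric(ncol(X))))
  labels <- integer(n)
  labels[sub_idx] <- sub_labels
  rest <- setdiff(seq_len(n), sub_idx)
  if (length(rest)) {
    d <- tn_dist_to_centers(X[rest, , drop = FALSE], centroids)
    labels[rest] <- max.col(-d, ties.method = "first")
  }
  ## refresh centroids over all windows; retry with a new seed if the full
  ## assignment emptied a cluster (bounded, then error)
  if (length(unique(labels)) < k) {
    if (seed < 1e6) {
      return(consensus_kmeans(X, k, n_resamples, subsample_frac,
                              seed = seed + 7919L, max_windows = max_windows,
                              keep_consensus = keep_consensus))
    }
    stop("empty cluster after consensus assignment; retries exhausted")
  }
  centroids <- t(vapply(seq_len(k), function(c)
    colMeans(X[labels == c, , drop = FALSE]), numeric(ncol(X))))
  colnames(centroids) <- colnames(X)
  if (is.null(keep_consensus)) keep_consensus <- m <= 2000L
  structure(list(k = k, labels = labels, centroids = centroids,
                 consensus = if (keep_consensus) consensus else NULL,
                 consensus_idx = sub_idx, seed = seed),
            class = "tn_state_partition")
}

tn_dist_to_centers <- function(X, centers) {
  d <- matrix(0, nrow(X), nrow(centers))
  for (c in seq_len(nrow(centers)))
    d[, c] <- rowSums(sweep(X, 2L, centers[c, ])^2)
  d
}

## ---- cluster-validity indices -------------------------------------------
## Each index function takes the precomputed per-k k-means summaries and
## returns its voted k. W[k] = total within-cluster SS at k clusters.

tn_index_votes <- function(X, k_range, seed, B_gap = 10L,
                           max_index_windows = 1500L,
                           index_set = c("ch", "silhouette", "db", "dunn",
                                         "gap", "hartigan", "kl",
                                         "ballhall")) {
  n <- nrow(X)
  p <- ncol(X)
  set.seed(as.integer(seed))
  k_ext <- seq.int(1L, max(k_range) + 1L)   # W needed at 1..max+1 for KL etc.
  fits <- vector("list", max(k_ext))
  W <- numeric(max(k_ext))
  W[1] <- sum(scale(X, scale = FALSE)^2)
  fits[[1]] <- list(cluster = rep(1L, n))
  for (k in k_ext[-1]) {
    fits[[k]] <- tn_kmeans(X, k, nstart = 5L)
    W[k] <- fits[[k]]$tot.withinss
  }
  totss <- W[1]
  sub <- if (n > max_index_windows) sort(sample.int(n, max_index_windows))
         else seq_len(n)
  dsub <- stats::dist(X[sub, , drop = FALSE])

  idx_fun <- list(
    ch = function() {
      ch <- vapply(k_range, function(k)
        ((totss - W[k]) / (k - 1)) / (W[k] / (n - k)), numeric(1))
      k_range[which.max(ch)]
    },
    silhouette = function() {
      sw <- vapply(k_range, function(k) {
        sil <- cluster::silhouette(fits[[k]]$cluster[sub], dsub)
        mean(sil[, "sil_width"])
      }, numeric(1))
      k_range[which.max(sw)]
    },
    db = function() {
      db <- vapply(k_range, function(k) {
        cl <- fits[[k]]$cluster
        cen <- fits[[k]]$centers
        s <- vapply(seq_len(k), function(c)
          sqrt(mean(rowSums(sweep(X[cl == c, , drop = FALSE], 2L,
                                  cen[c, ])^2))), numeric(1))
        dc <- as.matrix(stats::dist(cen))
        r <- vapply(seq_len(k), function(c)
          max(((s[c] + s[-c]) / dc[c, -c])), numeric(1))
        mean(r)
      }, numeric(1))
      k_range[which.min(db)]
    },
    dunn = function() {
      dm <- as.matrix(dsub)
      dn <- vapply(k_range, function(k) {
        cl <- fits[[k]]$cluster[sub]
        diam <- max(vapply(unique(cl), function(c) {
          idx <- which(cl == c)
          if (length(idx) < 2) 0 else max(dm[idx, idx])
        }, numeric(1)))
        sep <- min(vapply(seq_len(k - 1), function(a) {
          min(vapply((a + 1):k, function(b) {
            ia <- which(cl == a); ib <- which(cl == b)
            if (!length(ia) || !length(ib)) Inf else min(dm[ia, ib])
          }, numeric(1)))
        }, numeric(1)))
        if (diam == 0) Inf else sep / diam
      }, numeric(1))
      k_range[which.max(dn)]
    },
    gap = function() {
      rng <- apply(X, 2L, range)
      logWref <- matrix(0, B_gap, length(k_ext) - 1L)
      for (b in seq_len(B_gap)) {
        Xr <- vapply(seq_len(p), function(j)
          stats::runif(n, rng[1, j], rng[2, j]), numeric(n))
        for (k in k_ext[-1])
          logWref[b, k - 1L] <- log(tn_kmeans(Xr, k, nstart = 1L)$tot.withinss)
      }
      ks <- k_ext[-1]
      gap <- colMeans(logWref) - log(W[ks])
      se <- apply(logWref, 2L, stats::sd) * sqrt(1 + 1 / B_gap)
      in_range <- ks %in% k_range
      for (i in which(in_range)) {
        if (i + 1L <= length(ks) && gap[i] >= gap[i + 1L] - se[i + 1L])
          return(ks[i])
      }
      k_range[which.max(gap[in_range])]
    },
    hartigan = function() {
      H <- vapply(k_range, function(k)
        (W[k] / W[k + 1L] - 1) * (n - k - 1), numeric(1))
      below <- which(H <= 10)
      if (length(below)) k_range[below[1]] else k_range[which.min(H)]
    },
    kl = function() {
      diffk <- function(k) (k - 1)^(2 / p) * W[k - 1L] - k^(2 / p) * W[k]
      kl <- vapply(k_range, function(k) {
        if (k + 1L > max(k_ext)) return(NA_real_)
        denom <- diffk(k + 1L)
        if (abs(denom) < 1e-12) return(NA_real_)
        abs(diffk(k) / denom)
      }, numeric(1))
      k_range[which.max(kl)]
    },
    ballhall = function() {
      bh <- W[c(1L, k_range)] / c(1L, k_range)
      drop <- bh[-length(bh)] - bh[-1]
      k_range[which.max(drop)]
    })

  votes <- integer(0)
  failures <- character(0)
  for (nm in index_set) {
    v <- tryCatch(idx_fun[[nm]](), error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", nm, conditionMessage(e)))
      NA_integer_
    })
    votes[nm] <- v
  }
  if (all(is.na(votes))) {
    stop("all validity indices failed: ", paste(failures, collapse = "; "))
  }
  list(votes = votes, failures = failures)
}

#' Choose the number of brain states by validity-index majority vote
#'
#' Each configured cluster-validity index votes for its optimal `k` over
#' `k_range` (k-means fits with k-means++ seeding); the modal `k` wins, with
#' ties broken toward smaller `k`. The default index set comprises
#' Calinski-Harabasz, mean silhouette width, Davies-Bouldin, Dunn, the gap
#' statistic (Tibshirani first-SE-max rule), Hartigan's rule,
#' Krzanowski-Lai, and the Ball-Hall successive-drop rule.
#'
#' Distance-based indices (silhouette, Dunn) are computed on at most
#' `max_index_windows` subsampled windows for tractability. When the data
#' hold a single effective cluster no `k >= 2` is "right"; the vote
#' dispersion reported alongside the winner quantifies that instability
#' instead of silently forcing a choice.
#'
#' @param windows numeric matrix of pooled (standardised) window features.
#' @param k_range candidate numbers of clusters, default `2:6`.
#' @param index_set character subset of
#'   `c("ch","silhouette","db","dunn","gap","hartigan","kl","ballhall")`;
#'   at least 3 required.
#' @param seed integer seed.
#' @param B_gap number of uniform reference datasets for the gap statistic.
#' @param max_index_windows subsample cap for distance-based indices.
#' @return list with `k_selected`, `index_votes` (named integer vector),
#'   `dispersion` (1 - modal vote share; 0 = unanimous), and `failures`.
#' @export
select_k <- function(windows, k_range = 2:6,
                     index_set = c("ch", "silhouette", "db", "dunn", "gap",
                                   "hartigan", "kl", "ballhall"),
                     seed = 1L, B_gap = 10L, max_index_windows = 1500L) {
  X <- as.matrix(windows)
  stopifnot(length(index_set) >= 3L, min(k_range) >= 2L,
            max(k_range) + 1L < nrow(X))
  res <- tn_index_votes(X, sort(unique(as.integer(k_range))), seed = seed,
                        B_gap = B_gap,
                        max_index_windows = max_index_windows,
                        index_set = index_set)
  votes <- res$votes[!is.na(res$votes)]
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k_sel <- min(winners)   # tie toward smaller k
  list(k_selected = k_sel, index_votes = res$votes,
       dispersion = 1 - max(tab) / length(votes), failures = res$failures)
}

#' Dwell-time statistics from a window state-label sequence
#'
#' Run-length encodes one subject's window labels and reports, per visited
#' state, the number of runs and the mean run length in windows and in
#' seconds (`windows * step * TR`). The subject's mean dwell time is the
#' unweighted mean over the states the subject visits.
#'
#' @param labels integer/character vector of per-window state labels.
#' @param TR repetition time in seconds.
#' @param step window step in timepoints.
#' @return object of class `tn_dwell_stats`: list with `per_state` (data
#'   frame: state, n_runs, mean_run_windows, mean_run_s), `mean_dwell_windows`,
#'   `mean_dwell_s`, `n_windows`.
#' @examples
#' dwell_times(c(1, 1, 1, 2, 2, 1, 1), TR = 2.3)
#' @export
dwell_times <- function(labels, TR = 2.3, step = 1L) {
  stopifnot(length(labels) >= 1L, TR > 0, step >= 1L)
  r <- rle(as.vector(labels))
  states <- sort(unique(r$values))
  per_state <- data.frame(
    state = states,
    n_runs = vapply(states, function(s) sum(r$values == s), integer(1)),
    mean_run_windows = vapply(states, function(s)
      mean(r$lengths[r$values == s]), numeric(1)))
  per_state$mean_run_s <- per_state$mean_run_windows * step * TR
  mean_dwell_windows <- mean(per_state$mean_run_windows)
  structure(list(per_state = per_state,
                 mean_dwell_windows = mean_dwell_windows,
                 mean_dwell_s = mean_dwell_windows * step * TR,
                 n_windows = length(labels)),
            class = "tn_dwell_stats")
}

#' Group-level state partition from per-subject windows
#'
#' Pools the per-window Fisher-z vectors of all subjects in one group,
#' standardises each feature (group-wise z-scoring), selects `k` by
#' validity-index majority vote when not fixed, runs [consensus_kmeans()],
#' and splits the labels back into per-subject sequences.
#'
#' @param subject_windows named list of `tn_windows` objects (one per
#'   subject of a single group).
#' @param k fixed number of states, or `NULL` to choose via [select_k()].
#' @param k_range candidate `k` values when `k` is `NULL`.
#' @param n_resamples,subsample_frac,max_windows passed to
#'   [consensus_kmeans()].
#' @param seed integer seed (used for both selection and clustering).
#' @param group_name label stored on the result.
#' @return object of class `tn_group_partition`: `group_name`, `k_selected`,
#'   `index_votes`, `centroids` (Fisher-z space, unstandardised), `labels`
#'   (named list of per-subject label sequences), `partition` (the
#'   `tn_state_partition`), `scaling` (feature means/sds used).
#' @export
group_state_partition <- function(subject_windows, k = NULL, k_range = 2:6,
                                  n_resamples = 100L, subsample_frac = 0.8,
                                  max_windows = 2000L, seed = 1L,
                                  group_name = NA_character_) {
  stopifnot(length(subject_windows) >= 1L,
            all(vapply(subject_windows, inherits, logical(1), "tn_windows")))
  z_list <- lapply(subject_windows, `[[`, "z6")
  n_per <- vapply(z_list, nrow, integer(1))
  Z <- do.call(rbind, z_list)
  mu <- colMeans(Z)
  sd_ <- apply(Z, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  Zs <- sweep(sweep(Z, 2L, mu), 2L, sd_, "/")
  votes <- NULL
  if (is.null(k)) {
    sel <- select_k(Zs, k_range = k_range, seed = seed)
    k <- sel$k_selected
    votes <- sel$index_votes
  }
  part <- consensus_kmeans(Zs, k, n_resamples = n_resamples,
                           subsample_frac = subsample_frac,
                           max_windows = max_windows, seed = seed)
  ## centroids back in raw Fisher-z units
  cent <- sweep(sweep(part$centroids, 2L, sd_, "*"), 2L, mu, "+")
  colnames(cent) <- colnames(Z)
  ends <- cumsum(n_per)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  labels <- Map(function(s, e) part$labels[s:e], starts, ends)
  names(labels) <- names(subject_windows)
  structure(list(group_name = group_name, k_selected = k,
                 index_votes = votes, centroids = cent, labels = labels,
                 partition = part, scaling = list(mean = mu, sd = sd_)),
            class = "tn_group_partition")
}
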