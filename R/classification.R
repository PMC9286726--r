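#' CART hyperparameters
#'
#' Defaults follow common practice for classification trees on small
#' samples: a node is split only if it holds at least
#' `min(20, ceiling(n/3))` cases, children must keep at least
#' `min(7, max(1, floor(n/10)))` cases, and a split must improve relative
#' Gini impurity by at least `cp` of the root impurity. `NULL` values are
#' resolved at fit time from the sample size.
#'
#' @param minsplit minimum node size to attempt a split.
#' @param minbucket minimum child (leaf) size.
#' @param cp complexity parameter: minimum relative impurity improvement.
#' @param maxdepth maximum tree depth.
#' @return list of class `tn_cart_control`.
#' @export
cart_control <- function(minsplit = NULL, minbucket = NULL, cp = 0.01,
                         maxdepth = 10L) {
  stopifnot(cp >= 0, maxdepth >= 1L)
  structure(list(minsplit = minsplit, minbucket = minbucket, cp = cp,
                 maxdepth = as.integer(maxdepth)),
            class = "tn_cart_control")
}

tn_gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

## Majority class with ties broken toward the alphabetically first label.
tn_majority <- function(y, levels_) {
  counts <- table(factor(y, levels = levels_))
  names(counts)[which.max(counts)]   # which.max keeps the first (sorted) max
}

tn_cart_grow <- function(x, y, levels_, ctl, depth, n_root, gini_root) {
  n <- length(y)
  node_counts <- table(factor(y, levels = levels_))
  node_gini <- tn_gini(node_counts)
  leaf <- list(type = "leaf", class = tn_majority(y, levels_), n = n,
               counts = as.vector(node_counts))
  if (n < ctl$minsplit || depth >= ctl$maxdepth || node_gini == 0) {
    return(leaf)
  }
  best <- NULL
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    uv <- sort(unique(v))
    if (length(uv) < 2L) next
    cuts <- (uv[-1] + uv[-length(uv)]) / 2
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left)
      nr <- n - nl
      if (nl < ctl$minbucket || nr < ctl$minbucket) next
      g <- (nl * tn_gini(table(factor(y[left], levels = levels_))) +
              nr * tn_gini(table(factor(y[!left], levels = levels_)))) / n
      gain <- node_gini - g
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(var = j, cut = cut, gain = gain)
      }
    }
  }
  ## rpart-style stopping: improvement relative to the root impurity
  if (is.null(best) ||
      (n / n_root) * best$gain < ctl$cp * gini_root) {
    return(leaf)
  }
  left <- x[, best$var] <= best$cut
  list(type = "split", var = best$var, cut = best$cut, n = n,
       left = tn_cart_grow(x[left, , drop = FALSE], y[left], levels_, ctl,
                           depth + 1L, n_root, gini_root),
       right = tn_cart_grow(x[!left, , drop = FALSE], y[!left], levels_, ctl,
                            depth + 1L, n_root, gini_root))
}

#' Fit a classification tree (CART)
#'
#' Binary axis-aligned splits chosen to minimise Gini impurity, with
#' min-node / min-leaf size control and complexity-parameter stopping
#' (a split must improve root-relative impurity by at least `cp`).
#' Deterministic given the data; leaf class ties break toward the
#' alphabetically first label.
#'
#' @param x numeric matrix or data frame of features (n >= 6).
#' @param y class labels (2 or more classes present).
#' @param control a [cart_control()].
#' @return object of class `tn_cart`.
#' @export
cart_fit <- function(x, y, control = cart_control()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  # analysis-level calls use n >= 6; LOOCV folds may hold one row fewer
  stopifnot(nrow(x) == length(y), nrow(x) >= 5L)
  levels_ <- sort(unique(y))
  if (length(levels_) < 2L) stop("single-class input: nothing to classify")
  n <- nrow(x)
  ctl <- control
  if (is.null(ctl$minsplit)) ctl$minsplit <- min(20L, ceiling(n / 3))
  if (is.null(ctl$minbucket)) ctl$minbucket <- min(7L, max(1L, floor(n / 10)))
  root_gini <- tn_gini(table(factor(y, levels = levels_)))
  tree <- tn_cart_grow(x, y, levels_, ctl, depth = 0L, n_root = n,
                       gini_root = root_gini)
  structure(list(tree = tree, levels = levels_, control = ctl,
                 features = colnames(x)),
            class = "tn_cart")
}

#' @param object a `tn_cart` fit.
#' @param newdata numeric matrix or data frame of features.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @rdname cart_fit
#' @export
predict.tn_cart <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  apply(newdata, 1L, function(row) {
    node <- object$tree
    while (node$type == "split") {
      node <- if (row[node$var] <= node$cut) node$left else node$right
    }
    node$class
  })
}

#' One-sided no-information-rate test
#'
#' Tests whether an observed classification accuracy beats the
#' no-information rate (the largest class proportion): the exact binomial
#' tail `P(X >= round(accuracy * n))` with `X ~ Binomial(n, nir)`.
#'
#' @param accuracy observed accuracy in `[0, 1]`.
#' @param n number of classified cases.
#' @param nir no-information rate (largest class fraction).
#' @return one-sided p value.
#' @export
nir_test <- function(accuracy, n, nir) {
  stopifnot(accuracy >= 0, accuracy <= 1, n >= 1, nir >= 0, nir <= 1)
  k <- round(accuracy * n)
  stats::pbinom(k - 1, n, nir, lower.tail = FALSE)
}

#' Leave-one-out cross-validated CART accuracy
#'
#' Fits one tree per held-out case (n fits), predicts each held-out case,
#' and tests the resulting accuracy against the no-information rate with
#' [nir_test()].
#'
#' @param x numeric matrix/data frame of features (e.g. `nii_mean`,
#'   `nii_sd`).
#' @param y class labels.
#' @param control a [cart_control()] applied to every fold.
#' @param pair label naming the contrast.
#' @return object of class `tn_classification`: `pair`, `accuracy`, `nir`,
#'   `p_vs_nir`, `predictions`, `truth`, `n`.
#' @export
loocv_accuracy <- function(x, y, control = cart_control(), pair = NA) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  stopifnot(n == length(y))
  preds <- character(n)
  for (i in seq_len(n)) {
    fit <- cart_fit(x[-i, , drop = FALSE], y[-i], control = control)
    preds[i] <- predict(fit, x[i, , drop = FALSE])
  }
  acc <- mean(preds == y)
  nir <- max(table(y)) / n
  structure(list(pair = pair, accuracy = acc, nir = nir,
                 p_vs_nir = nir_test(acc, n, nir),
                 predictions = preds, truth = y, n = n),
            class = "tn_classification")
}

#' @export
print.tn_classification <- function(x, ...) {
  cat(sprintf("%s: LOOCV accuracy %.1f%% (NIR %.1f%%, p vs NIR = %.4g)\n",
              if (is.na(x$pair)) "classification" else x$pair,
              100 * x$accuracy, 100 * x$nir, x$p_vs_nir))
  invisible(x)
}
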