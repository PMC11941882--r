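#' Names of the three feature rankers
#' @export
RANKERS <- c("relieff", "ftest", "boruta")

#' Ranker configuration
#'
#' @param k_neighbors neighbor count for RReliefF (default 10).
#' @param boruta_max_iter maximum Boruta iterations (default 100).
#' @param boruta_trees forest size per Boruta iteration (default 100).
#' @param alpha significance level used for the F-test's reported
#'   0.01/0.05 flags and Boruta's binomial decision (default 0.01 for Boruta
#'   decisions; flags always report both 0.01 and 0.05).
#' @param seed integer seed.
#' @return list of class `ranker_config`.
#' @export
ranker_config <- function(k_neighbors = 10L, boruta_max_iter = 100L,
                          boruta_trees = 100L, alpha = 0.01, seed = 1L) {
  if (k_neighbors < 1) jf_stop("jf_parameter_error", "k_neighbors must be >= 1")
  if (boruta_max_iter < 10)
    jf_stop("jf_parameter_error", "boruta_max_iter must be >= 10")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 boruta_max_iter = as.integer(boruta_max_iter),
                 boruta_trees = as.integer(boruta_trees),
                 alpha = alpha, seed = as.integer(seed)),
            class = "ranker_config")
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y))
    jf_stop("jf_validation_error", "missing values in features or target")
  if (nrow(X) != length(y))
    jf_stop("jf_parameter_error", "X rows and y length differ")
  if (stats::sd(y) == 0)
    jf_stop("jf_degenerate_error", "constant target: ranking undefined")
  X
}

#' RReliefF feature ranking for a continuous target
#'
#' Regression variant of ReliefF (the target is a concentration, not a
#' class): for every instance, its k nearest neighbors (Manhattan distance on
#' range-scaled features) contribute to the probabilities of differing in
#' prediction, in each attribute, and in both; the weight
#' `W[f] = P(dA|dC) - P(dA|not dC)` is estimated from those accumulators.
#' Deterministic: all instances are used, uniform neighbor weights.
#'
#' @param X samples x features matrix (column names required).
#' @param y continuous target.
#' @param config `ranker_config`.
#' @return character vector: feature names by descending weight, with the
#'   weights attached as attribute `weights`.
#' @export
rank_relieff <- function(X, y, config = ranker_config()) {
  X <- check_xy(X, y)
  n <- nrow(X); p <- ncol(X)
  k <- min(config$k_neighbors, n - 1L)
  rng <- apply(X, 2, function(v) diff(range(v)))
  Xs <- X
  for (j in seq_len(p))
    Xs[, j] <- if (rng[j] > 0) (X[, j] - min(X[, j])) / rng[j] else 0
  yr <- diff(range(y))
  yn <- (y - min(y)) / yr

  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  NdC <- 0
  NdA <- numeric(p); NdCdA <- numeric(p)
  m_total <- 0
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])  # indices into the reduced vector
    others <- seq_len(n)[-i]
    nb <- others[ord[seq_len(k)]]
    wq <- 1 / k
    for (j in nb) {
      dy <- abs(yn[i] - yn[j])
      dA <- abs(Xs[i, ] - Xs[j, ])
      NdC <- NdC + dy * wq
      NdA <- NdA + dA * wq
      NdCdA <- NdCdA + dy * dA * wq
      m_total <- m_total + wq
    }
  }
  W <- if (NdC > 0 && m_total - NdC > 0)
    NdCdA / NdC - (NdA - NdCdA) / (m_total - NdC)
  else numeric(p) * 0
  nm <- colnames(X)
  ord <- order(-W, nm)
  structure(nm[ord], weights = stats::setNames(W, nm)[ord])
}

#' Univariate F-test feature ranking
#'
#' Per feature, the F statistic of the simple linear regression of the target
#' on that feature, `F = (n-2) r^2 / (1 - r^2)`, with its two-sided p-value;
#' features are ordered by ascending p. Zero-variance features are undefined
#' and ranked last with p = 1.
#'
#' @inheritParams rank_relieff
#' @return feature names by ascending p-value, with attributes `p_values`,
#'   `sig_05`, `sig_01` (logical flags at the 0.05 / 0.01 levels).
#' @export
rank_ftest <- function(X, y, config = ranker_config()) {
  X <- check_xy(X, y)
  n <- nrow(X)
  nm <- colnames(X)
  r <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0) return(NA_real_)
    stats::cor(X[, j], y)
  }, numeric(1))
  Fstat <- (n - 2) * r^2 / pmax(1 - r^2, .Machine$double.eps)
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  p[is.na(p)] <- 1
  ord <- order(p, -abs(r), nm, na.last = TRUE)
  structure(nm[ord],
            p_values = stats::setNames(p, nm)[ord],
            sig_05 = stats::setNames(p <= 0.05, nm)[ord],
            sig_01 = stats::setNames(p <= 0.01, nm)[ord])
}

#' Boruta feature ranking
#'
#' Each feature is shadowed by a permuted copy; a random-forest regressor is
#' fit on the augmented matrix and a feature scores a "hit" when its impurity
#' importance exceeds the best shadow importance. Features are confirmed /
#' rejected by a one-sided binomial test on the hit count; the returned
#' ordering is confirmed > tentative > rejected, ties broken by mean
#' importance over the history, then alphabetically.
#'
#' @inheritParams rank_relieff
#' @return feature names (full permutation) with attributes `decision`
#'   (factor confirmed/tentative/rejected) and `mean_importance`.
#' @export
rank_boruta <- function(X, y, config = ranker_config()) {
  X <- check_xy(X, y)
  n <- nrow(X); p <- ncol(X)
  if (n < 5)
    jf_stop("jf_degenerate_error", "too few samples for Boruta")
  nm <- colnames(X)
  hits <- integer(p); iters <- 0L
  imp_hist <- matrix(NA_real_, nrow = 0, ncol = p)
  decision <- rep("tentative", p)
  with_seed(config$seed, {
    for (it in seq_len(config$boruta_max_iter)) {
      und <- decision == "tentative"
      if (!any(und)) break
      shadow <- apply(X, 2, sample)
      Xa <- cbind(X, shadow)
      storage.mode(Xa) <- "double"
      imp <- cpp_rf_importance(Xa, as.numeric(y),
                               ntree = config$boruta_trees,
                               mtry = max(1L, floor(ncol(Xa) / 3)),
                               min_split = 5L, max_depth = 25L,
                               seed = derive_seed(config$seed, it))
      real_imp <- imp[seq_len(p)]
      sh_max <- max(imp[(p + 1):(2 * p)])
      hits <- hits + as.integer(und & real_imp > sh_max)
      imp_hist <- rbind(imp_hist, real_imp)
      iters <- iters + 1L
      if (iters >= 10L) {
        # Bonferroni over the feature panel, as in reference implementations
        thr <- config$alpha / p
        p_conf <- stats::pbinom(hits[und] - 1L, iters, 0.5, lower.tail = FALSE)
        p_rej <- stats::pbinom(hits[und], iters, 0.5)
        dec <- decision[und]
        dec[p_conf <= thr] <- "confirmed"
        dec[p_rej <= thr] <- "rejected"
        decision[und] <- dec
      }
    }
  })
  mean_imp <- colMeans(imp_hist)
  tier <- match(decision, c("confirmed", "tentative", "rejected"))
  ord <- order(tier, -mean_imp, nm)
  structure(nm[ord],
            decision = factor(decision, c("confirmed", "tentative", "rejected"))[ord],
            mean_importance = stats::setNames(mean_imp, nm)[ord])
}

#' Run one ranker by name
#'
#' RReliefF sees z-scored features (it is distance-based); the F-test is
#' scale-invariant and Boruta's trees consume raw values.
#'
#' @param method one of [RANKERS].
#' @inheritParams rank_relieff
#' @return feature ordering (character vector).
#' @export
rank_features <- function(method, X, y, config = ranker_config()) {
  zscore_cols <- function(M) {
    M <- as.matrix(M)
    apply(M, 2, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
  }
  switch(method,
    relieff = rank_relieff(zscore_cols(X), y, config),
    ftest = rank_ftest(X, y, config),
    boruta = rank_boruta(X, y, config),
    jf_stop("jf_parameter_error", "unknown ranker '%s'", method))
}
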