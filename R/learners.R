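#' Learner and evaluation configuration
#'
#' Hyperparameters for the three tree-ensemble regressors and the repeated
#' train/test split protocol. The study never prints hyperparameters, so the
#' defaults are the field-standard ones; all are exposed so tests and batch
#' runs can scale compute down without touching the protocol.
#'
#' @param rf_trees random-forest size (default 500).
#' @param rf_min_split minimum node size to attempt a split (default 5).
#' @param xgb_rounds boosting rounds for the gradient-boosting learner
#'   (default 300).
#' @param xgb_depth tree depth (default 3).
#' @param xgb_eta learning rate (default 0.1).
#' @param xgb_subsample row subsample fraction per round (default 1).
#' @param ada_estimators AdaBoost.R2 estimator count (default 200).
#' @param ada_depth base-tree depth (default 3).
#' @param n_splits repeated random splits to average metrics over (default 20).
#' @param test_frac held-out fraction per split, stratified by jar
#'   (default 0.25).
#' @param split_by_cell if TRUE, hold out whole (jar, month) replicate cells
#'   instead of individual samples (default FALSE, the study's sample-level
#'   protocol). Cell-grouped splits avoid replicate leakage and are the
#'   conservative choice for noiseless or low-noise data.
#' @return list of class `learner_config`.
#' @export
learner_config <- function(rf_trees = 500L, rf_min_split = 5L,
                           xgb_rounds = 300L, xgb_depth = 3L, xgb_eta = 0.1,
                           xgb_subsample = 1.0,
                           ada_estimators = 200L, ada_depth = 3L,
                           n_splits = 20L, test_frac = 0.25,
                           split_by_cell = FALSE) {
  structure(list(rf_trees = as.integer(rf_trees),
                 rf_min_split = as.integer(rf_min_split),
                 xgb_rounds = as.integer(xgb_rounds),
                 xgb_depth = as.integer(xgb_depth),
                 xgb_eta = xgb_eta, xgb_subsample = xgb_subsample,
                 ada_estimators = as.integer(ada_estimators),
                 ada_depth = as.integer(ada_depth),
                 n_splits = as.integer(n_splits), test_frac = test_frac,
                 split_by_cell = isTRUE(split_by_cell)),
            class = "learner_config")
}

#' Names of the three regressors
#' @export
LEARNERS <- c("rf", "xgboost", "adaboost")

#' Fit one learner and predict held-out samples
#'
#' Tree learners consume raw (unscaled) features; they are scale-invariant.
#'
#' @param learner one of [LEARNERS], or `"mean"` (train-mean stub, used to
#'   exercise the Rp2 <= 0 contract).
#' @param X_train,y_train training data.
#' @param X_test matrix of samples to predict.
#' @param config `learner_config`.
#' @param seed integer seed for the learner's internal RNG.
#' @return numeric predictions, one per test row.
#' @export
fit_predict <- function(learner, X_train, y_train, X_test,
                        config = learner_config(), seed = 1L) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  storage.mode(X_train) <- "double"; storage.mode(X_test) <- "double"
  p <- ncol(X_train)
  seed <- as.integer(seed %% 2147483647L)
  switch(learner,
    rf = cpp_rf(X_train, as.numeric(y_train), X_test,
                ntree = config$rf_trees,
                mtry = max(1L, floor(p / 3)),
                min_split = config$rf_min_split,
                max_depth = 25L, seed = seed)$pred,
    xgboost = cpp_gbm(X_train, as.numeric(y_train), X_test,
                      nrounds = config$xgb_rounds,
                      max_depth = config$xgb_depth,
                      learning_rate = config$xgb_eta,
                      subsample = config$xgb_subsample,
                      min_split = 2L, seed = seed),
    adaboost = cpp_adaboost(X_train, as.numeric(y_train), X_test,
                            n_estimators = config$ada_estimators,
                            max_depth = config$ada_depth,
                            min_split = 2L, seed = seed),
    mean = rep(mean(y_train), nrow(X_test)),
    jf_stop("jf_parameter_error", "unknown learner '%s'", learner)
  )
}

#' Repeated jar-stratified, cell-grouped train/test splits
#'
#' For each repetition, holds out about `test_frac` of the (jar, month)
#' cells within every jar, keeping all replicates of a cell together.
#' Grouping by cell matters: replicates of one cell are near-identical (and
#' exactly identical at zero noise), so splitting them across train and test
#' would leak the test samples into training and reward memorisation instead
#' of generalisation. With ~54 aligned samples a single split is too noisy,
#' so metrics are averaged over repetitions.
#'
#' @param jar jar id per sample.
#' @param month month per sample (defines the replicate cell together with
#'   `jar`); may be `NULL` to fall back to ungrouped within-jar sampling.
#' @param n_splits number of repetitions.
#' @param test_frac held-out fraction of cells within each jar.
#' @param seed integer seed.
#' @return list of lists with integer `train` / `test` index vectors.
#' @export
make_splits <- function(jar, month, n_splits, test_frac, seed) {
  n <- length(jar)
  cell <- if (is.null(month)) seq_len(n) else paste(jar, month)
  with_seed(seed, lapply(seq_len(n_splits), function(s) {
    test <- unlist(lapply(split(seq_len(n), jar), function(ix) {
      cells <- unique(cell[ix])
      k <- max(1L, round(test_frac * length(cells)))
      if (k >= length(cells)) k <- length(cells) - 1L
      if (k < 1L) return(integer(0))
      held <- sample(cells, k)
      ix[cell[ix] %in% held]
    }), use.names = FALSE)
    list(train = setdiff(seq_len(n), test), test = sort(test))
  }))
}

#' Evaluate one (feature subset, learner) pair
#'
#' Trains on each split's training part, predicts the held-out part, and
#' averages test-set R-squared and RMSEP over the splits; RPD is derived from
#' the averaged R-squared (per-split RPD is infinite whenever a split is
#' predicted exactly).
#'
#' @param X samples x features matrix (already restricted to the subset).
#' @param y response vector (mg/L).
#' @param learner one of [LEARNERS].
#' @param splits list from [make_splits()].
#' @param config `learner_config`.
#' @param seed integer seed for learner fits.
#' @return list of class `eval_metrics`: `rp2`, `rmsep`, `rpd`, `n_test`.
#' @export
fit_predict_eval <- function(X, y, learner, splits,
                             config = learner_config(), seed = 1L) {
  X <- as.matrix(X)
  if (length(splits) == 0)
    jf_stop("jf_parameter_error", "no splits supplied")
  r2s <- numeric(length(splits)); rms <- numeric(length(splits))
  for (s in seq_along(splits)) {
    tr <- splits[[s]]$train; te <- splits[[s]]$test
    if (length(te) < 3)
      jf_stop("jf_evaluation_error", "test set smaller than 3 samples")
    pred <- fit_predict(learner, X[tr, , drop = FALSE], y[tr],
                        X[te, , drop = FALSE], config,
                        seed = derive_seed(seed, s))
    sst <- sum((y[te] - mean(y[te]))^2)
    r2s[s] <- if (sst > 0) 1 - sum((pred - y[te])^2) / sst else NA_real_
    rms[s] <- rmse(y[te], pred)
  }
  rp2 <- mean(r2s, na.rm = TRUE)
  structure(list(rp2 = rp2, rmsep = mean(rms), rpd = rpd_safe(rp2),
                 n_test = length(splits[[1]]$test)),
            class = "eval_metrics")
}
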