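#' Nested forward subsets from a feature ordering
#'
#' Sequential forward construction: subset i holds the top-i features of the
#' ranking, so 9 ion features yield 9 nested subsets and the last subset is
#' the full feature set.
#'
#' @param ordering character permutation of feature names.
#' @return list of class `ranked_subsets`: `ordering` and `subsets` (list of
#'   character vectors).
#' @export
build_nested_subsets <- function(ordering) {
  ordering <- as.character(ordering)
  if (anyDuplicated(ordering))
    jf_stop("jf_validation_error", "ordering contains duplicate feature names")
  structure(list(ordering = ordering,
                 subsets = lapply(seq_along(ordering),
                                  function(i) ordering[seq_len(i)])),
            class = "ranked_subsets")
}

#' Choose the refined subset from per-subset metrics
#'
#' The refined subset is the one with the highest test-set R-squared; the
#' study treats "highest Rp2" and "lowest RMSEP" as co-optimal, so when the
#' two argmaxima disagree R-squared wins and the conflict is recorded in the
#' `conflict` attribute. Exact R-squared ties break toward the smaller
#' subset.
#'
#' @param metrics_by_subset list of `eval_metrics`, indexed by subset size.
#' @return integer subset index with attribute `conflict` (logical).
#' @export
select_refined_subset <- function(metrics_by_subset) {
  if (length(metrics_by_subset) == 0)
    jf_stop("jf_parameter_error", "no subset metrics supplied")
  rp2 <- vapply(metrics_by_subset, function(m) m$rp2, numeric(1))
  rms <- vapply(metrics_by_subset, function(m) m$rmsep, numeric(1))
  best_r2 <- which.max(rp2)            # first max: ties go to smaller subset
  best_rms <- which.min(rms)
  structure(as.integer(best_r2), conflict = best_r2 != best_rms)
}

#' Common features across the three models' refined subsets
#'
#' Strict intersection of the three sets; if it is empty (never reported in
#' the study, but the function must be total) the fallback keeps features
#' present in at least 2 of the 3 sets, with a warning.
#'
#' @param refined_subsets list of character vectors (3 in the standard
#'   pipeline; fewer when the learner set is restricted).
#' @return character feature set with attribute `fallback` (logical).
#' @export
common_features <- function(refined_subsets) {
  stopifnot(length(refined_subsets) >= 1)
  inter <- Reduce(intersect, refined_subsets)
  if (length(inter) > 0) return(structure(inter, fallback = FALSE))
  counts <- table(unlist(lapply(refined_subsets, unique)))
  need <- max(2L, ceiling(length(refined_subsets) / 2))
  fb <- names(counts)[counts >= need]
  warning("empty strict intersection of refined subsets; falling back to majority features")
  structure(fb, fallback = TRUE)
}

#' Majority vote across the three rankers' key-feature sets
#'
#' Final key features are those appearing in at least 2 of the 3 per-ranker
#' key-feature sets.
#'
#' @param key_sets list of character vectors (3 in the standard pipeline; a
#'   single set passes through unchanged so a restricted one-ranker run
#'   degenerates to plain forward selection).
#' @param feature_order optional vector fixing the output order (defaults to
#'   [ION_NAMES] followed by any extras).
#' @return character feature set.
#' @export
majority_vote <- function(key_sets, feature_order = ION_NAMES) {
  stopifnot(length(key_sets) >= 1)
  counts <- table(unlist(lapply(key_sets, unique)))
  keys <- names(counts)[counts >= min(2L, length(key_sets))]
  ord <- c(feature_order, setdiff(keys, feature_order))
  keys[order(match(keys, ord))]
}

#' Combine key features over a group's representatives
#'
#' Multi-representative groups report one pooled key set: the union of the
#' representatives' final keys (matching how the study lists a single key
#' set for groups with several representatives).
#'
#' @param per_representative_keys list (length >= 1) of character vectors.
#' @return character feature set in [ION_NAMES] order.
#' @export
group_key_features <- function(per_representative_keys) {
  if (length(per_representative_keys) == 0)
    jf_stop("jf_parameter_error", "no representative results supplied")
  keys <- unique(unlist(per_representative_keys))
  keys[order(match(keys, c(ION_NAMES, setdiff(keys, ION_NAMES))))]
}

#' Consensus key-feature selection for one target substance
#'
#' The core procedure: rank the 9 ion features with each of the three
#' rankers, build nested forward subsets, evaluate every subset with the
#' three tree-ensemble regressors over repeated stratified splits, take each
#' model's refined subset, intersect within ranker, and majority-vote across
#' rankers.
#'
#' @param X samples x 9 ion matrix.
#' @param y target flavor concentrations (mg/L).
#' @param jar jar id per sample (split stratification).
#' @param month month per sample (replicate-cell grouping for the splits).
#' @param rankers ranker names (default all of [RANKERS]).
#' @param learners learner names (default all of [LEARNERS]).
#' @param lconfig `learner_config`.
#' @param rconfig `ranker_config`.
#' @param seed integer seed.
#' @return list of class `key_feature_result`: `orderings`, `per_ranker`
#'   (refined subset index/features and per-model metrics), `per_ranker_common`,
#'   `final_keys`.
#' @export
select_key_features <- function(X, y, jar, month = NULL,
                                rankers = RANKERS, learners = LEARNERS,
                                lconfig = learner_config(),
                                rconfig = ranker_config(),
                                seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 12)
    jf_stop("jf_insufficient_data_error",
            "need >= 12 aligned samples, got %d", nrow(X))
  splits <- make_splits(jar, if (lconfig$split_by_cell) month else NULL,
                        lconfig$n_splits, lconfig$test_frac,
                        seed = derive_seed(seed, 977L))
  orderings <- list(); per_ranker <- list(); per_common <- list()
  for (rk in rankers) {
    rcfg <- rconfig; rcfg$seed <- derive_seed(seed, match(rk, RANKERS))
    ordering <- rank_features(rk, X, y, rcfg)
    ns <- build_nested_subsets(as.character(ordering))
    eval_grid <- list(); refined <- list()
    for (ln in learners) {
      metrics <- lapply(ns$subsets, function(ss)
        fit_predict_eval(X[, ss, drop = FALSE], y, ln, splits, lconfig,
                         seed = derive_seed(seed, 100L + match(ln, LEARNERS))))
      idx <- select_refined_subset(metrics)
      eval_grid[[ln]] <- metrics
      refined[[ln]] <- list(index = as.integer(idx),
                            features = ns$subsets[[idx]],
                            conflict = attr(idx, "conflict"),
                            metrics = metrics[[idx]])
    }
    common <- common_features(lapply(refined, `[[`, "features"))
    orderings[[rk]] <- as.character(ordering)
    per_ranker[[rk]] <- list(refined = refined, eval_grid = eval_grid)
    per_common[[rk]] <- as.character(common)
  }
  final <- majority_vote(per_common)
  structure(list(orderings = orderings, per_ranker = per_ranker,
                 per_ranker_common = per_common, final_keys = final),
            class = "key_feature_result")
}

#' Run the consensus pipeline over all flavor groups
#'
#' For every group representative, runs [select_key_features()] on the
#' aligned ion/flavor samples, pools multi-representative groups by union,
#' and re-evaluates each group's final key set against the all-9-feature
#' baseline with all three learners.
#'
#' @param dataset `study_dataset`.
#' @param grouping `flavor_grouping` from [group_flavors()].
#' @param rankers,learners,lconfig,rconfig,seed as in [select_key_features()].
#' @return list of class `consensus_result`: per group, `representatives`
#'   (per-representative `key_feature_result`s), `final_keys`, and
#'   `evaluation` (per representative x learner, metrics for the final key
#'   set and the 9-feature baseline).
#' @export
run_consensus <- function(dataset, grouping,
                          rankers = RANKERS, learners = LEARNERS,
                          lconfig = learner_config(),
                          rconfig = ranker_config(),
                          seed = 1L) {
  groups <- names(grouping$representatives)
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    reps <- grouping$representatives[[g]]
    rep_results <- list()
    for (ri in seq_along(reps)) {
      al <- aligned_samples(dataset, reps[ri])
      rep_results[[reps[ri]]] <- select_key_features(
        al$X, al$y, al$jar, al$month, rankers, learners, lconfig, rconfig,
        seed = derive_seed(seed, 1000L * gi + ri))
    }
    final <- group_key_features(lapply(rep_results, `[[`, "final_keys"))
    evaluation <- list()
    for (ri in seq_along(reps)) {
      al <- aligned_samples(dataset, reps[ri])
      splits <- make_splits(al$jar, if (lconfig$split_by_cell) al$month else NULL,
                            lconfig$n_splits, lconfig$test_frac,
                            seed = derive_seed(seed, 5000L + 1000L * gi + ri))
      evaluation[[reps[ri]]] <- lapply(stats::setNames(learners, learners),
        function(ln) list(
          keys = fit_predict_eval(al$X[, final, drop = FALSE], al$y, ln,
                                  splits, lconfig,
                                  seed = derive_seed(seed, 7000L + gi)),
          baseline = fit_predict_eval(al$X, al$y, ln, splits, lconfig,
                                      seed = derive_seed(seed, 8000L + gi))))
    }
    out[[g]] <- list(representatives = rep_results, final_keys = final,
                     evaluation = evaluation)
  }
  structure(out, class = "consensus_result")
}

#' Flatten a consensus result into the comparison-table layout
#'
#' One row per (group, representative, learner, feature set), mirroring the
#' published comparison of final-key models against the all-9-ion baseline.
#'
#' @param result `consensus_result`.
#' @return data.frame with columns group, representative, learner,
#'   n_features, rp2, rmsep, rpd, final_keys, low_rp2 (flag, never
#'   suppressed: TRUE when rp2 < 0.85).
#' @export
consensus_table <- function(result) {
  rows <- list()
  for (g in names(result)) {
    res <- result[[g]]
    for (rep_name in names(res$evaluation)) {
      for (ln in names(res$evaluation[[rep_name]])) {
        ev <- res$evaluation[[rep_name]][[ln]]
        for (kind in c("keys", "baseline")) {
          m <- ev[[kind]]
          rows[[length(rows) + 1]] <- data.frame(
            group = g, representative = rep_name, learner = ln,
            n_features = if (kind == "keys") length(res$final_keys) else
              length(ION_NAMES),
            rp2 = m$rp2, rmsep = m$rmsep, rpd = m$rpd,
            final_keys = paste(res$final_keys, collapse = " "),
            low_rp2 = is.na(m$rp2) || m$rp2 < 0.85)
        }
      }
    }
  }
  do.call(rbind, rows)
}
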