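#' Planted-key recovery harness
#'
#' Runs the consensus selection stage on a synthetic study and compares the
#' recovered final key features of every group against the planted ground
#' truth. Groups are taken from the generator's truth assignment (clustering
#' recovery is assessed separately), with one representative per group: all
#' members of a synthetic group share the same latent, so any member is an
#' equivalent target.
#'
#' @param config `synth_config` describing the study to generate.
#' @param lconfig `learner_config` (scaled-down settings only reduce
#'   compute, not the stated design).
#' @param rconfig `ranker_config`.
#' @param seed integer seed for the selection stage.
#' @return data.frame: group, planted, recovered (space-separated),
#'   jaccard, exact (logical).
#' @export
evaluate_recovery <- function(config,
                              lconfig = learner_config(),
                              rconfig = ranker_config(),
                              seed = 1L) {
  study <- generate_study(config)
  tr <- study$truth
  rows <- list()
  for (g in names(tr$planted_keys)) {
    members <- names(tr$group_assignment)[tr$group_assignment == g]
    al <- aligned_samples(study$dataset, members[1])
    res <- select_key_features(al$X, al$y, al$jar, al$month,
                               lconfig = lconfig, rconfig = rconfig,
                               seed = derive_seed(seed, match(g, names(tr$planted_keys))))
    rows[[g]] <- data.frame(
      group = g,
      planted = paste(tr$planted_keys[[g]], collapse = " "),
      recovered = paste(res$final_keys, collapse = " "),
      jaccard = jaccard(res$final_keys, tr$planted_keys[[g]]),
      exact = setequal(res$final_keys, tr$planted_keys[[g]]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean planted-key Jaccard over several seeds
#'
#' @param noise_sd residual noise level of the generated studies.
#' @param seeds integer vector of generator seeds.
#' @param lconfig,rconfig compute settings passed to [evaluate_recovery()].
#' @return data.frame with one row per seed (`seed`, `mean_jaccard`,
#'   `n_exact`) plus attribute `mean` (grand mean Jaccard).
#' @export
recovery_over_seeds <- function(noise_sd, seeds,
                                lconfig = learner_config(),
                                rconfig = ranker_config()) {
  per_seed <- lapply(seeds, function(s) {
    rec <- evaluate_recovery(synth_config(noise_sd = noise_sd, seed = s),
                             lconfig, rconfig, seed = derive_seed(s, 101L))
    data.frame(seed = s, mean_jaccard = mean(rec$jaccard),
               n_exact = sum(rec$exact))
  })
  out <- do.call(rbind, per_seed)
  attr(out, "mean") <- mean(out$mean_jaccard)
  out
}

#' Clustering recovery over seeds
#'
#' Generates studies at the given noise level, clusters the flavor
#' trajectories with k = number of planted groups, and reports the adjusted
#' Rand index against the planted assignment.
#'
#' @param noise_sd residual noise level.
#' @param seeds integer vector of generator seeds.
#' @param n_init k-means restarts.
#' @return data.frame (`seed`, `ari`) with attribute `mean`.
#' @export
clustering_recovery <- function(noise_sd, seeds, n_init = 50L) {
  per_seed <- lapply(seeds, function(s) {
    study <- generate_study(synth_config(noise_sd = noise_sd, seed = s))
    g <- group_flavors(study$dataset$flavors, k = study$truth$group_sizes |>
                         length(), seed = derive_seed(s, 7L), n_init = n_init)
    tr <- study$truth$group_assignment
    data.frame(seed = s,
               ari = adjusted_rand_index(g$labels[names(tr)], tr))
  })
  out <- do.call(rbind, per_seed)
  attr(out, "mean") <- mean(out$ari)
  out
}
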