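#' Load a pipeline configuration
#'
#' YAML file (or an equivalent R list) with sections:
#' \preformatted{
#' seed: 1
#' out_dir: runs/demo
#' data:            # either synth: ... or paths to the three CSVs
#'   jars: path.csv
#'   ions: path.csv
#'   flavors: path.csv
#' synth:           # used when data: is absent
#'   noise_sd: 0.1
#'   effect_size: 1
#' grouping: {k: 10, n_init: 50}
#' selection: {n_splits: 20, rf_trees: 500, ...}
#' association: {p_threshold: 0.05}
#' }
#'
#' @param x path to a YAML file, or a list.
#' @return validated config list.
#' @export
load_pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir))
    jf_stop("jf_config_error", "config requires out_dir")
  if (is.null(cfg$data) && is.null(cfg$synth))
    jf_stop("jf_config_error", "config requires a data: or synth: section")
  if (!is.null(cfg$data)) {
    for (f in c("jars", "ions", "flavors")) {
      if (is.null(cfg$data[[f]]))
        jf_stop("jf_config_error", "data section missing '%s' path", f)
      if (!file.exists(cfg$data[[f]]))
        jf_stop("jf_config_error", "data path does not exist: %s", cfg$data[[f]])
    }
  }
  cfg
}

take <- function(lst, nm, default) if (is.null(lst[[nm]])) default else lst[[nm]]

#' Run the full pipeline: synth/load, group, select, associate
#'
#' Stages are pure functions of (inputs, config, seeds); the manifest records
#' package version, per-stage seeds, input file hashes and output paths so
#' deterministic stages can be rerun bit-identically. The global seed is
#' expanded into per-stage seeds with [derive_seed()] (offsets 1-4).
#'
#' @param config config list or YAML path (see [load_pipeline_config()]).
#' @return manifest list, invisibly written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stats::setNames(lapply(1:4, function(i) derive_seed(cfg$seed, i)),
                           c("synth", "group", "select", "associate"))
  manifest <- list(package = "jarflavor",
                   version = as.character(utils::packageVersion("jarflavor")),
                   seed = cfg$seed, stage_seeds = seeds,
                   stages = list())
  log_stage <- function(name, ...) {
    message(sprintf("[%s] %s", name, sprintf(...)))
  }

  # stage 1: data
  t0 <- Sys.time()
  if (!is.null(cfg$data)) {
    dataset <- assemble_dataset(read_jar_table(cfg$data$jars),
                                read_ion_table(cfg$data$ions),
                                read_flavor_table(cfg$data$flavors, "long"))
    truth <- NULL
    manifest$stages$data <- list(
      source = "files",
      hashes = lapply(cfg$data, function(p) unname(tools::md5sum(p))))
  } else {
    sc <- synth_config(
      n_jars = take(cfg$synth, "n_jars", 6L),
      n_replicates = take(cfg$synth, "n_replicates", 3L),
      n_flavors = take(cfg$synth, "n_flavors", 48L),
      n_groups = take(cfg$synth, "n_groups", 10L),
      effect_size = take(cfg$synth, "effect_size", 1),
      noise_sd = take(cfg$synth, "noise_sd", 0.1),
      jar_effect_sd = take(cfg$synth, "jar_effect_sd", 1),
      seed = seeds$synth)
    study <- generate_study(sc)
    dataset <- study$dataset; truth <- study$truth
    write_study(study, file.path(cfg$out_dir, "synth"))
    manifest$stages$data <- list(source = "synth",
                                 out = file.path(cfg$out_dir, "synth"))
  }
  log_stage("data", "%d jars, %d ion samples, %d substances (%.1fs)",
            nrow(dataset$jars), nrow(dataset$ions),
            length(flavor_substances(dataset$flavors)),
            as.numeric(Sys.time() - t0, units = "secs"))

  # stage 2: grouping
  t0 <- Sys.time()
  grouping <- group_flavors(dataset$flavors,
                            k = take(cfg$grouping, "k", 10L),
                            seed = seeds$group,
                            n_init = take(cfg$grouping, "n_init", 50L))
  gr_path <- file.path(cfg$out_dir, "grouping.csv")
  reps <- unlist(grouping$representatives, use.names = FALSE)
  utils::write.csv(data.frame(
    substance = names(grouping$labels),
    group = paste0("G", grouping$labels),
    is_representative = names(grouping$labels) %in% reps),
    gr_path, row.names = FALSE, quote = FALSE)
  manifest$stages$grouping <- list(k = grouping$k, out = gr_path)
  log_stage("group", "k=%d, %d representatives (%.1fs)", grouping$k,
            length(reps), as.numeric(Sys.time() - t0, units = "secs"))

  # stage 3: consensus selection
  t0 <- Sys.time()
  sel <- cfg$selection
  lcfg <- learner_config(
    rf_trees = take(sel, "rf_trees", 500L),
    xgb_rounds = take(sel, "xgb_rounds", 300L),
    xgb_depth = take(sel, "xgb_depth", 3L),
    xgb_eta = take(sel, "xgb_eta", 0.1),
    ada_estimators = take(sel, "ada_estimators", 200L),
    ada_depth = take(sel, "ada_depth", 3L),
    n_splits = take(sel, "n_splits", 20L),
    test_frac = take(sel, "test_frac", 0.25))
  rcfg <- ranker_config(
    k_neighbors = take(sel, "k_neighbors", 10L),
    boruta_max_iter = take(sel, "boruta_max_iter", 100L),
    boruta_trees = take(sel, "boruta_trees", 100L))
  consensus <- run_consensus(dataset, grouping,
                             rankers = take(sel, "rankers", RANKERS),
                             learners = take(sel, "learners", LEARNERS),
                             lconfig = lcfg, rconfig = rcfg,
                             seed = seeds$select)
  keys_path <- file.path(cfg$out_dir, "key_features.json")
  jsonlite::write_json(
    lapply(consensus, function(g) list(
      final_keys = g$final_keys,
      representatives = lapply(g$representatives, function(r) list(
        orderings = r$orderings, common = r$per_ranker_common,
        final_keys = r$final_keys)))),
    keys_path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  tbl_path <- file.path(cfg$out_dir, "evaluation.csv")
  utils::write.csv(consensus_table(consensus), tbl_path,
                   row.names = FALSE, quote = FALSE)
  manifest$stages$selection <- list(out_keys = keys_path, out_table = tbl_path)
  log_stage("select", "%d groups (%.1fs)", length(consensus),
            as.numeric(Sys.time() - t0, units = "secs"))

  # stage 4: association + network
  t0 <- Sys.time()
  p_thr <- take(cfg$association, "p_threshold", 0.05)
  jar_edges <- jar_ion_partial_edges(dataset)
  M <- standardize_trajectories(dataset$flavors)
  ion_cols <- dataset$ions[dataset$ions$month != 0, ]
  flav_edges <- list()
  for (g in names(consensus)) {
    keys <- consensus[[g]]$final_keys
    members <- names(grouping$labels)[
      paste0("G", grouping$labels) == g]
    if (length(keys) == 0) next
    FM <- vapply(members, function(s) {
      al <- aligned_samples(dataset, s)
      al$y
    }, numeric(sum(dataset$ions$month != 0)))
    flav_edges[[g]] <- correlation_edges(
      as.matrix(ion_cols[, keys, drop = FALSE]), FM,
      scheme = "standard", source_tier = "ion", target_tier = "flavor")
  }
  flav_edges <- do.call(rbind, flav_edges)
  edges_path <- file.path(cfg$out_dir, "edges.csv")
  utils::write.csv(rbind(jar_edges, flav_edges), edges_path,
                   row.names = FALSE, quote = FALSE)
  net <- build_network(jar_edges, flav_edges, p_threshold = p_thr)
  net_path <- file.path(cfg$out_dir, "network.graphml")
  write_network_graphml(net, net_path)
  manifest$stages$association <- list(out_edges = edges_path,
                                      out_network = net_path,
                                      p_threshold = p_thr)
  log_stage("associate", "%d edges kept at p<=%.2f (%.1fs)",
            igraph::ecount(net), p_thr,
            as.numeric(Sys.time() - t0, units = "secs"))

  man_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
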