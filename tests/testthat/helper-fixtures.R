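# Shared fixtures and scaled-down compute settings. Scaling down ensemble
# sizes / split counts reduces runtime only; the study design (jars,
# replicates, months, ions, flavors, groups) is never changed in tests.

fixture_path <- function(name) {
  system.file("extdata", name, package = "jarflavor", mustWork = TRUE)
}

test_lconfig <- function(...) {
  args <- utils::modifyList(
    list(rf_trees = 100L, xgb_rounds = 100L, ada_estimators = 60L,
         n_splits = 8L), list(...))
  do.call(learner_config, args)
}

test_rconfig <- function(...) {
  ranker_config(boruta_max_iter = 30L, boruta_trees = 60L, ...)
}

# default synthetic study used across tests (generation is fast)
make_study <- function(noise_sd = 0, seed = 3, ...) {
  generate_study(synth_config(noise_sd = noise_sd, seed = seed, ...))
}

# long-layout flavor CSV written from a flavor_table, for reader tests
write_long_flavor_csv <- function(flavors) {
  path <- tempfile(fileext = ".csv")
  write_flavor_table(flavors, path)
  path
}
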