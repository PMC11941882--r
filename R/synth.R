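#' Initial metal-ion concentrations of the base liquor (mg/L)
#'
#' Measured before storage; identical for every jar because all jars were
#' filled with the same base liquor.
#' @export
BASELINE_IONS <- c(Ca = 0.656, Na = 0.198, Mg = 0.094, Al = 0.192,
                   K = 0.0693, Fe = 0.135, Mn = 0.0182, Cu = 0.00285,
                   Zn = 0.0171)

#' Synthetic-study configuration
#'
#' The defaults ARE the study design: 6 jars x 3 replicates, flavor months
#' 0/4/8/12/16/20, ion months 0/12/16/20, 9 ions, 48 flavor substances in 10
#' groups. `noise_sd` is the residual standard deviation as a fraction of the
#' signal sd (applied to ion replicates and flavor residuals); the default
#' 0.1 is a modest replicate-level noise typical of targeted GC-MS/ICP-MS
#' panels.
#'
#' @param n_jars number of jars (>= 2; default 6).
#' @param n_replicates parallel replicates per jar (default 3).
#' @param months flavor observation months (default 0,4,8,12,16,20).
#' @param ion_names the 9 ion names (default [ION_NAMES]).
#' @param n_flavors number of flavor substances (default 48).
#' @param n_groups number of planted flavor groups (default 10).
#' @param planted_keys optional named list, group -> ion subset; `NULL` draws
#'   distinct subsets of size 2-4 per group from the seed.
#' @param effect_size standardized slope per planted ion (default 1).
#' @param noise_sd residual sd as fraction of signal sd (default 0.1).
#' @param jar_effect_sd sd of the ion-by-jar drift perturbation relative to
#'   the parameter-driven trend (default 1). This unmodelled jar
#'   heterogeneity makes the 9 ion trajectories linearly independent; set to
#'   0 to obtain drift that is a pure linear function of jar parameters.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_jars = 6L, n_replicates = 3L,
                         months = FLAVOR_MONTHS, ion_names = ION_NAMES,
                         n_flavors = 48L, n_groups = 10L,
                         planted_keys = NULL, effect_size = 1,
                         noise_sd = 0.1, jar_effect_sd = 1, seed = 1L) {
  if (n_jars < 2)
    jf_stop("jf_config_error", "need at least 2 jars for contrasts")
  if (n_groups > n_flavors)
    jf_stop("jf_config_error", "n_groups cannot exceed n_flavors")
  if (effect_size <= 0) jf_stop("jf_config_error", "effect_size must be > 0")
  if (noise_sd < 0) jf_stop("jf_config_error", "noise_sd must be >= 0")
  if (!is.null(planted_keys)) {
    ok <- all(vapply(planted_keys, function(s)
      length(s) > 0 && all(s %in% ion_names), logical(1)))
    if (!ok)
      jf_stop("jf_config_error",
              "planted_keys must be non-empty subsets of ion_names")
  }
  structure(list(n_jars = as.integer(n_jars),
                 n_replicates = as.integer(n_replicates),
                 months = as.integer(months), ion_names = ion_names,
                 n_flavors = as.integer(n_flavors),
                 n_groups = as.integer(n_groups),
                 planted_keys = planted_keys, effect_size = effect_size,
                 noise_sd = noise_sd, jar_effect_sd = jar_effect_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Draw jar parameters bracketing the studied formulations
#'
#' Uniform draws inside ranges bracketing the six studied jars:
#' Cu in `[0, 0.25]`, Fe in `[5.0, 6.1]`, Zn in `[0, 0.36]` (mg/L),
#' P-max in `[70, 155]`, P-min in `[2, 7]` (um).
#'
#' @param config `synth_config`.
#' @return `jar_table` with `config$n_jars` rows.
#' @export
generate_jars <- function(config) {
  n <- config$n_jars
  with_seed(derive_seed(config$seed, 11L), jar_table(data.frame(
    jar_id = seq_len(n),
    cu = stats::runif(n, 0, 0.25),
    fe = stats::runif(n, 5.0, 6.1),
    zn = stats::runif(n, 0, 0.36),
    p_max = stats::runif(n, 70, 155),
    p_min = stats::runif(n, 2, 7))))
}

# jar-parameter -> ion-drift sign pattern observed in the study:
# jar Fe and P-max depress Baijiu Fe and raise Al; jar Zn raises Mg and K;
# P-min raises Na and Ca. Rows = ions, cols = jar parameters.
ion_beta_matrix <- function(ion_names) {
  B <- matrix(0, length(ion_names), 5,
              dimnames = list(ion_names, c("cu", "fe", "zn", "p_max", "p_min")))
  B["Fe", "fe"] <- -0.5; B["Fe", "p_max"] <- -0.5
  B["Al", "fe"] <- 0.5;  B["Al", "p_max"] <- 0.5
  B["Mg", "zn"] <- 0.5;  B["K", "zn"] <- 0.5
  B["Na", "p_min"] <- 0.5; B["Ca", "p_min"] <- 0.5
  B
}

# deterministic per-(ion, jar) drift slopes: param-driven trend plus a seeded
# ion-by-jar perturbation (unmodelled jar heterogeneity). The perturbation is
# what makes the 9 trajectories linearly independent, hence planted ions
# identifiable even at noise_sd = 0.
ion_slopes <- function(jars, config) {
  Z <- scale(as.matrix(jars[c("cu", "fe", "zn", "p_max", "p_min")]))
  Z[is.nan(Z)] <- 0
  B <- ion_beta_matrix(config$ion_names)
  gamma <- with_seed(derive_seed(config$seed, 13L),
                     matrix(config$jar_effect_sd *
                              stats::rnorm(length(config$ion_names) * nrow(jars)),
                            length(config$ion_names), nrow(jars),
                            dimnames = list(config$ion_names, jars$jar_id)))
  U <- B %*% t(Z) + gamma                       # ions x jars, ~N(0,1) scale
  base <- BASELINE_IONS[config$ion_names]
  out <- sweep(U, 1, base / 20, "*")            # month-20 change ~ +-baseline
  dimnames(out) <- list(config$ion_names, jars$jar_id)
  out
}

# seeded per-(ion, jar, month) fluctuation of the deterministic trajectory,
# mimicking the reported "significant fluctuations" of ion concentrations
# between aging time points. Shared across replicates (so noise_sd = 0 still
# yields identical replicates) and zero at month 0; scaled by jar_effect_sd
# so a pure linear-in-parameters drift is available at jar_effect_sd = 0.
# Without this term the 18 (jar, month) cells give near-collinear ion
# trajectories and no method could identify planted subsets.
ion_fluct <- function(jars, config, months_all) {
  months_all <- sort(unique(months_all))
  arr <- with_seed(derive_seed(config$seed, 31L),
                   array(1.0 * config$jar_effect_sd *
                           stats::rnorm(length(config$ion_names) *
                                          nrow(jars) * length(months_all)),
                         dim = c(length(config$ion_names), nrow(jars),
                                 length(months_all)),
                         dimnames = list(config$ion_names, jars$jar_id,
                                         months_all)))
  arr[, , months_all == 0] <- 0
  arr
}

# noiseless ion concentration for every (ion, jar) at a given month
ion_mean_at <- function(slopes, config, month, fluct = NULL) {
  base <- BASELINE_IONS[config$ion_names]
  det <- base + slopes * month
  if (!is.null(fluct) && month > 0)
    det <- det + base * fluct[, , as.character(month)]
  pmax(det, 0)
}

#' Generate metal-ion records with jar-driven drift
#'
#' Each ion trajectory is baseline + month-proportional drift whose slope is
#' a linear function of the jar parameters (sign pattern above) plus an
#' ion-by-jar perturbation; replicate noise of sd `noise_sd` x signal-sd is
#' added at months 12/16/20 and values are clipped at 0. Month-0 records
#' equal the shared baseline exactly.
#'
#' @param jars `jar_table` from [generate_jars()].
#' @param config `synth_config`.
#' @return list: `ions` (`ion_table`), `slopes` (ion x jar drift matrix).
#' @export
generate_ions <- function(jars, config) {
  slopes <- ion_slopes(jars, config)
  fluct <- ion_fluct(jars, config, c(config$months, ION_MONTHS))
  months_obs <- intersect(ION_MONTHS, c(0L, config$months))
  grid <- expand.grid(jar_id = jars$jar_id,
                      replicate = seq_len(config$n_replicates),
                      month = months_obs)
  det <- matrix(NA_real_, nrow(grid), length(config$ion_names),
                dimnames = list(NULL, config$ion_names))
  for (i in seq_len(nrow(grid)))
    det[i, ] <- ion_mean_at(slopes, config, grid$month[i],
                            fluct)[, as.character(grid$jar_id[i])]
  sig_sd <- apply(det[grid$month > 0, , drop = FALSE], 2, stats::sd)
  vals <- with_seed(derive_seed(config$seed, 17L), {
    eps <- matrix(stats::rnorm(length(det)), nrow(det))
    noisy <- det + sweep(eps, 2, config$noise_sd * sig_sd, "*")
    noisy[grid$month == 0, ] <- det[grid$month == 0, ]  # baseline is exact
    pmax(noisy, 0)
  })
  df <- cbind(grid, as.data.frame(vals))
  list(ions = ion_table(df[order(df$jar_id, df$replicate, df$month), ]),
       slopes = slopes, fluct = fluct)
}

# sizes of the 10 groups: random composition constrained to exercise all
# three bands of the representative rule (<=5, 6-10, >10)
draw_group_sizes <- function(n_flavors, n_groups, seed) {
  with_seed(seed, {
    for (try in 1:1000) {
      cuts <- sort(sample(seq_len(n_flavors - 1), n_groups - 1))
      sizes <- diff(c(0, cuts, n_flavors))
      if (n_groups >= 3 && n_flavors >= 20) {
        if (any(sizes <= 5) && any(sizes > 5 & sizes <= 10) && any(sizes > 10))
          return(sizes)
      } else if (all(sizes >= 1)) return(sizes)
    }
    jf_stop("jf_config_error", "could not draw group sizes")
  })
}

draw_planted_keys <- function(config) {
  if (!is.null(config$planted_keys)) return(config$planted_keys)
  with_seed(derive_seed(config$seed, 19L), {
    keys <- list(); seen <- character(0)
    for (g in seq_len(config$n_groups)) {
      repeat {
        sz <- sample(2:3, 1)
        ss <- sort(sample(config$ion_names, sz))
        sig <- paste(ss, collapse = "|")
        if (!sig %in% seen) { seen <- c(seen, sig); break }
      }
      keys[[paste0("G", g)]] <- ss
    }
    keys
  })
}

#' Generate flavor records driven by planted ion subsets
#'
#' Substances are partitioned into groups; each group shares one latent
#' trajectory, a standardized linear combination (slope `effect_size`) of its
#' planted ions evaluated at matching keys (measured ion values where ion
#' records exist, the noiseless model value at months without ion data).
#' Each substance applies its own positive scale and offset plus Gaussian
#' noise of sd `noise_sd` x latent-sd; concentrations are clipped at 0.
#'
#' @param jars `jar_table`.
#' @param ion_out list from [generate_ions()].
#' @param config `synth_config`.
#' @return list: `flavors` (`flavor_table`), `truth` (list of class
#'   `synth_truth`: `group_assignment`, `planted_keys`, `group_sizes`,
#'   `jar_ion_slopes`).
#' @export
generate_flavors <- function(jars, ion_out, config) {
  keys <- draw_planted_keys(config)
  sizes <- draw_group_sizes(config$n_flavors, config$n_groups,
                            derive_seed(config$seed, 23L))
  ions <- ion_out$ions
  grid <- expand.grid(jar_id = jars$jar_id,
                      replicate = seq_len(config$n_replicates),
                      month = config$months)
  # ion value per (grid row, ion): measured where a record exists, model mean otherwise
  ion_vals <- matrix(NA_real_, nrow(grid), length(config$ion_names),
                     dimnames = list(NULL, config$ion_names))
  key_rec <- paste(ions$jar_id, ions$replicate, ions$month)
  key_grid <- paste(grid$jar_id, grid$replicate, grid$month)
  hit <- match(key_grid, key_rec)
  for (i in seq_len(nrow(grid))) {
    ion_vals[i, ] <- if (!is.na(hit[i]))
      as.numeric(ions[hit[i], config$ion_names])
    else ion_mean_at(ion_out$slopes, config, grid$month[i],
                     ion_out$fluct)[, as.character(grid$jar_id[i])]
  }
  ion_z <- scale(ion_vals)
  ion_z[is.nan(ion_z)] <- 0

  latents <- vapply(names(keys), function(g) {
    lv <- rowSums(ion_z[, keys[[g]], drop = FALSE]) * config$effect_size
    sdv <- stats::sd(lv)
    if (sdv > 0) (lv - mean(lv)) / sdv else lv
  }, numeric(nrow(grid)))

  classes <- c("acid", "ester/lipid", "alcohol", "aldehyde", "ketone",
               "cycloalkane", "other")
  group_of <- rep(seq_len(config$n_groups), sizes)
  subs <- sprintf("flavor_%02d", seq_len(config$n_flavors))
  rows <- with_seed(derive_seed(config$seed, 29L), {
    chem <- sample(classes, config$n_flavors, replace = TRUE)
    out <- vector("list", config$n_flavors)
    for (s in seq_len(config$n_flavors)) {
      g <- group_of[s]
      b <- stats::rlnorm(1, 0, 1)             # per-substance scale
      a <- b * stats::runif(1, 3, 6)          # offset keeping values positive
      eps <- stats::rnorm(nrow(grid))
      val <- pmax(a + b * (latents[, g] + config$noise_sd * eps), 0)
      out[[s]] <- data.frame(substance = subs[s], chem_class = chem[s],
                             jar_id = grid$jar_id, replicate = grid$replicate,
                             month = grid$month, mg_per_l = val)
    }
    out
  })
  truth <- structure(list(
    group_assignment = stats::setNames(paste0("G", group_of), subs),
    planted_keys = keys, group_sizes = sizes,
    jar_ion_slopes = ion_out$slopes), class = "synth_truth")
  list(flavors = flavor_table(do.call(rbind, rows)), truth = truth)
}

#' Generate a complete synthetic study
#'
#' @param config `synth_config`.
#' @return list: `dataset` (`study_dataset`), `truth` (`synth_truth`).
#' @export
generate_study <- function(config = synth_config()) {
  jars <- generate_jars(config)
  io <- generate_ions(jars, config)
  fl <- generate_flavors(jars, io, config)
  list(dataset = assemble_dataset(jars, io$ions, fl$flavors),
       truth = fl$truth)
}

#' Write a synthetic study to a directory
#'
#' Emits the three CSV schemas of the data model plus `truth.json`.
#'
#' @param study list from [generate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_jar_table(study$dataset$jars, file.path(dir, "jars.csv"))
  write_ion_table(study$dataset$ions, file.path(dir, "ions.csv"))
  write_flavor_table(study$dataset$flavors, file.path(dir, "flavors.csv"))
  tr <- study$truth
  jsonlite::write_json(
    list(group_assignment = as.list(tr$group_assignment),
         planted_keys = tr$planted_keys,
         group_sizes = tr$group_sizes,
         jar_ion_slopes = as.data.frame(tr$jar_ion_slopes)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
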