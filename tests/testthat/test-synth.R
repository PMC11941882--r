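test_that("generate_jars draws inside the bracketing ranges, deterministically", {
  cfg <- synth_config(seed = 1)
  jars <- generate_jars(cfg)
  expect_equal(nrow(jars), 6L)
  expect_true(all(jars$cu >= 0 & jars$cu <= 0.25))
  expect_true(all(jars$fe >= 5.0 & jars$fe <= 6.1))
  expect_true(all(jars$zn >= 0 & jars$zn <= 0.36))
  expect_true(all(jars$p_max >= 70 & jars$p_max <= 155))
  expect_true(all(jars$p_min >= 2 & jars$p_min <= 7))
  expect_identical(jars, generate_jars(cfg))
  expect_error(synth_config(n_jars = 1), class = "jf_config_error")
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_groups = 49), class = "jf_config_error")
  expect_error(synth_config(effect_size = 0), class = "jf_config_error")
  expect_error(synth_config(noise_sd = -0.1), class = "jf_config_error")
  expect_error(synth_config(planted_keys = list(G1 = c("Zn", "Pb"))),
               class = "jf_config_error")
})

test_that("ion records: exact baseline at month 0, identical replicates at zero noise", {
  cfg <- synth_config(noise_sd = 0, seed = 4)
  jars <- generate_jars(cfg)
  io <- generate_ions(jars, cfg)
  m0 <- io$ions[io$ions$month == 0, ]
  for (nm in ION_NAMES)
    expect_true(all(m0[[nm]] == BASELINE_IONS[[nm]]))
  m20 <- io$ions[io$ions$month == 20 & io$ions$jar_id == 1, ]
  expect_equal(nrow(unique(m20[ION_NAMES])), 1L)  # replicates identical
})

test_that("jar-Zn raises K at month 20 when heterogeneity is off", {
  cfg <- synth_config(noise_sd = 0, jar_effect_sd = 0, seed = 8)
  jars <- generate_jars(cfg)
  # two jars equal in everything but Zn content
  jars <- jar_table(data.frame(jar_id = 1:2, cu = 0.1, fe = 5.5,
                               zn = c(0.05, 0.30), p_max = 100, p_min = 4))
  cfg$n_jars <- 2L
  io <- generate_ions(jars, cfg)
  k20 <- io$ions[io$ions$month == 20 & io$ions$replicate == 1, ]
  expect_gt(k20$K[k20$jar_id == 2], k20$K[k20$jar_id == 1])
})

test_that("default study: 48 flavors in 10 groups spanning all size bands", {
  st <- make_study(seed = 3)
  tr <- st$truth
  expect_length(flavor_substances(st$dataset$flavors), 48L)
  expect_length(tr$planted_keys, 10L)
  expect_equal(sum(tr$group_sizes), 48L)
  expect_true(any(tr$group_sizes <= 5))
  expect_true(any(tr$group_sizes > 5 & tr$group_sizes <= 10))
  expect_true(any(tr$group_sizes > 10))
  expect_true(all(vapply(tr$planted_keys,
                         function(s) all(s %in% ION_NAMES), logical(1))))
})

test_that("zero noise: group members are affine transforms (r = 1)", {
  st <- make_study(noise_sd = 0, seed = 3)
  tr <- st$truth
  g <- names(which(table(tr$group_assignment) >= 2))[1]
  mem <- names(tr$group_assignment)[tr$group_assignment == g][1:2]
  fl <- st$dataset$flavors
  v1 <- fl$mg_per_l[fl$substance == mem[1]]
  v2 <- fl$mg_per_l[fl$substance == mem[2]]
  expect_equal(stats::cor(v1, v2), 1, tolerance = 1e-10)
})

test_that("zero noise: planted ion out-correlates every non-planted ion", {
  st <- make_study(noise_sd = 0, seed = 3,
                   planted_keys = stats::setNames(
                     rep(list("Zn"), 10), paste0("G", 1:10)))
  tr <- st$truth
  s <- names(tr$group_assignment)[1]
  al <- aligned_samples(st$dataset, s)
  r <- abs(stats::cor(al$X, al$y))[, 1]
  expect_equal(names(which.max(r)), "Zn")
})

test_that("generation is deterministic under a fixed seed", {
  a <- make_study(noise_sd = 0.2, seed = 11)
  b <- make_study(noise_sd = 0.2, seed = 11)
  expect_identical(a$dataset$ions, b$dataset$ions)
  expect_identical(a$dataset$flavors, b$dataset$flavors)
  expect_identical(a$truth$planted_keys, b$truth$planted_keys)
  c <- make_study(noise_sd = 0.2, seed = 12)
  expect_false(identical(a$dataset$ions, c$dataset$ions))
})

test_that("write_study emits the three CSV schemas plus truth JSON", {
  st <- make_study(seed = 6)
  d <- tempfile()
  write_study(st, d)
  expect_true(all(file.exists(file.path(
    d, c("jars.csv", "ions.csv", "flavors.csv", "truth.json")))))
  jars <- read_jar_table(file.path(d, "jars.csv"))
  expect_equal(nrow(jars), 6L)
  tr <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_equal(sort(unname(unlist(tr$group_sizes))),
               sort(unname(st$truth$group_sizes)))
})
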