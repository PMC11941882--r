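test_that("jar table fixture parses with the published values", {
  jars <- read_jar_table(fixture_path("jar_parameters.csv"))
  expect_s3_class(jars, "jar_table")
  expect_equal(nrow(jars), 6L)
  j1 <- jars[jars$jar_id == 1, ]
  expect_equal(j1$cu, 0)
  expect_equal(j1$fe, 5.12)
  expect_equal(j1$zn, 0.0077)
  expect_equal(j1$p_max, 76.78)
  expect_equal(j1$p_min, 5.86)
})

test_that("jar reader enforces schema and invariants", {
  p <- tempfile(fileext = ".csv")
  writeLines("jar_id,cu,fe,zn,p_max", p)   # header only, missing p_min
  expect_error(read_jar_table(p), class = "jf_schema_error")

  writeLines(c("jar_id,cu,fe,zn,p_max,p_min"), p)
  expect_equal(nrow(read_jar_table(p)), 0L)  # header-only file -> empty

  writeLines(c("jar_id,cu,fe,zn,p_max,p_min", "1,0,5,0.1,5,6"), p)
  expect_error(read_jar_table(p), class = "jf_validation_error")  # p_max < p_min

  writeLines(c("jar_id,cu,fe,zn,p_max,p_min", "1,abc,5,0.1,80,6"), p)
  expect_error(read_jar_table(p), class = "jf_parse_error")
})

test_that("wide flavor fixture yields 48 records with published cells", {
  fl <- read_flavor_table(fixture_path("flavor_substances.csv"), "wide")
  subs <- flavor_substances(fl)
  expect_length(subs, 48L)
  el <- fl[fl$substance == "Ethyl lactate" & fl$month == 20, ]
  expect_equal(el$mg_per_l[el$jar_id == 1], 2022.28)
  expect_equal(el$mg_per_l[el$jar_id == 6], 2091.28)
  # initial column is shared month-0 data replicated across the jars present
  init <- fl[fl$substance == "Ethyl lactate" & fl$month == 0, ]
  expect_setequal(init$jar_id, c(1, 3, 6))
  expect_true(all(init$mg_per_l == 3113.46))
})

test_that("flavor reader rejects duplicates and unknown columns", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("substance,m12_n1,m12_n2", "A,1,2", "a,3,4"), p)
  expect_error(read_flavor_table(p, "wide"), class = "jf_validation_error")
  writeLines(c("substance,month12jar1", "A,1"), p)
  expect_error(read_flavor_table(p, "wide"), class = "jf_schema_error")
  # single substance, three wide columns -> 3 series entries
  writeLines(c("substance,m12_n1,m16_n1,m20_n1", "A,1,2,3"), p)
  fl <- read_flavor_table(p, "wide")
  expect_equal(nrow(fl), 3L)
})

test_that("ion reader groups long rows and validates the 9-ion panel", {
  ions <- read_ion_table(fixture_path("ion_initial.csv"))
  expect_equal(nrow(ions), 1L)
  expect_equal(ions$Ca, 0.656)
  expect_equal(ions$Zn, 0.0171)
  expect_equal(ions$Cu, 0.00285)
  expect_equal(ions$K, 0.0693)

  p <- tempfile(fileext = ".csv")
  df <- utils::read.csv(fixture_path("ion_initial.csv"))
  utils::write.csv(df[-1, ], p, row.names = FALSE)  # drop one ion -> 8
  expect_error(read_ion_table(p), class = "jf_validation_error")

  df2 <- df; df2$ion[1] <- "Pb"
  utils::write.csv(df2, p, row.names = FALSE)
  expect_error(read_ion_table(p), class = "jf_validation_error")
})

test_that("tables round-trip through CSV", {
  st <- make_study(noise_sd = 0.1, seed = 5)
  d <- tempfile(); dir.create(d)
  write_jar_table(st$dataset$jars, file.path(d, "j.csv"))
  write_ion_table(st$dataset$ions, file.path(d, "i.csv"))
  jars2 <- read_jar_table(file.path(d, "j.csv"))
  ions2 <- read_ion_table(file.path(d, "i.csv"))
  expect_equal(as.data.frame(jars2), as.data.frame(st$dataset$jars),
               tolerance = 1e-12)
  o1 <- st$dataset$ions[order(st$dataset$ions$jar_id,
                              st$dataset$ions$replicate,
                              st$dataset$ions$month), ]
  rownames(o1) <- NULL
  expect_equal(as.data.frame(ions2), as.data.frame(o1), tolerance = 1e-12)
})

test_that("assemble_dataset cross-checks jar linkage", {
  st <- make_study(seed = 2)
  ds <- st$dataset
  expect_equal(sort(unique(ds$design$jar_id)), 1:6)
  bad <- ds$flavors
  bad$jar_id[1] <- 9L
  expect_error(assemble_dataset(ds$jars, ds$ions, bad),
               class = "jf_linkage_error")
  empty_ions <- ds$ions[0, ]
  empty_fl <- ds$flavors[0, ]
  ds0 <- assemble_dataset(ds$jars, empty_ions, empty_fl)
  expect_equal(nrow(ds0$design), 0L)
})

test_that("aligned_samples joins ions and one substance on shared keys", {
  st <- make_study(seed = 2)
  s <- flavor_substances(st$dataset$flavors)[1]
  al <- aligned_samples(st$dataset, s)
  expect_equal(nrow(al$X), 54L)  # 6 jars x 3 replicates x months {12,16,20}
  expect_equal(colnames(al$X), ION_NAMES)
  expect_length(al$y, 54L)
  expect_error(aligned_samples(st$dataset, "no such compound"),
               class = "jf_validation_error")
})
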