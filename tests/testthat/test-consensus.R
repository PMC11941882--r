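fake_metrics <- function(rp2, rmsep = NULL) {
  if (is.null(rmsep)) rmsep <- 1 - rp2
  Map(function(a, b) structure(list(rp2 = a, rmsep = b, rpd = NA, n_test = 12),
                               class = "eval_metrics"),
      rp2, rmsep)
}

test_that("nested subsets are strictly nested prefixes", {
  ns <- build_nested_subsets(ION_NAMES)
  expect_length(ns$subsets, 9L)
  expect_equal(ns$subsets[[9]], ION_NAMES)
  for (i in 2:9) {
    expect_true(all(ns$subsets[[i - 1]] %in% ns$subsets[[i]]))
    expect_length(ns$subsets[[i]], i)
  }
  expect_equal(build_nested_subsets("A")$subsets, list("A"))
  expect_equal(build_nested_subsets(c("Zn", "Cu", "K", "Mg"))$subsets[[3]],
               c("Zn", "Cu", "K"))
  expect_error(build_nested_subsets(c("A", "A")), class = "jf_validation_error")
})

test_that("refined-subset choice maximizes Rp2 with logged RMSEP conflicts", {
  m <- fake_metrics(c(0.5, 0.8, 0.9, 0.95, 0.9, 0.85))
  idx <- select_refined_subset(m)
  expect_equal(as.integer(idx), 4L)
  expect_false(attr(idx, "conflict"))

  expect_equal(as.integer(select_refined_subset(fake_metrics(0.7))), 1L)

  # Rp2 argmax at 4, RMSEP argmin at 5 -> 4 wins, conflict recorded
  m2 <- fake_metrics(c(0.5, 0.8, 0.9, 0.95, 0.9),
                     rmsep = c(0.5, 0.3, 0.2, 0.15, 0.1))
  idx2 <- select_refined_subset(m2)
  expect_equal(as.integer(idx2), 4L)
  expect_true(attr(idx2, "conflict"))

  # exact ties break toward the smaller subset
  expect_equal(as.integer(select_refined_subset(
    fake_metrics(c(0.9, 0.9, 0.8)))), 1L)
  expect_error(select_refined_subset(list()), class = "jf_parameter_error")
})

test_that("refined-subset choice equals brute-force prefix enumeration", {
  with_seed(17, {
    for (rep in 1:25) {
      k <- sample(2:5, 1)
      rp2 <- round(runif(k, -0.5, 0.99), 3)
      m <- fake_metrics(rp2)
      # independent oracle: literal scan over all prefix lengths
      best <- 1
      for (i in seq_len(k)) if (rp2[i] > rp2[best]) best <- i
      expect_equal(as.integer(select_refined_subset(m)), best)
    }
  })
})

test_that("common_features intersects, with >=2-of-3 fallback", {
  s <- c("Zn", "Cu", "K", "Mg")
  expect_setequal(common_features(list(s, s, s)), s)
  expect_setequal(common_features(list(
    c("Zn", "Cu", "K", "Mg", "Na"), c("Zn", "Cu", "K", "Mg"),
    c("Mg", "K", "Cu", "Zn", "Fe"))), s)
  expect_warning(
    fb <- common_features(list(c("A", "B"), c("B", "C"), c("C", "D"))),
    "fallback|falling back")
  expect_setequal(as.character(fb), c("B", "C"))
  expect_true(attr(fb, "fallback"))
})

test_that("majority vote reproduces the published worked example", {
  got <- majority_vote(list(c("Zn", "Cu", "K", "Mg"),
                            c("Zn", "Ca", "K", "Na"),
                            c("Zn", "Na", "Ca", "Mn", "Al")))
  expect_setequal(got, c("Zn", "Na", "Ca", "K"))
  expect_length(majority_vote(list("Ca", "Na", "Mg")), 0L)
  expect_setequal(majority_vote(list(c("Zn", "K"), c("Zn", "K"), c("Zn", "K"))),
                  c("Zn", "K"))
})

test_that("group keys pool representatives by union", {
  expect_setequal(group_key_features(list(c("Zn", "Na"))), c("Zn", "Na"))
  expect_setequal(group_key_features(list(c("Zn", "Na"), c("Zn", "Fe"))),
                  c("Zn", "Na", "Fe"))
  got <- group_key_features(list(c("Zn", "Na", "Fe"), c("Zn", "Mg", "Mn")))
  expect_length(got, 5L)  # two overlapping representative sets pool to 5
  expect_error(group_key_features(list()), class = "jf_parameter_error")
})

test_that("select_key_features honors contracts and votes soundly", {
  st <- make_study(noise_sd = 0.1, seed = 6)
  s <- names(st$truth$group_assignment)[1]
  al <- aligned_samples(st$dataset, s)
  res <- select_key_features(al$X, al$y, al$jar, al$month,
                             lconfig = test_lconfig(n_splits = 5L),
                             rconfig = test_rconfig(), seed = 13)
  # vote soundness: every final key sits in >= 2 per-ranker common sets
  for (k in res$final_keys) {
    hits <- sum(vapply(res$per_ranker_common, function(s) k %in% s, logical(1)))
    expect_gte(hits, 2L)
  }
  # nestedness of every evaluated ordering
  for (rk in names(res$orderings))
    expect_setequal(res$orderings[[rk]], ION_NAMES)
  expect_error(select_key_features(al$X[1:8, ], al$y[1:8], al$jar[1:8]),
               class = "jf_insufficient_data_error")
})

test_that("single ranker + single learner degenerates to plain forward selection", {
  st <- make_study(noise_sd = 0, seed = 6)
  s <- names(st$truth$group_assignment)[1]
  al <- aligned_samples(st$dataset, s)
  lcfg <- test_lconfig(n_splits = 5L)
  res <- select_key_features(al$X, al$y, al$jar, al$month,
                             rankers = "ftest", learners = "rf",
                             lconfig = lcfg, rconfig = test_rconfig(),
                             seed = 13)
  # with one ranker and one learner, final keys = that model's refined prefix
  expect_setequal(res$final_keys,
                  res$per_ranker$ftest$refined$rf$features)
})

test_that("run_consensus evaluates final keys against the 9-ion baseline", {
  st <- make_study(noise_sd = 0.1, seed = 6, n_flavors = 12L, n_groups = 3L)
  g <- group_flavors(st$dataset$flavors, k = 3, seed = 2, n_init = 10)
  res <- run_consensus(st$dataset, g, lconfig = test_lconfig(n_splits = 4L),
                       rconfig = test_rconfig(), seed = 3)
  expect_length(res, 3L)
  tbl <- consensus_table(res)
  expect_true(all(c("group", "representative", "learner", "n_features",
                    "rp2", "rmsep", "rpd", "final_keys", "low_rp2")
                  %in% names(tbl)))
  expect_setequal(unique(tbl$n_features[tbl$n_features != 9]),
                  unique(lengths(lapply(res, `[[`, "final_keys"))))
  expect_true(all(tbl$rmsep >= 0))
})
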