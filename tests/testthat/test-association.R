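test_that("pearson_with_p matches hand arithmetic and contracts", {
  expect_equal(pearson_with_p(1:5, 2 * (1:5) + 1)$r, 1)
  pw <- pearson_with_p(c(1, 2, 3), c(1, 2, 2))
  expect_equal(pw$r, 0.8660254, tolerance = 1e-6)
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)),
               class = "jf_degenerate_error")
  expect_error(pearson_with_p(1:2, 1:2), class = "jf_parameter_error")
})

test_that("t-based p-value sits within Monte-Carlo error of a permutation null", {
  with_seed(3, {
    x <- rnorm(12)
    y <- 0.6 * x + rnorm(12)
  })
  pw <- pearson_with_p(x, y)
  nperm <- 4000
  robs <- abs(stats::cor(x, y))
  exceed <- with_seed(8, sum(replicate(
    nperm, abs(stats::cor(x, sample(y))) >= robs)))
  p_perm <- (exceed + 1) / (nperm + 1)
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(pw$p - p_perm), 4 * se + 0.005)
})

test_that("partial correlation with no controls reduces exactly to Pearson", {
  with_seed(5, { x <- rnorm(20); y <- rnorm(20) })
  expect_identical(partial_correlation(x, y, NULL)[c("r", "p")],
                   pearson_with_p(x, y)[c("r", "p")])
})

test_that("controlling the shared driver removes the correlation", {
  with_seed(9, {
    c1 <- rnorm(60)
    x <- c1 + 0.05 * rnorm(60)
    y <- c1 + 0.1 * rnorm(60)
  })
  pc <- partial_correlation(x, y, cbind(c1))
  expect_lt(abs(pc$r), 0.3)
  expect_gt(abs(pearson_with_p(x, y)$r), 0.9)
})

test_that("residual method agrees with the precision-matrix formula to 1e-10", {
  with_seed(12, {
    for (rep in 1:10) {
      n <- 30; k <- sample(1:3, 1)
      C <- matrix(rnorm(n * k), n, k)
      x <- rnorm(n) + C %*% rnorm(k)
      y <- rnorm(n) + C %*% rnorm(k)
      pc <- partial_correlation(as.numeric(x), as.numeric(y), C)
      # oracle: inverse of the joint correlation matrix
      S <- stats::cor(cbind(x, y, C))
      P <- solve(S)
      r_prec <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
      expect_equal(pc$r, r_prec, tolerance = 1e-10)
    }
  })
})

test_that("collinear controls raise a rank error", {
  with_seed(2, { x <- rnorm(15); y <- rnorm(15); c1 <- rnorm(15) })
  expect_error(partial_correlation(x, y, cbind(c1, 2 * c1)),
               class = "jf_rank_error")
})

test_that("star_marks implements both caption schemes with inclusive bounds", {
  expect_equal(star_marks(0.03, "standard"), "*")
  expect_equal(star_marks(0.07, "partial"), "+")
  expect_equal(star_marks(0.5, "standard"), "")
  expect_equal(star_marks(0.5, "partial"), "")
  expect_equal(star_marks(0.05, "standard"), "*")
  expect_equal(star_marks(0.01, "standard"), "**")
  expect_equal(star_marks(0.1, "partial"), "+")
  expect_equal(star_marks(0.05, "partial"), "++")
  expect_error(star_marks(1.2, "standard"), class = "jf_parameter_error")
})

test_that("jar contrasts reproduce the published percent changes", {
  fl <- read_flavor_table(fixture_path("flavor_substances.csv"), "wide")
  bd <- jar_contrast(fl, "2,3-butanediol", 1, 6, 20)
  expect_equal(bd$pct_change, 100 * (71.28 - 83.45) / 83.45, tolerance = 1e-9)
  expect_equal(bd$pct_change, -14.58, tolerance = 0.01)
  el <- jar_contrast(fl, "Ethyl lactate", 1, 6, 20)
  expect_equal(el$pct_change, 3.41, tolerance = 0.01)
  same <- jar_contrast(fl, "Acetal", 1, 1, 20)
  expect_equal(same$pct_change, 0)
  # zero baseline is flagged, not fabricated
  oct0 <- jar_contrast(fl, "Octanoic acid", 3, 6, 12)
  expect_true(oct0$undefined_baseline)
  expect_true(is.na(oct0$pct_change))
})

test_that("network keeps tiers, filters by p, and grows monotonically", {
  edges1 <- data.frame(source = "P-min", target = "Na",
                       source_tier = "jar_parameter", target_tier = "ion",
                       r = 0.9, p = 0.01)
  edges2 <- data.frame(source = c("Na", "Zn"), target = c("f1", "f2"),
                       source_tier = "ion", target_tier = "flavor",
                       r = c(0.8, -0.5), p = c(0.04, 0.2))
  g05 <- build_network(edges1, edges2, 0.05)
  expect_equal(igraph::ecount(g05), 2)
  expect_setequal(igraph::V(g05)$tier[igraph::V(g05)$name == "Na"], "ion")
  g001 <- build_network(edges1, edges2, 0.001)
  g30 <- build_network(edges1, edges2, 0.3)
  expect_lte(igraph::ecount(g001), igraph::ecount(g05))
  expect_lte(igraph::ecount(g05), igraph::ecount(g30))
  expect_equal(igraph::ecount(g001), 0)
  bad <- edges1; bad$source_tier <- "barrel"
  expect_error(build_network(bad, edges2, 0.05), class = "jf_validation_error")
  p <- tempfile(fileext = ".graphml")
  write_network_graphml(g05, p)
  expect_true(file.exists(p) && file.size(p) > 0)
})

test_that("zero-noise study: planted ion-flavor edges all significant", {
  st <- make_study(noise_sd = 0, seed = 3)
  tr <- st$truth
  ions <- st$dataset$ions[st$dataset$ions$month != 0, ]
  for (g in names(tr$planted_keys)[1:3]) {
    s <- names(tr$group_assignment)[tr$group_assignment == g][1]
    al <- aligned_samples(st$dataset, s)
    for (ion in tr$planted_keys[[g]]) {
      pw <- pearson_with_p(al$X[, ion], al$y)
      expect_lte(pw$p, 0.05)
    }
  }
})

test_that("jar-parameter partial correlations produce a full edge table", {
  st <- make_study(noise_sd = 0.1, seed = 4)
  edges <- jar_ion_partial_edges(st$dataset)
  expect_equal(nrow(edges), 5 * 9)
  expect_true(all(abs(edges$r) <= 1 + 1e-12))
  expect_true(all(edges$p >= 0 & edges$p <= 1))
  expect_true(all(edges$stars %in% c("", "+", "++")))
})
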