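test_that("standardize_trajectories z-scores rows with population sd", {
  fl <- flavor_table(data.frame(
    substance = rep(c("A", "B"), each = 3),
    jar_id = 1L, replicate = 1L, month = rep(c(4L, 8L, 12L), 2),
    mg_per_l = c(1, 2, 3, 5, 5, 5)))
  expect_warning(M <- standardize_trajectories(fl), "constant")
  expect_equal(M["A", ], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(M["B", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(M)) < 1e-12))
})

test_that("mismatched key grids raise an alignment error", {
  fl <- flavor_table(data.frame(
    substance = c("A", "A", "B"),
    jar_id = 1L, replicate = 1L, month = c(4L, 8L, 4L),
    mg_per_l = c(1, 2, 3)))
  expect_error(standardize_trajectories(fl), class = "jf_alignment_error")
})

test_that("k-means: k = n gives singleton clusters with zero objective", {
  # distinct rows (noise > 0) so singleton clusters are well-defined
  st <- make_study(noise_sd = 0.1, seed = 5, n_flavors = 8L, n_groups = 4L)
  M <- standardize_trajectories(st$dataset$flavors)
  g <- kmeans_cluster(M, k = nrow(M), seed = 1)
  expect_equal(g$wss, 0, tolerance = 1e-20)
  expect_equal(sort(tabulate(g$labels, nrow(M))), rep(1L, nrow(M)))
  expect_error(kmeans_cluster(M, k = nrow(M) + 1, seed = 1),
               class = "jf_parameter_error")
})

test_that("two planted blobs are recovered exactly (ARI = 1)", {
  st <- make_study(noise_sd = 0, seed = 9, n_flavors = 12L, n_groups = 2L)
  M <- standardize_trajectories(st$dataset$flavors)
  g <- kmeans_cluster(M, k = 2, seed = 4)
  tr <- st$truth$group_assignment
  expect_equal(adjusted_rand_index(g$labels[names(tr)], tr), 1)
})

test_that("default study clusters into 10 non-empty groups, reproducibly", {
  st <- make_study(seed = 3)
  M <- standardize_trajectories(st$dataset$flavors)
  g1 <- kmeans_cluster(M, k = 10, seed = 21)
  g2 <- kmeans_cluster(M, k = 10, seed = 21)
  expect_identical(g1$labels, g2$labels)
  expect_equal(length(unique(g1$labels)), 10L)
  expect_true(all(tabulate(g1$labels, 10) >= 1))
})

test_that("representative_count implements the size bands", {
  expect_equal(representative_count(1), 1L)
  expect_equal(representative_count(5), 1L)
  expect_equal(representative_count(7), 2L)
  expect_equal(representative_count(10), 2L)  # size-10 gap -> 2-rep band
  expect_equal(representative_count(12), 3L)
  expect_error(representative_count(0), class = "jf_parameter_error")
})

test_that("representatives are the centroid-nearest members, ties alphabetical", {
  # centroid-equal member must rank first
  M <- rbind(a_noisy = c(1, 2, 3, 4) + c(0.5, -0.4, 0.3, -0.2),
             b_exact = c(1, 2, 3, 4),
             c_noisy = c(1, 2, 3, 4) + c(-0.6, 0.5, -0.4, 0.6))
  centroid <- c(1, 2, 3, 4)
  expect_equal(select_representatives(rownames(M), M, centroid, 1), "b_exact")
  # perfect ties break alphabetically
  M2 <- rbind(b = c(1, 2, 3), a = c(2, 4, 6), c = c(0.5, 1, 1.5))
  expect_equal(select_representatives(rownames(M2), M2, c(1, 2, 3), 2),
               c("a", "b"))
  expect_error(select_representatives("x", M2, c(1, 2, 3), 2),
               class = "jf_parameter_error")
})

test_that("total representatives equals the size rule summed over groups", {
  st <- make_study(seed = 3)
  g <- group_flavors(st$dataset$flavors, k = 10, seed = 5, n_init = 20)
  sizes <- tabulate(g$labels, g$k)
  expect_equal(sum(lengths(g$representatives)),
               sum(representative_count(sizes)))
  for (j in seq_len(g$k)) {
    members <- names(g$labels)[g$labels == j]
    expect_true(all(g$representatives[[j]] %in% members))
  }
})
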