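test_that("trajectory distances are Euclidean on raw 4-vectors", {
  df <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    scale = "BI",
    baseline = c(0, 0, 10), day1 = c(0, 0, 12), day30 = c(0, 4, 14),
    day90 = c(0, 3, 16)
  )
  d <- as.matrix(trajectory_distances(df))
  expect_equal(d["a", "b"], 5)  # 3-4-5 triangle
  expect_equal(d["a", "a"], 0)

  set.seed(6)
  for (i in 1:20) {
    X <- tibble::tibble(subject_id = c("x", "y", "z"),
                        baseline = rnorm(3), day1 = rnorm(3),
                        day30 = rnorm(3), day90 = rnorm(3))
    m <- as.matrix(trajectory_distances(X))
    expect_lte(m[1, 3], m[1, 2] + m[2, 3] + 1e-12)
  }

  mixed <- tibble::tibble(subject_id = c("a", "b"), scale = c("BI", "NIHSS"),
                          baseline = 1:2, day1 = 1:2, day30 = 1:2, day90 = 1:2)
  expect_error(trajectory_distances(mixed), "separately")
})

test_that("agglomeration merges duplicates first and makes n-1 merges", {
  df <- tibble::tibble(
    subject_id = c("a1", "a2", "b1", "b2"),
    baseline = c(0, 0, 50, 50), day1 = c(0, 0, 50, 50),
    day30 = c(0, 0, 50, 50), day90 = c(0, 0, 50, 50)
  )
  tree <- agglomerate(trajectory_distances(df))
  expect_equal(length(tree$height), 3)
  expect_equal(tree$height[1:2], c(0, 0))
  cut2 <- cutree(tree, 2)
  expect_equal(unname(cut2[c("a1", "a2")]), rep(cut2[["a1"]], 2))
  expect_equal(unname(cut2[c("b1", "b2")]), rep(cut2[["b1"]], 2))
})

test_that("silhouette follows the standard formula and conventions", {
  # two tight clusters far apart: silhouette approaches 1
  set.seed(8)
  X <- rbind(matrix(rnorm(8, 0, 0.1), 4), matrix(rnorm(8, 10, 0.1), 4))
  D <- dist(X)
  s <- silhouette_score(rep(1:2, each = 4), D)
  expect_gte(s$mean, 0.98)
  expect_true(all(s$widths$silhouette >= -1 & s$widths$silhouette <= 1))

  # singleton convention: every point its own cluster gives mean 0
  s0 <- silhouette_score(1:8, D)
  expect_equal(s0$mean, 0)

  expect_error(silhouette_score(rep(1, 8), D), "single cluster")

  # label permutation invariance
  lab <- rep(1:2, each = 4)
  perm <- c(2, 1)[lab]
  expect_equal(silhouette_score(lab, D)$mean, silhouette_score(perm, D)$mean)
})

test_that("silhouette agrees with the cluster package on random partitions", {
  skip_if_not_installed("cluster")
  set.seed(12)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 3), n)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    D <- dist(X)
    ours <- silhouette_score(lab, D)
    ref <- cluster::silhouette(lab, D)
    if (is.matrix(ref)) {
      expect_equal(ours$widths$silhouette, unname(ref[, "sil_width"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("tree cuts match the exhaustive best-silhouette partition on blobs", {
  set.seed(21)
  X <- rbind(matrix(rnorm(8, 0, 0.5), 4), matrix(rnorm(8, 20, 0.5), 4))
  D <- as.matrix(dist(X))
  tree <- agglomerate(stats::as.dist(D))
  cut2 <- cutree(tree, 2)
  oracle <- best_partition_silhouette(D, 2)
  expect_equal(silhouette_score(cut2, D)$mean, oracle$mean, tolerance = 1e-12)
})

test_that("K selection recovers planted clusters and is deterministic", {
  tspec <- list(BI = planted_traj_spec(K = 5, size = 6))
  ok <- 0
  for (s in 1:10) {
    spec <- ground_truth_spec(n_regions = 4,
                              region_labels = default_region_labels(4),
                              trajectory_spec = tspec, seed = 100 + s)
    sim <- simulate_trajectories(spec, "BI")
    sol <- cluster_trajectories(sim$scores)
    ari <- mclust::adjustedRandIndex(sol$labels[names(sim$true_labels)],
                                     sim$true_labels)
    ok <- ok + (sol$k_selected == 5 && ari == 1)
  }
  expect_gte(ok, 9)

  spec <- ground_truth_spec(n_regions = 4, region_labels = default_region_labels(4),
                            trajectory_spec = tspec, seed = 77)
  sim <- simulate_trajectories(spec, "BI")
  s1 <- cluster_trajectories(sim$scores)
  s2 <- cluster_trajectories(sim$scores)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$silhouette_by_k, s2$silhouette_by_k)
  expect_equal(sort(unique(unname(s1$labels))), seq_len(s1$k_selected))
})

test_that("duplicated two-group data selects K = 2; degenerate input errors", {
  df <- tibble::tibble(
    subject_id = sprintf("s%d", 1:8),
    baseline = rep(c(0, 40), each = 4), day1 = rep(c(1, 41), each = 4),
    day30 = rep(c(2, 42), each = 4), day90 = rep(c(3, 43), each = 4)
  )
  sol <- cluster_trajectories(df)
  expect_equal(sol$k_selected, 2)

  same <- tibble::tibble(subject_id = c("a", "b", "c"), baseline = 1, day1 = 1,
                         day30 = 1, day90 = 1)
  expect_error(cluster_trajectories(same), "degenerate")
})

test_that("tidy, glance and incomplete-subject handling work end to end", {
  tspec <- list(NIHSS = planted_traj_spec(K = 2, size = 5, sep_per_tp = 8,
                                          noise_sd = 1, scale_max = 42))
  spec <- ground_truth_spec(n_regions = 4, region_labels = default_region_labels(4),
                            trajectory_spec = tspec, seed = 3)
  sim <- simulate_trajectories(spec, "NIHSS")
  scores <- sim$scores
  scores$day90[1] <- NA
  scores$complete[1] <- FALSE
  sol <- cluster_trajectories(scores)
  expect_equal(sol$n, 9)
  td <- tidy(sol)
  expect_equal(nrow(td), 9)
  expect_false(scores$subject_id[1] %in% td$subject_id)
  gl <- glance(sol)
  expect_equal(gl$k_selected, sol$k_selected)
  expect_true(gl$mean_silhouette >= -1 && gl$mean_silhouette <= 1)
})
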