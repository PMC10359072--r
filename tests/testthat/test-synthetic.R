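test_that("base covariance is deterministic, SPD, unit diagonal", {
  S1 <- make_base_covariance(45, seed = 3)
  S2 <- make_base_covariance(45, seed = 3)
  expect_identical(S1, S2)
  expect_false(identical(S1, make_base_covariance(45, seed = 4)))
  expect_equal(diag(S1), rep(1, 45))
  expect_gt(min(eigen(S1, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(dim(make_base_covariance(2, seed = 1)), c(2, 2))
  expect_error(make_base_covariance(1), "at least 2")

  # block structure raises within-block correlation
  blocks <- rep(1:2, each = 10)
  Sb <- make_base_covariance(20, block_structure = blocks, seed = 5)
  within <- Sb[1:10, 1:10][upper.tri(diag(10))]
  between <- Sb[1:10, 11:20]
  expect_gt(mean(within), mean(between))
})

test_that("normative cohorts are reproducible and centred on the base matrix", {
  spec <- small_spec(R = 10, seed = 5)
  a <- simulate_normative_cohort(spec, n_subjects = 3, T = 50)
  b <- simulate_normative_cohort(spec, n_subjects = 3, T = 50)
  expect_identical(lapply(a, `[[`, "data"), lapply(b, `[[`, "data"))
  expect_equal(unname(apply(a[[1]]$data, 2, sd)), rep(1, 10), tolerance = 1e-12)

  # mean sample correlation across many subjects approaches the base entry
  coh <- simulate_normative_cohort(spec, n_subjects = 200, T = 400)
  r12 <- vapply(coh, function(ts) cor(ts$data[, 1], ts$data[, 2]), numeric(1))
  se <- sd(r12) / sqrt(length(r12))
  expect_lt(abs(mean(r12) - spec$base_covariance[1, 2]), 3 * se + 0.01)
})

test_that("a very large jitter makes subjects share the base covariance", {
  spec <- small_spec(R = 5, seed = 8, subject_jitter = 1e7)
  coh <- simulate_normative_cohort(spec, n_subjects = 4, T = 5000)
  for (ts in coh) {
    expect_lt(max(abs(cor(ts$data) - spec$base_covariance)), 0.08)
  }
})

test_that("planted patients carry symmetric ground truth of the right size", {
  spec0 <- small_spec(R = 8, seed = 14)
  p0 <- simulate_patient(spec0, "left", T = 60)
  ut <- upper.tri(p0$truth$labels)
  expect_true(all(p0$truth$labels[ut] == "normal"))
  expect_true(all(diag(p0$truth$labels) == "excluded"))

  pa <- tibble::tibble(i = 2, j = 5, direction = "hyper", magnitude = 6)
  spec1 <- small_spec(R = 8, seed = 14, planted_anomalies = pa)
  p1 <- simulate_patient(spec1, "right", T = 60)
  expect_equal(sum(p1$truth$labels[ut] == "hyper"), 1)
  expect_equal(p1$truth$labels[2, 5], "hyper")
  expect_equal(p1$truth$labels, t(p1$truth$labels))
  expect_error(small_spec(R = 8, planted_anomalies = tibble::tibble(
    i = 5, j = 2, direction = "hyper", magnitude = 6)))
})

test_that("planted tangent offsets move the patient covariance as specified", {
  pa <- tibble::tibble(i = 1, j = 2, direction = "hypo", magnitude = 6)
  spec <- small_spec(R = 4, seed = 9, planted_anomalies = pa)
  T <- 2000
  sd0 <- sqrt(1 / spec$subject_jitter + 1 / T)
  p <- simulate_patient(spec, "left", T = T)
  # the estimated tangent offset at the planted pair recovers -magnitude * sd
  Tm <- tangent_project(estimate_connectivity(p$ts, lambda = 0.01),
                        spec$base_covariance)
  expect_lt(abs(Tm[1, 2] - (-6 * sd0)), 0.12)
  # unplanted pairs stay near zero
  expect_lt(abs(Tm[3, 4]), 0.12)
})

test_that("trajectory simulation respects means, bounds and integer rounding", {
  ts0 <- list(BI = list(means = matrix(c(10, 20, 30, 40), 1), sizes = 5,
                        noise_sd = 0))
  spec <- small_spec(R = 4, trajectory_spec = ts0)
  sim <- simulate_trajectories(spec, "BI")
  tp <- c("baseline", "day1", "day30", "day90")
  for (i in seq_len(5)) {
    expect_equal(unlist(sim$scores[i, tp], use.names = FALSE), c(10, 20, 30, 40))
  }
  expect_true(all(sim$scores$complete))

  clip <- list(BI = list(means = matrix(c(98, 98, 98, 98), 1), sizes = 40,
                         noise_sd = 5))
  spec2 <- small_spec(R = 4, seed = 2, trajectory_spec = clip)
  sim2 <- simulate_trajectories(spec2, "BI")
  vals <- unlist(sim2$scores[, tp])
  expect_true(all(vals <= 100))
  expect_true(all(vals == round(vals)))

  too_many <- list(BI = list(means = matrix(0, 6, 4), sizes = rep(1, 6),
                             noise_sd = 1))
  spec3 <- small_spec(R = 4, trajectory_spec = too_many)
  sim3 <- simulate_trajectories(spec3, "BI")   # K == n is allowed
  expect_equal(length(unique(sim3$true_labels)), 6)
  expect_error(simulate_trajectories(spec3, "FMA1"), "no trajectory spec")
})

test_that("structural ratings respond to the association strength", {
  labels <- setNames(rep(1:5, length.out = 22), sprintf("p%02d", 1:22))
  r1 <- simulate_structural_ratings(labels, association_strength = 1, seed = 4)
  expect_true(all(r1$integrity %in% 0:2) && all(r1$proximity %in% 0:2))
  by_ct <- dplyr::n_distinct(
    dplyr::summarise(dplyr::group_by(dplyr::mutate(r1, cl = labels[subject_id]),
                                     cl, tract_class),
                     v = dplyr::n_distinct(integrity), .groups = "drop")$v)
  expect_equal(by_ct, 1)  # integrity constant within cluster x tract

  # strength 0: cluster has no effect, Kruskal-Wallis stays null-calibrated
  nonsig <- 0
  for (s in 1:100) {
    r0 <- simulate_structural_ratings(labels, association_strength = 0, seed = s)
    cst <- r0[r0$tract_class == "CST", ]
    p <- compare_clusters_numeric(cst$integrity, labels[cst$subject_id])$omnibus$p_value
    nonsig <- nonsig + (p > 0.05)
  }
  expect_gte(nonsig, 90)
})
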