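test_that("connectivity estimation shrinks correlations toward identity", {
  set.seed(1)
  x <- rnorm(50)
  X <- cbind(a = x, b = x, c = rnorm(50))
  C <- estimate_connectivity(X, lambda = 0.1)
  expect_equal(C[1, 2], 0.9, tolerance = 1e-12)
  expect_equal(unname(diag(unclass_mat(C))), c(1, 1, 1))

  # shrinkage contract: eigenvalues bounded below by lambda
  Y <- matrix(rnorm(30 * 6), 30)
  ev <- eigen(unclass_mat(estimate_connectivity(Y, 0.05)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), 0.05 - 1e-10)

  Z <- cbind(rnorm(40), rep(1, 40))
  colnames(Z) <- c("ok", "flat")
  expect_error(estimate_connectivity(Z), "zero-variance region: flat")
})

test_that("independent long series give near-zero off-diagonals", {
  set.seed(2)
  T <- 2000
  X <- matrix(rnorm(T * 5), T)
  C <- estimate_connectivity(X, lambda = 0.01)
  off <- C[upper.tri(C)]
  expect_true(all(abs(off) < 4 / sqrt(T)))
})

test_that("normative fit masks exactly the ceiling(P/3) most variable pairs", {
  spec <- small_spec(R = 8, seed = 77)
  coh <- simulate_normative_cohort(spec, n_subjects = 30, T = 200)
  mod <- fit_normative(lapply(coh, estimate_connectivity))
  P <- 8 * 7 / 2
  expect_equal(sum(mod$mask[upper.tri(mod$mask)]), ceiling(P / 3))
  # masked pairs have the largest normative SDs
  sd_up <- mod$sigma[upper.tri(mod$sigma)]
  masked <- mod$mask[upper.tri(mod$mask)]
  expect_gte(min(sd_up[masked]), max(sd_up[!masked]))
  # mask matrix is symmetric with a FALSE diagonal
  expect_equal(mod$mask, t(mod$mask))
  expect_false(any(diag(mod$mask)))
})

test_that("an identical-matrix cohort is rejected as degenerate", {
  C <- rand_spd(5, seed = 3)
  expect_error(fit_normative(list(C, C, C)), "degenerate")
})

test_that("normative mean is near zero for a homogeneous cohort", {
  # first-order Karcher property: the cohort's tangent mean at its own
  # Frechet mean vanishes as n grows
  spec <- small_spec(R = 6, seed = 13)
  coh <- simulate_normative_cohort(spec, n_subjects = 120, T = 300)
  mod <- fit_normative(lapply(coh, estimate_connectivity))
  expect_lt(max(abs(mod$mu)), 1e-2)
})

test_that("anomaly labels follow the z thresholds with an inclusive boundary", {
  spec <- small_spec(R = 6, seed = 21)
  coh <- simulate_normative_cohort(spec, n_subjects = 60, T = 300)
  mod <- fit_normative(lapply(coh, estimate_connectivity))

  # a patient at the reference with mu forced to zero: all unmasked normal
  mod0 <- mod
  mod0$mu[] <- 0
  am0 <- score_anomalies(mod$reference, mod0)
  ut <- upper.tri(am0$labels)
  expect_true(all(am0$labels[ut][am0$labels[ut] != "excluded"] == "normal"))

  # construct a patient whose tangent value sits exactly at +3 SD on one pair
  pick <- which(!mod$mask & upper.tri(mod$mask), arr.ind = TRUE)[1, ]
  Tm <- mod$mu
  Tm[pick[1], pick[2]] <- Tm[pick[2], pick[1]] <-
    mod$mu[pick[1], pick[2]] + 3 * mod$sigma[pick[1], pick[2]]
  patient <- tangent_embed(Tm, mod$reference)
  am3 <- score_anomalies(patient, mod)
  expect_equal(am3$z_values[pick[1], pick[2]], 3, tolerance = 1e-8)
  # inclusive boundary: a z exactly at the threshold is still "normal"
  amb <- score_anomalies(patient, mod,
                         sigma_threshold = am3$z_values[pick[1], pick[2]])
  expect_equal(amb$labels[pick[1], pick[2]], "normal")

  # nudging above the threshold flips the label to hyper
  Tm[pick[1], pick[2]] <- Tm[pick[2], pick[1]] <-
    mod$mu[pick[1], pick[2]] + 3.01 * mod$sigma[pick[1], pick[2]]
  am31 <- score_anomalies(tangent_embed(Tm, mod$reference), mod)
  expect_equal(am31$labels[pick[1], pick[2]], "hyper")

  # excluded set is exactly mask plus diagonal, and labels stay symmetric
  expect_equal(am3$labels == "excluded", mod$mask | diag(TRUE, 6))
  expect_equal(am3$labels, t(am3$labels))

  expect_error(score_anomalies(rand_spd(4, 1), mod), "size")
})

test_that("raising the sigma threshold shrinks the anomaly set", {
  spec <- small_spec(R = 8, seed = 31)
  coh <- simulate_normative_cohort(spec, n_subjects = 60, T = 120)
  mod <- fit_normative(lapply(coh, estimate_connectivity))
  pat <- simulate_normative_cohort(spec, n_subjects = 2, T = 120, seed = 999)[[1]]
  C <- estimate_connectivity(pat)
  n_anom <- vapply(c(1, 2, 3, 4), function(thr) {
    am <- score_anomalies(C, mod, sigma_threshold = thr)
    sum(am$labels %in% c("hypo", "hyper"))
  }, numeric(1))
  expect_true(all(diff(n_anom) <= 0))
})

test_that("anomaly counts split by laterality and mirror correctly", {
  labels <- default_region_labels(6)
  tags <- paste(labels$hemisphere, labels$class, labels$name, sep = ":")
  L <- matrix("normal", 6, 6, dimnames = list(tags, tags))
  diag(L) <- "excluded"
  am <- structure(list(labels = L, z_values = matrix(NA_real_, 6, 6),
                       region_labels = labels, sigma_threshold = 3),
                  class = "anomaly_matrix")
  c0 <- count_anomalies(am, lesion_side = "right")
  expect_true(all(c0$hypo_count == 0) && all(c0$hyper_count == 0))

  # one hyper pair between two right-hemisphere regions, right lesion
  r_idx <- which(labels$hemisphere == "R")[1:2]
  L2 <- L
  L2[r_idx[1], r_idx[2]] <- L2[r_idx[2], r_idx[1]] <- "hyper"
  am2 <- am; am2$labels <- L2
  c2 <- count_anomalies(am2, lesion_side = "right")
  expect_equal(sum(c2$hyper_count), 2)  # incident to both endpoints
  expect_equal(c2$laterality[r_idx], rep("ipsilesional", 2))
  tot <- anomaly_totals(c2)
  expect_equal(sum(tot$hyper_incident[tot$laterality == "ipsilesional"]), 2)
  expect_equal(sum(tot$flagged_parcels), 2)

  # mirroring the anomaly matrix across hemispheres and flipping the lesion
  # side reproduces the same laterality-resolved counts
  mirror_idx <- match(paste(ifelse(labels$hemisphere == "L", "R",
                                   ifelse(labels$hemisphere == "R", "L", "M")),
                            labels$class, labels$name),
                      paste(labels$hemisphere, labels$class, labels$name))
  L3 <- L2[mirror_idx, mirror_idx]
  am3 <- am
  am3$labels <- L3
  dimnames(am3$labels) <- dimnames(L)
  c3 <- count_anomalies(am3, lesion_side = "left")
  agg2 <- anomaly_totals(c2)
  agg3 <- anomaly_totals(c3)
  expect_equal(agg2, agg3)

  bad <- labels; bad$hemisphere[1] <- "X"
  expect_error(count_anomalies(am, labels = bad, lesion_side = "left"),
               "unknown hemisphere")
})
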