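# Shared fixtures, built in code.

# Random SPD correlation-like matrix (unit diagonal after cov2cor).
rand_spd <- function(R, seed = 1, corr = TRUE) {
  set.seed(seed)
  A <- matrix(rnorm(R * R), R)
  S <- crossprod(A) / R + diag(R) * 0.5
  if (corr) S <- stats::cov2cor(S)
  (S + t(S)) / 2
}

# Long-format score records for one subject/scale across all four timepoints.
score_records <- function(subject_id, scale, values) {
  data.frame(subject_id = subject_id, scale = scale,
             timepoint = c("baseline", "day1", "day30", "day90"),
             value = values)
}

# A small ground-truth spec used across tests.
small_spec <- function(R = 6, seed = 11, ...) {
  ground_truth_spec(n_regions = R, region_labels = default_region_labels(R),
                    seed = seed, ...)
}

# Well-separated K-cluster trajectory spec: adjacent cluster means differ by
# `sep_per_tp` on every timepoint (Euclidean separation 2 * sep_per_tp).
planted_traj_spec <- function(K = 5, size = 6, sep_per_tp = 12, noise_sd = 3,
                              scale_max = 100) {
  base <- seq(5, by = sep_per_tp, length.out = K)
  means <- t(vapply(base, function(b) b + c(0, 1, 2, 3), numeric(4)))
  stopifnot(max(means) <= scale_max)
  list(means = means, sizes = rep(size, K), noise_sd = noise_sd)
}

# Exhaustive best partition of n <= 8 points into exactly k nonempty clusters,
# maximizing mean silhouette (independent oracle for tree cuts).
best_partition_silhouette <- function(D, k) {
  n <- nrow(D)
  stopifnot(n <= 8)
  best <- -Inf; best_labels <- NULL
  assign_next <- function(labels, i, used) {
    if (i > n) {
      if (used == k) {
        s <- silhouette_score(labels, D)$mean
        if (s > best) { best <<- s; best_labels <<- labels }
      }
      return(invisible())
    }
    for (lab in seq_len(min(used + 1, k))) {
      assign_next(c(labels, lab), i + 1, max(used, lab))
    }
  }
  assign_next(integer(0), 1, 0)
  list(mean = best, labels = best_labels)
}

# Exact Friedman p-value by enumerating all within-row orderings of the
# observed values (ties preserved): permutation distribution of the
# tie-corrected statistic.
friedman_exact_p <- function(y) {
  n <- nrow(y); k <- ncol(y)
  perms <- gtools_permutations(k)
  stat_of <- function(mat) {
    ft <- suppressWarnings(stats::friedman.test(mat))
    s <- unname(ft$statistic)
    if (!is.finite(s)) 0 else s
  }
  obs <- stat_of(y)
  total <- nrow(perms)^n
  count <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
  for (g in seq_len(nrow(grid))) {
    mat <- t(vapply(seq_len(n), function(r) y[r, perms[grid[g, r], ]], numeric(k)))
    if (stat_of(mat) >= obs - 1e-12) count <- count + 1
  }
  count / total
}

# All permutations of 1..k (tiny k only).
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- gtools_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(pos, sub + (sub >= pos))
  }))
}

# Strip conn_matrix attributes for raw-matrix comparisons.
unclass_mat <- function(x) { attr(x, "kind") <- NULL; unclass(x) }

# Build a complete small synthetic study on disk: normative cohort, patients
# (optionally with planted anomalies in the first trajectory cluster), scores
# for two scales, metadata and structural ratings. Returns the paths plus the
# planted truth.
make_study_dir <- function(root, seed = 1, planted = TRUE) {
  R <- 8; T <- 120
  labels <- default_region_labels(R)
  tspec <- list(
    BI = planted_traj_spec(K = 2, size = 4, sep_per_tp = 15, noise_sd = 2),
    NIHSS = planted_traj_spec(K = 2, size = 4, sep_per_tp = 8, noise_sd = 1,
                              scale_max = 42)
  )
  spec <- ground_truth_spec(n_regions = R, region_labels = labels,
                            trajectory_spec = tspec, seed = seed)
  dir.create(file.path(root, "normative"), recursive = TRUE, showWarnings = FALSE)
  for (ts in simulate_normative_cohort(spec, 20, T)) {
    write_region_ts(ts, file.path(root, "normative", paste0(ts$subject_id, ".tsv")))
  }

  pa <- tibble::tibble(i = c(1, 2), j = c(4, 6),
                       direction = c("hypo", "hyper"), magnitude = 8)
  meta <- tibble::tibble(subject_id = sprintf("p%03d", 1:8),
                         lesion_side = rep(c("left", "right"), 4),
                         age = seq(48, 76, length.out = 8),
                         sex = rep(c("female", "male"), 4))
  spec_planted <- ground_truth_spec(n_regions = R, region_labels = labels,
                                    base_covariance = spec$base_covariance,
                                    planted_anomalies = pa,
                                    trajectory_spec = tspec, seed = seed)
  dir.create(file.path(root, "patients"), showWarnings = FALSE)
  for (k in 1:8) {
    sp <- if (planted && k <= 4) spec_planted else spec
    p <- simulate_patient(sp, meta$lesion_side[k], T = T, seed = seed * 100 + k)
    p$ts$subject_id <- meta$subject_id[k]
    write_region_ts(p$ts, file.path(root, "patients",
                                    paste0(meta$subject_id[k], ".tsv")))
  }

  long <- do.call(rbind, lapply(c("BI", "NIHSS"), function(sc) {
    w <- simulate_trajectories(spec, sc)$scores
    data.frame(subject_id = rep(w$subject_id, each = 4), scale = sc,
               timepoint = rep(c("baseline", "day1", "day30", "day90"),
                               nrow(w)),
               value = as.numeric(t(as.matrix(
                 w[, c("baseline", "day1", "day30", "day90")]))))
  }))
  write.csv(long, file.path(root, "scores.csv"), row.names = FALSE, quote = FALSE)
  write.csv(meta, file.path(root, "metadata.csv"), row.names = FALSE, quote = FALSE)
  ratings <- simulate_structural_ratings(
    setNames(rep(1:2, each = 4), meta$subject_id), 1, seed = seed)
  write.csv(ratings, file.path(root, "ratings.csv"), row.names = FALSE, quote = FALSE)
  list(root = root, planted_pairs = pa, planted_subjects = meta$subject_id[1:4],
       labels = labels)
}

study_config <- function(study, out_dir, seed = 1) {
  run_config(
    normative_dir = file.path(study$root, "normative"),
    patient_dir = file.path(study$root, "patients"),
    scores_file = file.path(study$root, "scores.csv"),
    metadata_file = file.path(study$root, "metadata.csv"),
    ratings_file = file.path(study$root, "ratings.csv"),
    out_dir = out_dir, seed = seed
  )
}

with_seed_local <- function(seed, code) { set.seed(seed); force(code) }

# eigendecomposition helper independent of package internals
sym_fun_test <- function(S, f) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(f(e$values)) %*% t(e$vectors)
}
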