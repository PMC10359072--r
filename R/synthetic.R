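#' Default hemisphere-tagged region labels
#'
#' A synthetic stand-in for the 45-region motor + subcortical parcel set used
#' by the normative analysis (the original region list is study configuration,
#' not shipped here): 13 motor-network cortical region pairs, 9 subcortical
#' structure pairs and a midline brainstem node. For other `R`, roughly 60% of
#' region pairs are labelled cortical and the rest subcortical, with a midline
#' node when `R` is odd.
#'
#' @param R Number of regions (default 45).
#' @return Tibble with columns `hemisphere` (`"L"`/`"R"`/`"M"`), `class`, `name`.
#' @export
default_region_labels <- function(R = 45) {
  stopifnot(R >= 2)
  cortical <- c("M1", "S1", "SCEF", "preSMA", "SMA", "PMd", "PMv", "24dd",
                "6mp", "FEF", "55b", "OP4", "CingMot")
  subcort <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
               "amygdala", "accumbens", "ventral_dc", "cerebellum")
  n_pairs <- R %/% 2
  midline <- R %% 2 == 1
  n_cort <- if (R == 45) 13 else ceiling(0.6 * n_pairs)
  n_sub <- n_pairs - n_cort
  nm_c <- if (n_cort <= length(cortical)) cortical[seq_len(n_cort)] else
    sprintf("ctx%02d", seq_len(n_cort))
  nm_s <- if (n_sub <= length(subcort)) subcort[seq_len(max(0, n_sub))] else
    sprintf("sub%02d", seq_len(n_sub))
  pairs <- tibble::tibble(
    name = rep(c(nm_c, nm_s), each = 2),
    class = rep(c(rep("cortical", n_cort), rep("subcortical", n_sub)), each = 2),
    hemisphere = rep(c("L", "R"), times = n_pairs)
  )
  out <- pairs[, c("hemisphere", "class", "name")]
  if (midline) {
    out <- dplyr::bind_rows(out, tibble::tibble(hemisphere = "M",
                                                class = "subcortical",
                                                name = "brainstem"))
  }
  out
}

#' Unit-diagonal SPD base correlation matrix
#'
#' Deterministic, seeded construction of the population correlation matrix
#' used by the generators: a low-rank loading model `L L' + D` normalized to
#' unit diagonal, optionally with community structure (regions sharing a block
#' id load on an extra common factor, mimicking a motor community).
#'
#' @param R Number of regions (>= 2).
#' @param block_structure Optional integer vector of length `R` with block
#'   ids, or `NULL` for a single global factor.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return R x R unit-diagonal SPD correlation matrix.
#' @export
make_base_covariance <- function(R, block_structure = NULL, seed = 1) {
  if (!is.numeric(R) || R < 2) rlang::abort("R must be at least 2")
  R <- as.integer(R)
  with_seed(seed, {
    load <- runif(R, 0.3, 0.7)
    S <- load %o% load
    if (!is.null(block_structure)) {
      stopifnot(length(block_structure) == R)
      for (b in unique(block_structure)) {
        in_b <- block_structure == b
        bl <- numeric(R)
        bl[in_b] <- runif(sum(in_b), 0.25, 0.5)
        S <- S + bl %o% bl
      }
    }
    diag(S) <- diag(S) + runif(R, 0.3, 0.6)
    S <- stats::cov2cor(S)
    (S + t(S)) / 2
  })
}

#' Ground-truth specification for synthetic cohorts
#'
#' Bundles everything the generators need: the base correlation structure, the
#' inter-subject covariance dispersion, the planted connectivity anomalies and
#' the planted recovery-trajectory clusters.
#'
#' @param n_regions Number of regions R (default 45).
#' @param region_labels Label tibble, see [default_region_labels()].
#' @param base_covariance Unit-diagonal SPD matrix, or `NULL` to build one
#'   with [make_base_covariance()].
#' @param subject_jitter Wishart degrees of freedom `kappa` controlling
#'   inter-subject covariance variability around the base matrix (the draw is
#'   mean-preserving; smaller `kappa` means more variability; must be >=
#'   `n_regions`). Default 100.
#' @param planted_anomalies Tibble with columns `i`, `j` (region indices,
#'   i < j), `direction` (`"hypo"`/`"hyper"`), `magnitude` (in normative-SD
#'   units); default none.
#' @param trajectory_spec Named list (per scale) of lists with elements
#'   `means` (K x 4 matrix), `sizes` (length K) and `noise_sd`; default
#'   [default_trajectory_spec()].
#' @param seed Base integer seed; the generators derive per-operation streams
#'   from it.
#' @return List of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_regions = 45,
                              region_labels = default_region_labels(n_regions),
                              base_covariance = NULL,
                              subject_jitter = 100,
                              planted_anomalies = NULL,
                              trajectory_spec = default_trajectory_spec(),
                              seed = 1) {
  stopifnot(n_regions >= 2, nrow(region_labels) == n_regions)
  if (is.null(base_covariance)) {
    base_covariance <- make_base_covariance(n_regions, seed = seed)
  }
  base_covariance <- spd_check(base_covariance, "base_covariance")
  if (max(abs(diag(base_covariance) - 1)) > 1e-8) {
    rlang::abort("base_covariance must have unit diagonal")
  }
  if (subject_jitter < n_regions) {
    rlang::abort("subject_jitter (Wishart df) must be >= n_regions")
  }
  if (is.null(planted_anomalies)) {
    planted_anomalies <- tibble::tibble(i = integer(), j = integer(),
                                        direction = character(),
                                        magnitude = numeric())
  }
  planted_anomalies <- tibble::as_tibble(planted_anomalies)
  if (nrow(planted_anomalies)) {
    stopifnot(
      all(planted_anomalies$i >= 1), all(planted_anomalies$j <= n_regions),
      all(planted_anomalies$i < planted_anomalies$j),
      all(planted_anomalies$direction %in% c("hypo", "hyper")),
      all(planted_anomalies$magnitude > 0)
    )
  }
  for (ts in trajectory_spec) {
    stopifnot(is.matrix(ts$means), ncol(ts$means) == 4,
              length(ts$sizes) == nrow(ts$means), all(ts$sizes >= 1),
              ts$noise_sd >= 0)
  }
  structure(
    list(n_regions = as.integer(n_regions), region_labels = region_labels,
         base_covariance = base_covariance, subject_jitter = subject_jitter,
         planted_anomalies = planted_anomalies,
         trajectory_spec = trajectory_spec, seed = as.integer(seed)),
    class = "ground_truth_spec"
  )
}

#' Planted recovery-trajectory clusters used by default
#'
#' Cluster mean trajectories, sizes and noise levels per stroke scale,
#' emulating a 22-patient acute cohort: the cluster counts (6 for NIHSS, 2 for
#' FMA, 5 for BI, 2 for WMFT) and sizes match the phenotype structure the
#' pipeline is designed to recover, with baseline levels near the cohort means
#' (NIHSS ~11, FMA ~16, BI ~9, WMFT ~12) and integer-rounded scores.
#'
#' @return Named list (per scale) of `means` / `sizes` / `noise_sd`.
#' @export
default_trajectory_spec <- function() {
  m <- function(...) matrix(c(...), ncol = 4, byrow = TRUE)
  list(
    NIHSS = list(
      means = m(12, 10, 6, 3,
                8, 7, 5, 4,
                11, 11, 9, 8,
                12, 10, 10, 10,
                16, 15, 14, 13,
                22, 20, 18, 17),
      sizes = c(4, 3, 8, 4, 2, 1), noise_sd = 1.5
    ),
    FMA = list(
      means = m(16, 18, 25, 35,
                18, 14, 12, 10),
      sizes = c(18, 4), noise_sd = 3
    ),
    BI = list(
      means = m(10, 10, 20, 5,
                5, 5, 5, 10,
                10, 15, 40, 70,
                5, 10, 30, 60,
                10, 10, 15, 10),
      sizes = c(2, 5, 6, 3, 6), noise_sd = 4
    ),
    WMFT = list(
      means = m(11, 12, 14, 16,
                13, 13, 13, 20),
      sizes = c(16, 6), noise_sd = 1.5
    )
  )
}

# One Wishart-dispersed subject covariance around Sigma0 (mean-preserving).
draw_subject_cov <- function(Sigma0, kappa) {
  rWishart(1, df = kappa, Sigma = Sigma0 / kappa)[, , 1]
}

sample_gaussian_ts <- function(Sigma, T) {
  U <- NULL
  for (try in 1:10) {
    U <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (!is.null(U)) break
    message("non-SPD covariance draw; retrying with jitter")
    Sigma <- Sigma + diag(1e-8 * try, nrow(Sigma))
  }
  if (is.null(U)) rlang::abort("covariance not positive definite after retries")
  Z <- matrix(rnorm(T * nrow(Sigma)), T, nrow(Sigma))
  X <- Z %*% U
  X <- scale(X)  # unit variance per region
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Simulate a normative (healthy reference) cohort
#'
#' Each subject gets a covariance drawn around the base matrix with Wishart
#' dispersion `subject_jitter` (larger values concentrate subjects on the base
#' matrix) and then `T` independent zero-mean Gaussian samples with that
#' covariance, renormalized to unit variance per region. Temporal
#' autocorrelation is deliberately omitted: downstream analysis consumes only
#' the spatial covariance.
#'
#' @param spec A [ground_truth_spec()].
#' @param n_subjects Number of reference subjects (>= 2).
#' @param T Samples (volumes) per subject; a warning is issued when `T <= R`.
#' @param seed Seed for this operation; defaults to `spec$seed`.
#' @return List of [region_ts()] objects.
#' @export
simulate_normative_cohort <- function(spec, n_subjects = 200, T = 400,
                                      seed = spec$seed) {
  stopifnot(inherits(spec, "ground_truth_spec"), n_subjects >= 2)
  if (T <= spec$n_regions) {
    rlang::warn("T <= number of regions: correlation estimates will be noisy")
  }
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      Sigma_s <- draw_subject_cov(spec$base_covariance, spec$subject_jitter)
      region_ts(sample_gaussian_ts(Sigma_s, T), spec$region_labels,
                subject_id = sprintf("norm%03d", s))
    })
  })
}

#' Simulate one patient with planted connectivity anomalies
#'
#' The patient covariance is built by perturbing the base matrix in its own
#' tangent space: the planted pairs get offsets of
#' `direction * magnitude * pair_sd`, and the perturbed tangent matrix is
#' mapped back to the SPD manifold (which preserves positive definiteness by
#' construction). `pair_sd` should be the normative per-pair tangent SD; when
#' no fitted model is available, the analytic default `sqrt(1/kappa + 1/T)`
#' (jitter plus sampling variability) is used.
#'
#' @param spec A [ground_truth_spec()] with `planted_anomalies`.
#' @param lesion_side `"left"` or `"right"`.
#' @param T Samples per scan.
#' @param pair_sd Optional R x R matrix of normative per-pair tangent SDs
#'   (e.g. `model$sigma` from [fit_normative()]).
#' @param seed Seed for this operation; defaults to `spec$seed + 1`.
#' @return List with `ts` (a [region_ts()]), `truth` (an `anomaly_matrix` of
#'   planted labels, symmetric with excluded diagonal) and `lesion_side`.
#' @export
simulate_patient <- function(spec, lesion_side = c("left", "right"), T = 400,
                             pair_sd = NULL, seed = spec$seed + 1) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  lesion_side <- match.arg(lesion_side)
  R <- spec$n_regions
  pa <- spec$planted_anomalies
  default_sd <- sqrt(1 / spec$subject_jitter + 1 / T)
  P <- matrix(0, R, R)
  truth <- matrix("normal", R, R)
  if (nrow(pa)) {
    for (r in seq_len(nrow(pa))) {
      sdij <- if (is.null(pair_sd)) default_sd else pair_sd[pa$i[r], pa$j[r]]
      delta <- (if (pa$direction[r] == "hyper") 1 else -1) * pa$magnitude[r] * sdij
      P[pa$i[r], pa$j[r]] <- P[pa$j[r], pa$i[r]] <- delta
      truth[pa$i[r], pa$j[r]] <- truth[pa$j[r], pa$i[r]] <- pa$direction[r]
    }
  }
  Sigma_p <- tangent_embed(P, spec$base_covariance)
  ev_min <- min(eigen(Sigma_p, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    # unreachable for exp-map perturbations; kept as a defensive contract
    rlang::warn("perturbation broke positive definiteness; halving magnitudes")
    Sigma_p <- tangent_embed(P / 2, spec$base_covariance)
  }
  diag(truth) <- "excluded"
  tags <- region_tags(spec$region_labels)
  dimnames(truth) <- list(tags, tags)
  ts <- with_seed(seed, {
    region_ts(sample_gaussian_ts(Sigma_p, T), spec$region_labels,
              subject_id = "patient")
  })
  truth_am <- structure(
    list(labels = truth, z_values = matrix(NA_real_, R, R),
         region_labels = spec$region_labels, sigma_threshold = NA_real_),
    class = "anomaly_matrix"
  )
  list(ts = ts, truth = truth_am, lesion_side = lesion_side)
}

#' Simulate clustered recovery trajectories for one scale
#'
#' Each subject's 4-timepoint score vector is its planted cluster mean plus
#' iid Gaussian noise, rounded to integers (clinical scales are integer
#' valued) and clipped to the scale's score range.
#'
#' @param spec A [ground_truth_spec()] whose `trajectory_spec` contains the
#'   scale.
#' @param scale Scale name, e.g. `"BI"`.
#' @param scales Scale definition table, see [stroke_scales()].
#' @param seed Seed for this operation; defaults to `spec$seed + 2`.
#' @return List with `scores` (validated wide `score_table`) and
#'   `true_labels` (named integer vector of planted cluster ids).
#' @export
simulate_trajectories <- function(spec, scale, scales = stroke_scales(),
                                  seed = spec$seed + 2) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  tspec <- spec$trajectory_spec[[scale]]
  if (is.null(tspec)) rlang::abort(paste("no trajectory spec for scale", scale))
  def <- scales[scales$scale == scale, ]
  if (nrow(def) != 1) rlang::abort(paste("unknown scale", scale))
  K <- nrow(tspec$means)
  n <- sum(tspec$sizes)
  if (K > n) rlang::abort("more clusters than subjects")
  if (any(tspec$means < def$min_score) || any(tspec$means > def$max_score)) {
    rlang::abort("cluster means must lie within the scale bounds")
  }
  labels <- rep(seq_len(K), times = tspec$sizes)
  ids <- sprintf("p%03d", seq_len(n))
  vals <- with_seed(seed, {
    t(vapply(labels, function(k) {
      v <- tspec$means[k, ] + rnorm(4, 0, tspec$noise_sd)
      pmin(pmax(round(v), def$min_score), def$max_score)
    }, numeric(4)))
  })
  long <- tibble::tibble(
    subject_id = rep(ids, each = 4),
    scale = scale,
    timepoint = rep(timepoint_labels(), times = n),
    value = as.numeric(t(vals))
  )
  list(scores = validate_scores(as.data.frame(long), scales = scales),
       true_labels = stats::setNames(labels, ids))
}

#' Simulate 3-point structural connectivity ratings
#'
#' Integrity (0 = intact, 1 = visibly injured, 2 = absent) and lesion
#' proximity (0 = not adjacent, 1 = adjacent within 1 cm, 2 = inside the
#' fibers) ratings for the corticospinal tract, cortical-subcortical
#' projection fibers and subcortical connections, drawn from
#' cluster-conditional categorical distributions. `association_strength = 0`
#' gives identical distributions across clusters; `1` makes the rating a
#' deterministic function of the cluster.
#'
#' @param true_labels Named integer vector of cluster ids (names = subjects).
#' @param association_strength Mixing weight in `[0, 1]` between a shared base
#'   distribution and a cluster-determined point mass.
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `tract_class`, `integrity`, `proximity`.
#' @export
simulate_structural_ratings <- function(true_labels, association_strength = 0.5,
                                        seed = 1) {
  stopifnot(association_strength >= 0, association_strength <= 1)
  tracts <- c("CST", "cortical_subcortical_projection", "subcortical")
  base <- c(0.5, 0.3, 0.2)
  s <- association_strength
  with_seed(seed, {
    purrr::map_dfr(seq_along(true_labels), function(si) {
      k <- true_labels[si]
      purrr::map_dfr(seq_along(tracts), function(ti) {
        target <- (k - 1 + ti - 1) %% 3      # cluster-and-tract specific level
        probs <- (1 - s) * base
        probs[target + 1] <- probs[target + 1] + s
        tibble::tibble(
          subject_id = names(true_labels)[si],
          tract_class = tracts[ti],
          integrity = sample(0:2, 1, prob = probs),
          proximity = sample(0:2, 1, prob = probs)
        )
      })
    })
  })
}
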