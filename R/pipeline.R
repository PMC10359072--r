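#' Pipeline run configuration
#'
#' Collects paths and analysis parameters for [run_pipeline()]. All fractions
#' must lie in (0, 1); the seed is echoed (with a configuration fingerprint)
#' into every run manifest so a run is a pure function of inputs and
#' configuration.
#'
#' @param normative_dir Directory of normative region time-series files
#'   (`*.tsv`).
#' @param patient_dir Directory of patient time-series files.
#' @param scores_file Long-format clinical score file.
#' @param metadata_file Patient metadata file (delimited; must contain
#'   `subject_id` and `lesion_side`, lowercase enum strings).
#' @param ratings_file Optional structural-rating file (`subject_id`,
#'   `tract_class`, `integrity`, `proximity`).
#' @param out_dir Output run directory.
#' @param lambda Correlation shrinkage weight (default 0.05).
#' @param sigma_threshold Anomaly threshold in SD units (default 3).
#' @param mask_fraction Fraction of highest-variance pairs to exclude
#'   (default 1/3).
#' @param linkage Clustering linkage (default `"ward"`).
#' @param k_range Candidate K values, `NULL` for the default `2:min(10, n-1)`.
#' @param alpha Significance level for gates and post hoc triggers.
#' @param seed Integer seed recorded in outputs.
#' @return List of class `run_config`.
#' @export
run_config <- function(normative_dir, patient_dir, scores_file, metadata_file,
                       ratings_file = NULL, out_dir = "strokeconn_run",
                       lambda = 0.05, sigma_threshold = 3, mask_fraction = 1 / 3,
                       linkage = "ward", k_range = NULL, alpha = 0.05,
                       seed = 1) {
  stopifnot(lambda > 0, lambda < 1, mask_fraction > 0, mask_fraction < 1,
            sigma_threshold > 0, alpha > 0, alpha < 1)
  structure(
    list(normative_dir = normative_dir, patient_dir = patient_dir,
         scores_file = scores_file, metadata_file = metadata_file,
         ratings_file = ratings_file, out_dir = out_dir, lambda = lambda,
         sigma_threshold = sigma_threshold, mask_fraction = mask_fraction,
         linkage = linkage, k_range = k_range, alpha = alpha,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

config_fingerprint <- function(config) {
  fnv1a(paste(deparse(config[sort(names(config))]), collapse = "\n"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full connectome-phenotyping pipeline
#'
#' End-to-end orchestration: fit the normative tangent-space model from the
#' reference cohort, score every patient's anomaly matrix and laterality-split
#' anomaly counts, cluster the recovery trajectories per scale, run the
#' longitudinal Friedman/Dunn battery on the whole cohort, compare anomaly
#' counts and structural ratings between clusters, and write every artifact
#' (model, anomaly matrices, cluster solutions, heatmap tables, statistics
#' report, manifest) into one run directory. Any stage failure aborts with a
#' stage-named error and removes partial outputs. Reruns with the same inputs
#' and configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (dir.exists(out)) rlang::abort(paste("output directory already exists:", out))
  dir.create(out, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out, recursive = TRUE))

  norm_files <- sort(list.files(config$normative_dir, pattern = "\\.tsv$",
                                full.names = TRUE))
  pat_files <- sort(list.files(config$patient_dir, pattern = "\\.tsv$",
                               full.names = TRUE))
  pat_files <- pat_files[!grepl("\\.z\\.tsv$", pat_files)]
  if (!length(norm_files)) rlang::abort("no normative time-series files found")
  if (!length(pat_files)) rlang::abort("no patient time-series files found")

  model <- stage("fit_normative", {
    cohort <- lapply(norm_files, function(f) {
      estimate_connectivity(read_region_ts(f), lambda = config$lambda)
    })
    fit_normative(cohort, sigma_threshold = config$sigma_threshold,
                  mask_fraction = config$mask_fraction)
  })
  write_normative_model(model, file.path(out, "normative"))

  meta <- stage("read_metadata", {
    first <- readLines(config$metadata_file, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    tibble::as_tibble(read.delim(config$metadata_file, sep = sep))
  })
  stopifnot(all(c("subject_id", "lesion_side") %in% names(meta)))

  anomalies <- stage("score_anomalies", {
    dir.create(file.path(out, "anomalies"))
    res <- lapply(pat_files, function(f) {
      ts <- read_region_ts(f)
      side <- meta$lesion_side[match(ts$subject_id, meta$subject_id)]
      if (is.na(side)) rlang::abort(paste("no metadata for patient", ts$subject_id))
      am <- score_anomalies(estimate_connectivity(ts, lambda = config$lambda), model)
      write_anomaly_matrix(am, file.path(out, "anomalies",
                                         paste0(ts$subject_id, ".tsv")))
      counts <- count_anomalies(am, lesion_side = side)
      counts$subject_id <- ts$subject_id
      counts
    })
    dplyr::bind_rows(res)
  })
  write.table(anomalies, file.path(out, "anomaly_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  scores <- stage("read_scores", read_score_table(config$scores_file))
  solutions <- stage("cluster_trajectories", {
    cluster_all_scales(scores, k_range = config$k_range, linkage = config$linkage)
  })
  dir.create(file.path(out, "clusters"))
  for (sc in names(solutions)) {
    write_cluster_solution(solutions[[sc]], file.path(out, "clusters",
                                                      paste0(sc, ".json")))
    write.table(tidy(solutions[[sc]]),
                file.path(out, "clusters", paste0(sc, "_labels.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    traj <- dplyr::left_join(solutions[[sc]]$features, tidy(solutions[[sc]]),
                             by = "subject_id")
    write.table(traj, file.path(out, "clusters", paste0(sc, "_trajectories.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  stats_report <- stage("longitudinal_stats", {
    tp <- timepoint_labels()
    purrr::map_dfr(names(solutions), function(sc) {
      wide <- scores[scores$scale == sc & scores$complete, tp]
      fr <- friedman_w_test(as.matrix(wide))
      fr$scale <- sc
      fr
    })
  })
  dir.create(file.path(out, "stats"), showWarnings = FALSE)
  write.table(stats_report, file.path(out, "stats", "friedman.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  posthoc <- purrr::map_dfr(names(solutions), function(sc) {
    tp <- timepoint_labels()
    wide <- scores[scores$scale == sc & scores$complete, tp]
    ph <- dunn_posthoc_friedman(as.matrix(wide))
    ph$scale <- sc
    ph
  })
  write.table(posthoc, file.path(out, "stats", "dunn_posthoc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cluster_tests <- stage("compare_clusters", {
    purrr::map_dfr(names(solutions), function(sc) {
      lbl <- tidy(solutions[[sc]])
      totals <- anomalies |>
        dplyr::group_by(.data$subject_id, .data$class, .data$laterality) |>
        dplyr::summarise(hypo = sum(.data$hypo_count),
                         hyper = sum(.data$hyper_count), .groups = "drop") |>
        tidyr::pivot_longer(c("hypo", "hyper"), names_to = "direction",
                            values_to = "count") |>
        dplyr::inner_join(lbl, by = "subject_id")
      groups <- dplyr::group_split(totals, .data$class, .data$laterality,
                                   .data$direction)
      m <- length(groups)  # raw and Bonferroni-adjusted p are both reported
      purrr::map_dfr(groups, function(g) {
        if (dplyr::n_distinct(g$cluster) < 2) return(NULL)
        cc <- compare_clusters_numeric(g$count, g$cluster, alpha = config$alpha)
        tibble::tibble(scale = sc, variable = paste(g$class[1], g$laterality[1],
                                                    g$direction[1], sep = "_"),
                       statistic = cc$omnibus$statistic,
                       p_value = cc$omnibus$p_value,
                       p_bonferroni = min(1, cc$omnibus$p_value * m))
      })
    })
  })
  write.table(cluster_tests, file.path(out, "stats", "cluster_comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(config$ratings_file) && file.exists(config$ratings_file)) {
    ratings <- tibble::as_tibble(read.delim(config$ratings_file, sep = ","))
    rating_tests <- purrr::map_dfr(names(solutions), function(sc) {
      lbl <- tidy(solutions[[sc]])
      joined <- dplyr::inner_join(ratings, lbl, by = "subject_id")
      purrr::map_dfr(dplyr::group_split(joined, .data$tract_class), function(g) {
        if (dplyr::n_distinct(g$cluster) < 2) return(NULL)
        purrr::map_dfr(c("integrity", "proximity"), function(v) {
          cc <- compare_clusters_numeric(g[[v]], g$cluster, alpha = config$alpha)
          tibble::tibble(scale = sc, variable = paste(g$tract_class[1], v, sep = "_"),
                         statistic = cc$omnibus$statistic,
                         p_value = cc$omnibus$p_value)
        })
      })
    })
    write.table(rating_tests, file.path(out, "stats", "structural_ratings.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  heat <- stage("render_heatmaps", {
    dir.create(file.path(out, "heatmaps"))
    for (sc in names(solutions)) {
      ht <- render_heatmap_table(anomalies, tidy(solutions[[sc]]))
      write.table(ht, file.path(out, "heatmaps", paste0(sc, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    TRUE
  })

  manifest <- list(
    package = "strokeconn",
    config = config[setdiff(names(config), "k_range")],
    k_range = config$k_range %||% "auto",
    seed = config$seed,
    config_fingerprint = config_fingerprint(config),
    n_normative = length(norm_files),
    n_patients = length(pat_files),
    scales = names(solutions),
    outputs = sort(list.files(out, recursive = TRUE))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(out)
}

#' Per-cluster mean anomaly counts (heatmap table)
#'
#' The tabular form behind the anomaly heatmaps: for every region and
#' laterality, the mean hypo- and hyperconnection counts of the subjects in
#' each cluster. Rows are ordered ipsilesional first, then contralesional
#' (then midline), regions alphabetical within a block.
#'
#' @param counts Row-bound [count_anomalies()] tibbles with a `subject_id`
#'   column (one block per subject).
#' @param labels Tibble with `subject_id` and `cluster` (e.g.
#'   `tidy(cluster_solution)`); every subject in `counts` must be labelled.
#' @return Tibble with `region`, `laterality`, `cluster`, `n_subjects`,
#'   `mean_hypo`, `mean_hyper`.
#' @export
render_heatmap_table <- function(counts, labels) {
  stopifnot(all(c("subject_id", "cluster") %in% names(labels)))
  missing <- setdiff(unique(counts$subject_id), labels$subject_id)
  if (length(missing)) {
    rlang::abort(paste("unlabeled subject(s):", paste(utils::head(missing, 3),
                                                      collapse = ", ")))
  }
  joined <- dplyr::inner_join(tibble::as_tibble(counts), labels, by = "subject_id")
  out <- joined |>
    dplyr::group_by(.data$region, .data$laterality, .data$cluster) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     mean_hypo = mean(.data$hypo_count),
                     mean_hyper = mean(.data$hyper_count), .groups = "drop")
  lat_order <- c("ipsilesional", "contralesional", "midline")
  out$laterality <- factor(out$laterality, levels = lat_order)
  out <- dplyr::arrange(out, .data$laterality, .data$region, .data$cluster)
  out$laterality <- as.character(out$laterality)
  out
}
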