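# Artifact readers/writers. All formats are plain text: tab-separated matrices
# and tables with header rows, JSON for models, solutions and manifests.

write_tsv_matrix <- function(M, path) {
  df <- as.data.frame(M)
  names(df) <- colnames(M) %||% paste0("V", seq_len(ncol(M)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  as.matrix(df)
}

#' Read and write region time-series files
#'
#' T rows by R columns of BOLD samples, tab-separated, with a header row of
#' region labels encoded `hemisphere:class:name`.
#'
#' @param ts A [region_ts()].
#' @param path File path.
#' @param subject_id Subject id to attach on read (default: file stem).
#' @return `read_region_ts()` returns a [region_ts()];
#'   `write_region_ts()` returns `path` invisibly.
#' @export
write_region_ts <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  write_tsv_matrix(ts$data, path)
  invisible(path)
}

#' @rdname write_region_ts
#' @export
read_region_ts <- function(path, subject_id = NULL) {
  M <- read_tsv_matrix(path)
  labels <- parse_region_tags(colnames(M))
  region_ts(M, labels, subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Read a long-format clinical score file
#'
#' Delimited text with header `subject_id,scale,timepoint,value` (comma or
#' tab separated); validated and widened with [validate_scores()].
#'
#' @param path File path.
#' @param scales Scale definitions, see [stroke_scales()].
#' @return A validated `score_table`.
#' @export
read_score_table <- function(path, scales = stroke_scales()) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep)
  validate_scores(df, scales = scales)
}

#' @rdname read_score_table
#' @param scores Long-format score data frame (or a wide `score_table`, which
#'   is first melted back to long form).
#' @export
write_score_table <- function(scores, path) {
  if (inherits(scores, "score_table")) {
    tp <- timepoint_labels()
    scores <- tidyr::pivot_longer(
      dplyr::select(tibble::as_tibble(scores), "subject_id", "scale",
                    dplyr::all_of(tp)),
      cols = dplyr::all_of(tp), names_to = "timepoint", values_to = "value"
    )
    scores <- scores[!is.na(scores$value), ]
  }
  write.table(scores[, c("subject_id", "scale", "timepoint", "value")], path,
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a normative model
#'
#' Serialized as a directory: `model.json` (region labels, reference count,
#' sigma threshold, masked pairs as an i/j list) plus tab-separated matrices
#' `reference.tsv`, `mu.tsv`, `sigma.tsv`.
#'
#' @param model A [fit_normative()] model.
#' @param dir Directory path (created if needed).
#' @return `read_normative_model()` returns a `normative_model`;
#'   `write_normative_model()` returns `dir` invisibly.
#' @export
write_normative_model <- function(model, dir) {
  stopifnot(inherits(model, "normative_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  masked <- which(model$mask & upper.tri(model$mask), arr.ind = TRUE)
  header <- list(
    labels = region_tags(model$labels),
    n_reference = model$n_reference,
    sigma_threshold = model$sigma_threshold,
    mask_fraction = model$mask_fraction,
    mask_pairs = data.frame(i = unname(masked[, 1]), j = unname(masked[, 2]))
  )
  jsonlite::write_json(header, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tsv_matrix(model$reference, file.path(dir, "reference.tsv"))
  write_tsv_matrix(model$mu, file.path(dir, "mu.tsv"))
  write_tsv_matrix(model$sigma, file.path(dir, "sigma.tsv"))
  invisible(dir)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  reference <- read_tsv_matrix(file.path(dir, "reference.tsv"))
  mu <- read_tsv_matrix(file.path(dir, "mu.tsv"))
  sigma <- read_tsv_matrix(file.path(dir, "sigma.tsv"))
  R <- nrow(reference)
  tags <- header$labels
  rownames(reference) <- rownames(mu) <- rownames(sigma) <- tags
  mask <- matrix(FALSE, R, R, dimnames = list(tags, tags))
  mp <- header$mask_pairs
  if (length(mp) && nrow(mp)) {
    for (r in seq_len(nrow(mp))) {
      mask[mp$i[r], mp$j[r]] <- mask[mp$j[r], mp$i[r]] <- TRUE
    }
  }
  structure(
    list(reference = reference, mu = mu, sigma = sigma, mask = mask,
         labels = parse_region_tags(tags),
         n_reference = header$n_reference,
         sigma_threshold = header$sigma_threshold,
         mask_fraction = header$mask_fraction %||% 1 / 3),
    class = "normative_model"
  )
}

#' Read and write anomaly matrices
#'
#' Tab-separated R x R label matrix with entries -1 (hypoconnected), 0
#' (normal), 1 (hyperconnected) and NA (excluded), plus an optional companion
#' `<path>.z.tsv` of tangent z-scores.
#'
#' @param am An [score_anomalies()] result.
#' @param path File path for the label matrix.
#' @param with_z Also write/read the z-score matrix (default `TRUE`).
#' @return `read_anomaly_matrix()` returns an `anomaly_matrix`;
#'   `write_anomaly_matrix()` returns `path` invisibly.
#' @export
write_anomaly_matrix <- function(am, path, with_z = TRUE) {
  stopifnot(inherits(am, "anomaly_matrix"))
  code <- matrix(NA_integer_, nrow(am$labels), ncol(am$labels),
                 dimnames = dimnames(am$labels))
  code[am$labels == "normal"] <- 0L
  code[am$labels == "hypo"] <- -1L
  code[am$labels == "hyper"] <- 1L
  write_tsv_matrix(code, path)
  if (with_z) write_tsv_matrix(am$z_values, paste0(path, ".z.tsv"))
  invisible(path)
}

#' @rdname write_anomaly_matrix
#' @export
read_anomaly_matrix <- function(path, with_z = TRUE) {
  code <- read_tsv_matrix(path)
  labels <- matrix("excluded", nrow(code), ncol(code),
                   dimnames = list(colnames(code), colnames(code)))
  labels[!is.na(code) & code == 0] <- "normal"
  labels[!is.na(code) & code == -1] <- "hypo"
  labels[!is.na(code) & code == 1] <- "hyper"
  zpath <- paste0(path, ".z.tsv")
  z <- if (with_z && file.exists(zpath)) {
    zz <- read_tsv_matrix(zpath)
    rownames(zz) <- colnames(zz)
    zz
  } else {
    matrix(NA_real_, nrow(code), ncol(code))
  }
  structure(
    list(labels = labels, z_values = z,
         region_labels = parse_region_tags(colnames(code)),
         sigma_threshold = NA_real_),
    class = "anomaly_matrix"
  )
}

#' Read and write cluster solutions
#'
#' JSON holding the scale, selected K, silhouette-by-K curve, merge heights
#' and per-subject labels; labels are additionally written as a delimited
#' table next to the JSON by the pipeline.
#'
#' @param sol A [cluster_trajectories()] solution.
#' @param path JSON file path.
#' @return `read_cluster_solution()` returns a list (not a full
#'   `cluster_solution`: the tree is stored as merge heights only);
#'   `write_cluster_solution()` returns `path` invisibly.
#' @export
write_cluster_solution <- function(sol, path) {
  stopifnot(inherits(sol, "cluster_solution"))
  payload <- list(
    scale = sol$scale,
    n = sol$n,
    k_selected = sol$k_selected,
    silhouette_by_k = as.data.frame(sol$silhouette_by_k),
    merge_heights = sol$tree$height,
    labels = as.list(stats::setNames(unname(sol$labels), names(sol$labels)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_solution
#' @export
read_cluster_solution <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
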