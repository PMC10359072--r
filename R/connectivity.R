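# A conn_matrix is a plain numeric matrix carrying a "kind" attribute:
# "correlation" (SPD, unit diagonal) or "tangent" (symmetric, any sign).

conn_matrix <- function(values, kind = c("correlation", "tangent")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, kind = kind, class = c("conn_matrix", class(values)))
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix kind=%s %dx%d>\n", attr(x, "kind"), nrow(x), ncol(x)))
  print(utils::head(unclass_matrix(x)[, seq_len(min(6, ncol(x))), drop = FALSE], 6))
  invisible(x)
}

conn_kind <- function(x) attr(x, "kind") %||% "correlation"

#' A subject's region-by-time BOLD series
#'
#' Container for one subject's T x R matrix of BOLD samples plus the ordered,
#' hemisphere-tagged region labels. Column names of `data` are set to
#' `hemisphere:class:name` and must be unique; label order is fixed across a
#' cohort.
#'
#' @param data Numeric T x R matrix, no missing values.
#' @param labels Tibble with columns `hemisphere` (`"L"`, `"R"` or `"M"` for
#'   midline), `class` (`"cortical"`/`"subcortical"`) and `name`.
#' @param subject_id Identifier string.
#' @return An object of class `region_ts`.
#' @export
region_ts <- function(data, labels, subject_id = "subject") {
  stopifnot(is.matrix(data), is.data.frame(labels))
  if (ncol(data) != nrow(labels)) rlang::abort("one label row per data column required")
  if (ncol(data) < 2) rlang::abort("at least 2 regions required")
  if (anyNA(data)) rlang::abort("time series must not contain missing values")
  stopifnot(all(c("hemisphere", "class", "name") %in% names(labels)))
  tags <- region_tags(labels)
  if (anyDuplicated(tags)) rlang::abort("region labels must be unique")
  colnames(data) <- tags
  structure(list(subject_id = subject_id, data = data, labels = tibble::as_tibble(labels)),
            class = "region_ts")
}

region_tags <- function(labels) paste(labels$hemisphere, labels$class, labels$name, sep = ":")

parse_region_tags <- function(tags) {
  parts <- strsplit(tags, ":", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) rlang::abort(paste("malformed region label:", tags[bad][1]))
  tibble::tibble(
    hemisphere = vapply(parts, `[`, "", 1),
    class = vapply(parts, `[`, "", 2),
    name = vapply(parts, `[`, "", 3)
  )
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts %s: %d timepoints x %d regions>\n",
              x$subject_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Estimate a subject's functional connectivity matrix
#'
#' Sample Pearson correlation of the region time series, shrunk toward the
#' identity: `(1 - lambda) * C + lambda * I`. Shrinkage keeps the estimate
#' positive definite when the scan is short relative to the number of regions
#' (the motivating acquisitions have 128 volumes against 45 regions).
#'
#' @param ts A [region_ts()] or a plain T x R numeric matrix.
#' @param lambda Shrinkage weight in (0, 1); default 0.05.
#' @return A `conn_matrix` of kind `"correlation"` (unit diagonal, SPD).
#' @export
estimate_connectivity <- function(ts, lambda = 0.05) {
  X <- if (inherits(ts, "region_ts")) ts$data else as.matrix(ts)
  if (nrow(X) < 3) rlang::abort("need at least 3 timepoints")
  if (!(lambda > 0 && lambda < 1)) rlang::abort("lambda must be in (0, 1)")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    rlang::abort(paste("zero-variance region:", paste(utils::head(bad, 3), collapse = ", ")))
  }
  C <- stats::cor(X)
  S <- (1 - lambda) * C + lambda * diag(ncol(X))
  dimnames(S) <- dimnames(C)
  conn_matrix(S, "correlation")
}

#' Fit a normative tangent-space connectivity model
#'
#' The reference point is the Fréchet mean of the normative correlation
#' matrices. Every cohort matrix is projected to the tangent space at that
#' reference, and each off-diagonal pair gets a normative mean and standard
#' deviation (denominator n - 1) of its tangent values. The
#' `ceiling(P * mask_fraction)` pairs with the largest normative SD (ties
#' broken by row-major pair order) are excluded from anomaly calls: pairs that
#' vary most across healthy subjects are the most prone to false discovery.
#'
#' @param cohort List of `conn_matrix` correlation matrices (or plain SPD
#'   matrices) of a common size, one per reference subject.
#' @param sigma_threshold Anomaly threshold in normative SDs (default 3).
#' @param mask_fraction Fraction of pairs to exclude (default 1/3).
#' @return An object of class `normative_model` with elements `reference`,
#'   `mu`, `sigma` (R x R symmetric), `mask` (R x R logical, `TRUE` =
#'   excluded), `labels`, `n_reference`, `sigma_threshold`.
#' @export
fit_normative <- function(cohort, sigma_threshold = 3, mask_fraction = 1 / 3) {
  stopifnot(is.list(cohort))
  if (length(cohort) < 2) rlang::abort("need at least 2 reference subjects")
  mats <- lapply(cohort, unclass_matrix)
  R <- nrow(mats[[1]])
  tags <- colnames(mats[[1]])
  reference <- frechet_mean(mats)
  W <- spd_inv_sqrtm(reference)
  tangents <- lapply(mats, function(C) sym_fun(sym_check(W %*% C %*% W), log))

  ut <- upper.tri(matrix(0, R, R))
  tv <- vapply(tangents, function(Tm) Tm[ut], numeric(sum(ut)))  # P x n
  mu_p <- rowMeans(tv)
  sd_p <- apply(tv, 1, stats::sd)

  P <- R * (R - 1) / 2
  n_mask <- ceiling(P * mask_fraction)
  # upper.tri fills column-major; convert ranking to row-major (i, j) order
  idx <- which(ut, arr.ind = TRUE)
  rowmajor <- order(idx[, "row"], idx[, "col"])
  rank_rm <- integer(P); rank_rm[rowmajor] <- seq_len(P)
  masked_p <- rep(FALSE, P)
  masked_p[order(-sd_p, rank_rm)[seq_len(n_mask)]] <- TRUE

  if (any(sd_p[!masked_p] == 0)) {
    rlang::abort("degenerate cohort: zero tangent variance on an unmasked pair")
  }

  to_sym <- function(v, diag_val = 0) {
    M <- matrix(diag_val, R, R, dimnames = list(tags, tags))
    M[ut] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  structure(
    list(
      reference = reference,
      mu = to_sym(mu_p),
      sigma = to_sym(sd_p),
      mask = to_sym(masked_p) > 0,
      labels = if (is.null(tags)) NULL else parse_region_tags(tags),
      n_reference = length(mats),
      sigma_threshold = sigma_threshold,
      mask_fraction = mask_fraction
    ),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model: %d regions, n_reference=%d, threshold=%g SD, %d/%d pairs masked>\n",
    nrow(x$reference), x$n_reference, x$sigma_threshold,
    sum(x$mask[upper.tri(x$mask)]), sum(upper.tri(x$mask))
  ))
  invisible(x)
}

#' Score a patient against the normative model
#'
#' Projects the patient's correlation matrix to the tangent space at the
#' normative reference, z-scores every pair against the normative mean and SD,
#' and labels pairs `"hyper"` if z is strictly above `sigma_threshold`,
#' `"hypo"` if strictly below `-sigma_threshold`, and `"normal"` otherwise
#' (being exactly at the threshold counts as within range). Masked pairs and
#' the diagonal are `"excluded"`.
#'
#' @param patient `conn_matrix` correlation matrix (or plain SPD matrix) of
#'   the model's size.
#' @param model A [fit_normative()] model.
#' @param sigma_threshold Optional override of the model's threshold.
#' @return An object of class `anomaly_matrix`: list with `labels` (R x R
#'   character), `z_values` (R x R numeric, `NA` where excluded's z is
#'   undefined only on the diagonal), and `region_labels`.
#' @export
score_anomalies <- function(patient, model, sigma_threshold = NULL) {
  stopifnot(inherits(model, "normative_model"))
  C <- unclass_matrix(patient)
  R <- nrow(model$reference)
  if (!all(dim(C) == R)) rlang::abort("patient matrix size does not match the model")
  thr <- sigma_threshold %||% model$sigma_threshold
  Tm <- unclass_matrix(tangent_project(C, model$reference))
  z <- (Tm - model$mu) / ifelse(model$sigma > 0, model$sigma, NA)
  diag(z) <- NA
  labels <- matrix("normal", R, R, dimnames = dimnames(model$mu))
  labels[!is.na(z) & z > thr] <- "hyper"
  labels[!is.na(z) & z < -thr] <- "hypo"
  labels[model$mask] <- "excluded"
  diag(labels) <- "excluded"
  structure(
    list(labels = labels, z_values = z, region_labels = model$labels,
         sigma_threshold = thr),
    class = "anomaly_matrix"
  )
}

#' @export
print.anomaly_matrix <- function(x, ...) {
  ut <- upper.tri(x$labels)
  tab <- table(factor(x$labels[ut], levels = c("hypo", "normal", "hyper", "excluded")))
  cat(sprintf("<anomaly_matrix %d regions: %d hypo, %d normal, %d hyper, %d excluded pairs>\n",
              nrow(x$labels), tab["hypo"], tab["normal"], tab["hyper"], tab["excluded"]))
  invisible(x)
}

#' Tidy an anomaly matrix into one row per unordered pair
#'
#' @param x An [score_anomalies()] result.
#' @param ... Unused.
#' @return Tibble with columns `region_a`, `region_b`, `z`, `label`.
#' @method tidy anomaly_matrix
#' @export
tidy.anomaly_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$labels), arr.ind = TRUE)
  tags <- colnames(x$labels)
  tibble::tibble(
    region_a = if (is.null(tags)) ut[, 1] else tags[ut[, 1]],
    region_b = if (is.null(tags)) ut[, 2] else tags[ut[, 2]],
    z = x$z_values[ut],
    label = x$labels[ut]
  )
}

#' Per-region anomaly counts split by laterality
#'
#' Counts, for every region, the unmasked anomalous pairs incident to it
#' (each anomalous pair contributes to both endpoint regions). Regions on the
#' lesion's hemisphere are `ipsilesional`, opposite-hemisphere regions
#' `contralesional`, and midline regions (`"M"` tag) `midline`.
#'
#' @param am An [score_anomalies()] result.
#' @param labels Region label tibble (`hemisphere`, `class`, `name`); defaults
#'   to the labels carried by `am`.
#' @param lesion_side `"left"` or `"right"`.
#' @return Tibble of class `anomaly_counts`: one row per region with
#'   `hypo_count`, `hyper_count`, `any_anomaly` (parcel flag), `laterality`,
#'   `class`.
#' @seealso [anomaly_totals()] for class-by-laterality totals.
#' @export
count_anomalies <- function(am, labels = NULL, lesion_side = c("left", "right")) {
  stopifnot(inherits(am, "anomaly_matrix"))
  lesion_side <- match.arg(lesion_side)
  labels <- labels %||% am$region_labels
  if (is.null(labels)) rlang::abort("region labels are required")
  labels <- tibble::as_tibble(labels)
  R <- nrow(am$labels)
  stopifnot(nrow(labels) == R)
  known <- c("L", "R", "M")
  if (!all(labels$hemisphere %in% known)) {
    rlang::abort(paste("unknown hemisphere tag:",
                       setdiff(unique(labels$hemisphere), known)[1]))
  }
  lesion_tag <- if (lesion_side == "left") "L" else "R"
  lat <- dplyr::case_when(
    labels$hemisphere == "M" ~ "midline",
    labels$hemisphere == lesion_tag ~ "ipsilesional",
    TRUE ~ "contralesional"
  )
  L <- am$labels
  diag(L) <- "excluded"
  hypo <- L == "hypo"
  hyper <- L == "hyper"
  tibble::new_tibble(
    tibble::tibble(
      region = labels$name,
      hemisphere = labels$hemisphere,
      class = labels$class,
      laterality = lat,
      hypo_count = as.integer(rowSums(hypo)),
      hyper_count = as.integer(rowSums(hyper)),
      any_anomaly = rowSums(hypo) + rowSums(hyper) > 0
    ),
    class = "anomaly_counts"
  )
}

#' Class-by-laterality anomaly totals
#'
#' Aggregates [count_anomalies()] output: incident-pair totals and parcel-flag
#' counts (regions with at least one anomaly) per region class and laterality.
#' Both conventions are reported because region-level summaries are sometimes
#' quoted as anomaly counts and sometimes as counts of affected parcels.
#'
#' @param counts An [count_anomalies()] tibble.
#' @return Tibble with `class`, `laterality`, `hypo_incident`,
#'   `hyper_incident`, `hypo_parcels`, `hyper_parcels`, `flagged_parcels`.
#' @export
anomaly_totals <- function(counts) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(counts), .data$class, .data$laterality),
    hypo_incident = sum(.data$hypo_count),
    hyper_incident = sum(.data$hyper_count),
    hypo_parcels = sum(.data$hypo_count > 0),
    hyper_parcels = sum(.data$hyper_count > 0),
    flagged_parcels = sum(.data$any_anomaly),
    .groups = "drop"
  )
}
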