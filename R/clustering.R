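#' Euclidean distances between recovery trajectories
#'
#' Pairwise Euclidean distances between subjects' raw (unstandardized)
#' 4-timepoint score vectors; all four entries share the scale's units, so no
#' per-feature standardization is applied.
#'
#' @param features A validated `score_table` (see [validate_scores()])
#'   restricted to a single scale, or any data frame with `subject_id` and the
#'   four timepoint columns. Incomplete subjects are dropped.
#' @return A `dist` object labelled by subject id.
#' @export
trajectory_distances <- function(features) {
  stopifnot(is.data.frame(features))
  if ("scale" %in% names(features) && length(unique(features$scale)) > 1) {
    rlang::abort("features mix several scales; cluster each scale separately")
  }
  tp <- timepoint_labels()
  stopifnot(all(tp %in% names(features)))
  if ("complete" %in% names(features)) features <- features[features$complete, ]
  features <- features[stats::complete.cases(features[, tp]), ]
  if (nrow(features) < 2) rlang::abort("need at least 2 complete subjects")
  X <- as.matrix(features[, tp])
  rownames(X) <- features$subject_id
  stats::dist(X, method = "euclidean")
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Bottom-up merging with Ward (default, natural with Euclidean distances),
#' average or complete linkage; a thin wrapper around [stats::hclust()]
#' (`ward.D2` operates on unsquared Euclidean distances).
#'
#' @param distances A `dist` object.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return An `hclust` merge tree (n - 1 merges for n subjects).
#' @export
agglomerate <- function(distances, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(distances, "dist"))
  if (attr(distances, "Size") < 2) rlang::abort("need at least 2 subjects")
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  stats::hclust(distances, method = method)
}

#' Mean silhouette of a partition
#'
#' Standard silhouette widths `s(i) = (b - a) / max(a, b)` where `a` is the
#' mean distance of point `i` to its own cluster and `b` the smallest mean
#' distance to another cluster; points in singleton clusters contribute 0.
#'
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @param distances A `dist` object or symmetric distance matrix over the same
#'   points.
#' @return List with `mean` and `widths` (tibble: point, cluster, silhouette).
#' @export
silhouette_score <- function(labels, distances) {
  D <- as.matrix(distances)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2) rlang::abort("silhouette undefined for a single cluster")
  sizes <- table(factor(labels, levels = ks))
  s <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    if (sizes[as.character(own)] == 1) return(0)
    a <- sum(D[i, labels == own]) / (sizes[as.character(own)] - 1)
    b <- min(vapply(ks[ks != own], function(k) mean(D[i, labels == k]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  pts <- rownames(D) %||% as.character(seq_len(n))
  list(mean = mean(s),
       widths = tibble::tibble(point = pts, cluster = labels, silhouette = s))
}

#' Cluster recovery trajectories with silhouette-optimal K
#'
#' Agglomerative hierarchical clustering of the 4-timepoint score vectors for
#' one scale: the tree is cut at every K in `k_range`, the mean silhouette is
#' evaluated on each cut, and the K with the largest mean silhouette is
#' selected (ties go to the smallest K, favouring parsimony). Cluster ids are
#' renumbered 1..K in order of first appearance, so the procedure is fully
#' deterministic.
#'
#' @param features Single-scale score table (see [trajectory_distances()]).
#' @param k_range Candidate cluster counts; default `2:min(10, n - 1)`.
#' @param linkage Linkage criterion, see [agglomerate()].
#' @return An object of class `cluster_solution`: list with `scale`, `tree`,
#'   `k_selected`, `labels` (named integer vector), `silhouette_by_k`
#'   (tibble), `n`, `features`.
#' @examples
#' spec <- ground_truth_spec(n_regions = 4,
#'                           region_labels = default_region_labels(4), seed = 7)
#' sim <- simulate_trajectories(spec, "BI")
#' sol <- cluster_trajectories(sim$scores)
#' glance(sol)
#' @export
cluster_trajectories <- function(features, k_range = NULL,
                                 linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  d <- trajectory_distances(features)
  n <- attr(d, "Size")
  if (n < 3) rlang::abort("need at least 3 complete subjects to select K")
  if (all(d == 0)) rlang::abort("degenerate input: all trajectories identical")
  k_range <- k_range %||% 2:min(10, n - 1)
  stopifnot(all(k_range >= 2), all(k_range <= n))
  tree <- agglomerate(d, linkage)
  sil <- vapply(k_range, function(k) {
    silhouette_score(cutree(tree, k = k), d)$mean
  }, numeric(1))
  k_selected <- k_range[which.max(sil)]   # ties -> smallest K
  labels <- relabel_by_appearance(cutree(tree, k = k_selected))
  tp <- timepoint_labels()
  feats <- tibble::as_tibble(features)
  if ("complete" %in% names(feats)) feats <- feats[feats$complete, ]
  structure(
    list(
      scale = if ("scale" %in% names(feats)) unique(feats$scale) else NA_character_,
      tree = tree,
      k_selected = k_selected,
      labels = labels,
      silhouette_by_k = tibble::tibble(k = k_range, mean_silhouette = sil),
      n = n,
      features = feats[, intersect(c("subject_id", "scale", tp), names(feats))]
    ),
    class = "cluster_solution"
  )
}

relabel_by_appearance <- function(labels) {
  first <- unique(labels)
  out <- match(labels, first)
  names(out) <- names(labels)
  out
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution %s: n=%d, K=%d, mean silhouette %.3f>\n",
              x$scale, x$n, x$k_selected,
              x$silhouette_by_k$mean_silhouette[x$silhouette_by_k$k == x$k_selected]))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @describeIn cluster_trajectories One row per subject with its cluster id.
#' @param x,... A `cluster_solution` and unused arguments, for the `tidy` /
#'   `glance` methods.
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble::tibble(subject_id = names(x$labels), cluster = unname(x$labels))
}

#' @describeIn cluster_trajectories One-row summary (n, K, silhouette).
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(
    scale = x$scale, n = x$n, k_selected = x$k_selected,
    mean_silhouette = x$silhouette_by_k$mean_silhouette[
      x$silhouette_by_k$k == x$k_selected]
  )
}

#' Cluster every scale of a score table separately
#'
#' Scales are clustered independently: pooling heterogeneous scales into one
#' feature matrix degenerates into many near-singleton clusters on small
#' cohorts, so a per-scale solution list is the supported interface.
#'
#' @param score_table Validated multi-scale `score_table`.
#' @inheritParams cluster_trajectories
#' @return Named list of `cluster_solution` objects, one per scale.
#' @export
cluster_all_scales <- function(score_table, k_range = NULL, linkage = "ward") {
  scales <- unique(score_table$scale)
  stats::setNames(
    lapply(scales, function(sc) {
      cluster_trajectories(score_table[score_table$scale == sc, ],
                           k_range = k_range, linkage = linkage)
    }),
    scales
  )
}
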