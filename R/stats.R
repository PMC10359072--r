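#' Friedman test with Kendall's W effect size
#'
#' Repeated-measures comparison across k timepoints for n subjects: within-row
#' average ranks (ties averaged), the tie-corrected Friedman chi-square with
#' k - 1 degrees of freedom (delegated to [stats::friedman.test()]), and
#' Kendall's coefficient of concordance `W = chi2 / (n * (k - 1))`, which is 1
#' under perfect concordance and invariant to monotone transformations of the
#' scores.
#'
#' @param wide Numeric n x k matrix or data frame (rows = subjects, columns =
#'   timepoints), complete cases only.
#' @return One-row tibble of class `friedman_result`: `statistic`, `df`,
#'   `p_value`, `n_subjects`, `k_timepoints`, `kendalls_w`.
#' @examples
#' y <- matrix(c(4, 3, 2, 1, 5, 3, 2, 1, 4, 4, 2, 1), 3, 4, byrow = TRUE)
#' friedman_w_test(y)
#' @export
friedman_w_test <- function(wide) {
  y <- as.matrix(wide)
  if (anyNA(y)) rlang::abort("missing cells are not supported (no imputation)")
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 3) rlang::abort("need at least 2 subjects and 3 timepoints")
  ft <- friedman.test(y)
  chi2 <- unname(ft$statistic)
  if (!is.finite(chi2)) chi2 <- 0   # all rows fully tied
  p <- unname(ft$p.value)
  if (!is.finite(p)) p <- 1
  out <- tibble::tibble(
    statistic = chi2, df = k - 1, p_value = p,
    n_subjects = n, k_timepoints = k,
    kendalls_w = chi2 / (n * (k - 1))
  )
  class(out) <- c("friedman_result", class(out))
  out
}

#' Dunn's post hoc test after Friedman
#'
#' Pairwise comparisons of timepoint mean ranks using the Friedman rank
#' standard error `sqrt(k * (k + 1) / (6 * n))`, two-sided normal p-values and
#' Bonferroni correction over the `k * (k - 1) / 2` pairs.
#'
#' @inheritParams friedman_w_test
#' @param labels Optional column labels for the timepoints.
#' @return Tibble with `level_a`, `level_b`, `z`, `p_raw`, `p_adj`, `method`.
#' @export
dunn_posthoc_friedman <- function(wide, labels = NULL) {
  y <- as.matrix(wide)
  if (anyNA(y)) rlang::abort("missing cells are not supported (no imputation)")
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 3) rlang::abort("need at least 2 subjects and 3 timepoints")
  labels <- labels %||% colnames(y) %||% paste0("t", seq_len(k))
  r <- t(apply(y, 1, rank))
  mean_ranks <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(pi) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    z <- (mean_ranks[a] - mean_ranks[b]) / se
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(level_a = labels[a], level_b = labels[b],
                   z = unname(z), p_raw = p, p_adj = min(1, p * m),
                   method = "dunn_bonferroni")
  })
}

#' Kruskal-Wallis comparison across clusters with Dunn post hoc
#'
#' Tie-corrected Kruskal-Wallis omnibus test of a numeric variable across
#' cluster labels; when the omnibus p-value is at or below `alpha`, Dunn's
#' pairwise z-tests on mean ranks (with the tie-corrected pooled variance and
#' Bonferroni adjustment) are run. The workhorse for comparing anomaly counts
#' and structural ratings between recovery phenotypes.
#'
#' @param values Numeric vector.
#' @param clusters Cluster labels, same length.
#' @param alpha Gate for running the post hoc (default 0.05).
#' @return List of class `cluster_comparison`: `omnibus` (one-row tibble with
#'   `test_used`, `statistic`, `df`, `p_value`) and `posthoc` (tibble, empty
#'   when the gate fails).
#' @export
compare_clusters_numeric <- function(values, clusters, alpha = 0.05) {
  stopifnot(length(values) == length(clusters))
  keep <- !is.na(values) & !is.na(clusters)
  values <- values[keep]; clusters <- as.character(clusters[keep])
  ks <- sort(unique(clusters))
  if (length(ks) < 2) rlang::abort("need at least 2 clusters")
  if (stats::var(values) == 0) {
    kw_stat <- 0; kw_p <- 1; df <- length(ks) - 1
  } else {
    kt <- kruskal.test(values, factor(clusters))
    kw_stat <- unname(kt$statistic); kw_p <- unname(kt$p.value)
    df <- unname(kt$parameter)
  }
  posthoc <- if (kw_p <= alpha) dunn_posthoc_kw(values, clusters) else
    tibble::tibble(level_a = character(), level_b = character(), z = numeric(),
                   p_raw = numeric(), p_adj = numeric(), method = character())
  structure(
    list(
      omnibus = tibble::tibble(test_used = "kruskal_wallis",
                               statistic = kw_stat, df = df, p_value = kw_p,
                               alpha = alpha),
      posthoc = posthoc
    ),
    class = "cluster_comparison"
  )
}

dunn_posthoc_kw <- function(values, clusters) {
  N <- length(values)
  r <- rank(values)
  ks <- sort(unique(clusters))
  mean_ranks <- vapply(ks, function(k) mean(r[clusters == k]), numeric(1))
  ns <- vapply(ks, function(k) sum(clusters == k), numeric(1))
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(length(ks), 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(pi) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[a] + 1 / ns[b]))
    z <- if (se == 0) 0 else (mean_ranks[a] - mean_ranks[b]) / se
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(level_a = ks[a], level_b = ks[b], z = unname(z),
                   p_raw = p, p_adj = min(1, p * m), method = "dunn_bonferroni")
  })
}

#' @export
print.cluster_comparison <- function(x, ...) {
  print(x$omnibus)
  if (nrow(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' Gated two-group comparison of a continuous variable
#'
#' Demographic-table comparison rule: when both groups have at least 3
#' observations, run Shapiro-Wilk normality tests on each group and an F-test
#' of variance homogeneity; if all three p-values exceed `alpha`, compare with
#' an unpaired t-test, otherwise (or when the gate cannot run) with a Wilcoxon
#' rank-sum test. The returned p-value is Bonferroni-multiplied by
#' `bonferroni_m` and capped at 1; the gate decisions are recorded in
#' `gating_trace`.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alpha Gate significance level (default 0.05).
#' @param bonferroni_m Number of simultaneous comparisons (default 1).
#' @return One-row tibble with `test_used`, `statistic`, `p_raw`, `p_value`
#'   (adjusted), plus a `gating_trace` list-column (tibble of gate tests).
#' @export
compare_two_groups_continuous <- function(a, b, alpha = 0.05, bonferroni_m = 1) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) rlang::abort("both groups must be non-empty")
  gate <- NULL
  use_t <- FALSE
  if (length(a) >= 3 && length(b) >= 3) {
    sw <- function(x) {
      if (stats::var(x) == 0 || length(x) > 5000) return(0)  # treat as non-normal
      unname(shapiro.test(x)$p.value)
    }
    p_sw_a <- sw(a); p_sw_b <- sw(b)
    p_var <- if (stats::var(a) == 0 && stats::var(b) == 0) 1 else
      tryCatch(unname(var.test(a, b)$p.value), error = function(e) 0)
    gate <- tibble::tibble(
      gate = c("shapiro_a", "shapiro_b", "var_f"),
      p_value = c(p_sw_a, p_sw_b, p_var)
    )
    use_t <- all(gate$p_value > alpha)
  }
  if (use_t) {
    tt <- t.test(a, b, var.equal = TRUE)
    stat <- unname(tt$statistic); p <- unname(tt$p.value); used <- "t_test"
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    stat <- unname(wt$statistic); p <- unname(wt$p.value); used <- "wilcoxon_rank_sum"
    if (!is.finite(p)) p <- 1
  }
  tibble::tibble(
    test_used = used, statistic = stat, p_raw = p,
    p_value = min(1, p * bonferroni_m),
    gating_trace = list(gate %||% tibble::tibble(gate = character(),
                                                 p_value = numeric()))
  )
}

#' Association test for a two-way contingency table
#'
#' Chooses between the chi-square test with Yates continuity correction (2x2
#' tables with all expected cell counts at least 5) and Fisher's exact test
#' (any expected count below 5). Larger tables use Fisher when it is feasible
#' and fall back to the uncorrected chi-square with a warning otherwise.
#'
#' @param tab Matrix or table of non-negative counts.
#' @return One-row tibble with `test_used`, `statistic` (`NA` for Fisher),
#'   `p_value`, plus a `gating_trace` list-column recording the minimum
#'   expected count.
#' @examples
#' categorical_association(matrix(c(5, 0, 0, 5), 2))  # Fisher, p = 2/252
#' @export
categorical_association <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) rlang::abort("counts must be non-negative")
  if (sum(tab) == 0) rlang::abort("all-zero contingency table")
  expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
  min_exp <- min(expected)
  gate <- tibble::tibble(gate = "min_expected", p_value = NA_real_,
                         value = min_exp)
  if (min_exp < 5) {
    res <- tryCatch(
      fisher.test(tab),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      return(tibble::tibble(test_used = "fisher_exact", statistic = NA_real_,
                            p_value = unname(res$p.value),
                            gating_trace = list(gate)))
    }
    rlang::warn("Fisher's exact test infeasible; using uncorrected chi-square")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(tibble::tibble(test_used = "chi_square", statistic = unname(ct$statistic),
                          p_value = unname(ct$p.value), gating_trace = list(gate)))
  }
  correct <- all(dim(tab) == 2)
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble::tibble(
    test_used = if (correct) "chi_square_yates" else "chi_square",
    statistic = unname(ct$statistic), p_value = unname(ct$p.value),
    gating_trace = list(gate)
  )
}
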