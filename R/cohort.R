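#' Summarize a patient cohort, optionally by group
#'
#' Demographic-table summaries in the style of clinical reports: continuous
#' variables as median (IQR) with quartiles by linear interpolation (type 7),
#' categorical variables as count and percent of non-missing values, percents
#' rounded to the nearest integer (so 10 of 22 prints as "10 (45%)").
#'
#' @param patients Data frame, one row per patient. Columns other than
#'   `subject_id` and the grouping column are summarized: numeric columns as
#'   continuous, everything else as categorical.
#' @param group Optional name of a column holding group labels (e.g. cluster
#'   assignments). Each group is summarized separately, plus an `"all"` column
#'   group covering the full cohort.
#' @param vars Optional character vector restricting which columns to
#'   summarize.
#' @return A tibble with columns `variable`, `level` (`NA` for continuous
#'   variables), `group`, `n`, `median`, `q1`, `q3`, `pct`, `formatted`. Empty
#'   groups yield rows with `n = 0` and `formatted = "-"`.
#' @examples
#' ph <- tibble::tibble(subject_id = sprintf("p%02d", 1:22),
#'                      age = c(64, 56, 68, rep(60, 19)),
#'                      lesion_side = c(rep("right", 15), rep("left", 7)))
#' summarize_cohort(ph)
#' @export
summarize_cohort <- function(patients, group = NULL, vars = NULL) {
  stopifnot(is.data.frame(patients))
  if (nrow(patients) == 0) rlang::abort("empty cohort")
  skip <- c("subject_id", group)
  if (is.null(vars)) vars <- setdiff(names(patients), skip)
  groups <- if (is.null(group)) "all" else c("all", sort(unique(as.character(patients[[group]]))))

  one_group <- function(g) {
    rows <- if (g == "all") patients else patients[as.character(patients[[group]]) == g, , drop = FALSE]
    purrr::map_dfr(vars, function(v) summarize_variable(rows[[v]], v, g))
  }
  out <- purrr::map_dfr(groups, one_group)
  tibble::as_tibble(out)
}

summarize_variable <- function(x, variable, group) {
  if (is.numeric(x)) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble::tibble(variable = variable, level = NA_character_,
                            group = group, n = 0L, median = NA_real_,
                            q1 = NA_real_, q3 = NA_real_, pct = NA_real_,
                            formatted = "-"))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(
      variable = variable, level = NA_character_, group = group,
      n = length(x), median = q[2], q1 = q[1], q3 = q[3], pct = NA_real_,
      formatted = sprintf("%s (%s, %s)", format_num(q[2]), format_num(q[1]), format_num(q[3]))
    )
  } else {
    x <- as.character(x)
    x <- x[!is.na(x)]
    levels <- sort(unique(x))
    if (length(x) == 0) {
      return(tibble::tibble(variable = variable, level = NA_character_,
                            group = group, n = 0L, median = NA_real_,
                            q1 = NA_real_, q3 = NA_real_, pct = NA_real_,
                            formatted = "-"))
    }
    purrr::map_dfr(levels, function(lv) {
      n <- sum(x == lv)
      pct <- round(100 * n / length(x))
      tibble::tibble(
        variable = variable, level = lv, group = group,
        n = n, median = NA_real_, q1 = NA_real_, q3 = NA_real_, pct = pct,
        formatted = sprintf("%d (%d%%)", n, pct)
      )
    })
  }
}

format_num <- function(x) {
  if (abs(x - round(x)) < 1e-9) format(round(x)) else format(round(x, 2))
}
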