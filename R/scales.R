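#' Standardized stroke outcome scales
#'
#' Score ranges and severity directions for the four scales used to track
#' recovery: NIHSS (0-42, higher = more severe), Fugl-Meyer Assessment (FMA,
#' lower = more severe), Barthel Index (BI, 0-100, lower = more dependent) and
#' the Wolf Motor Function Test (WMFT, 0-75, lower = weaker upper-limb
#' function).
#'
#' The FMA maximum is configurable: the full assessment (motor, balance,
#' sensation, joint function) totals 226, but clinical studies often report a
#' motor subscale with a smaller range, and published baselines near 16 are
#' compatible with either. Pass `fma_max` to match the variant actually
#' administered.
#'
#' @param fma_max Maximum FMA total score (default 226, the full assessment).
#' @return A tibble with columns `scale`, `min_score`, `max_score`,
#'   `severity_direction` (`"higher_worse"` or `"lower_worse"`).
#' @examples
#' stroke_scales()
#' @export
stroke_scales <- function(fma_max = 226) {
  stopifnot(is.numeric(fma_max), length(fma_max) == 1, fma_max > 0)
  tibble::tibble(
    scale = c("NIHSS", "FMA", "BI", "WMFT"),
    min_score = c(0, 0, 0, 0),
    max_score = c(42, fma_max, 100, 75),
    severity_direction = c("higher_worse", "lower_worse", "lower_worse", "lower_worse")
  )
}

#' Assessment timepoints
#'
#' The four assessment occasions: admission day (baseline, pre-treatment), then
#' 1, 30 and 90 days after treatment.
#'
#' @return A tibble with columns `ordinal` (1-4) and `label`.
#' @export
timepoints <- function() {
  tibble::tibble(
    ordinal = 1:4,
    label = c("baseline", "day1", "day30", "day90")
  )
}

timepoint_labels <- function() timepoints()$label

#' Validate and widen a long clinical score table
#'
#' Checks a long-format score table (one row per subject, scale and timepoint)
#' against the scale definitions: known scale and timepoint labels, at most one
#' record per (subject, scale, timepoint), and values within the scale's score
#' range. Returns one row per (subject, scale) with the four timepoints as
#' columns; subjects missing any timepoint for a scale are flagged
#' `complete = FALSE` and are skipped by [cluster_trajectories()].
#'
#' The function is idempotent: applied to its own output it returns the same
#' table.
#'
#' @param scores Data frame with columns `subject_id`, `scale`, `timepoint`,
#'   `value` (long format), or a previously validated wide table.
#' @param scales Scale definition table, see [stroke_scales()].
#' @return A tibble of class `score_table` with columns `subject_id`, `scale`,
#'   `baseline`, `day1`, `day30`, `day90`, `complete`.
#' @examples
#' long <- tidyr::crossing(subject_id = c("s1", "s2"), scale = "NIHSS",
#'                         timepoint = timepoints()$label)
#' long$value <- c(12, 10, 6, 4, 20, 18, 15, 11)
#' validate_scores(long)
#' @export
validate_scores <- function(scores, scales = stroke_scales()) {
  stopifnot(is.data.frame(scores))
  tp <- timepoint_labels()
  if (inherits(scores, "score_table") && all(tp %in% names(scores))) {
    # already wide: re-run the range checks and return unchanged
    long <- tidyr::pivot_longer(
      dplyr::select(scores, "subject_id", "scale", dplyr::all_of(tp)),
      cols = dplyr::all_of(tp), names_to = "timepoint", values_to = "value"
    )
    long <- dplyr::filter(long, !is.na(.data$value))
    return(validate_scores(as.data.frame(long), scales = scales))
  }
  need <- c("subject_id", "scale", "timepoint", "value")
  if (!all(need %in% names(scores))) {
    rlang::abort(paste("score table must have columns:", paste(need, collapse = ", ")))
  }
  bad_scale <- setdiff(unique(scores$scale), scales$scale)
  if (length(bad_scale)) {
    rlang::abort(paste("unknown scale(s):", paste(bad_scale, collapse = ", ")))
  }
  bad_tp <- setdiff(unique(scores$timepoint), tp)
  if (length(bad_tp)) {
    rlang::abort(paste("unknown timepoint(s):", paste(bad_tp, collapse = ", ")))
  }
  dup <- dplyr::count(scores, .data$subject_id, .data$scale, .data$timepoint) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    rlang::abort(paste0(
      "duplicate record(s), e.g. subject ", dup$subject_id[1],
      " scale ", dup$scale[1], " timepoint ", dup$timepoint[1]
    ))
  }
  checked <- dplyr::left_join(scores, scales, by = "scale")
  oob <- dplyr::filter(checked, .data$value < .data$min_score | .data$value > .data$max_score)
  if (nrow(oob)) {
    rlang::abort(paste0(
      "score out of range [", oob$min_score[1], ", ", oob$max_score[1], "]: subject ",
      oob$subject_id[1], ", scale ", oob$scale[1], ", timepoint ", oob$timepoint[1],
      ", value ", oob$value[1]
    ))
  }
  wide <- tidyr::pivot_wider(
    scores[, need],
    names_from = "timepoint", values_from = "value"
  )
  for (nm in setdiff(tp, names(wide))) wide[[nm]] <- NA_real_
  wide <- dplyr::select(wide, "subject_id", "scale", dplyr::all_of(tp))
  wide$complete <- stats::complete.cases(wide[, tp])
  wide <- dplyr::arrange(wide, .data$scale, .data$subject_id)
  class(wide) <- c("score_table", class(wide))
  wide
}
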