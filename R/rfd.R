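#' Relative fixation duration per AOI label
#'
#' For each participant x stimulus (or any finer grouping), the relative
#' fixation duration of an AOI label is the summed duration of on-screen
#' fixations falling in cells carrying that label, divided by the
#' participant's total on-screen fixation duration for that stimulus. RFD
#' therefore measures time spent on an area relative to the rest of the
#' screen; off-screen fixations enter neither numerator nor denominator.
#' Every label present in the AOI map gets a row (zero when unvisited), so
#' RFD values sum to 1 whenever any on-screen fixation exists.
#'
#' @param assigned Labeled fixations from [assign_fixations()].
#' @param aoi The `aoi_map` used for assignment (defines the label set), or
#'   a character vector of labels.
#' @param keys Grouping columns; must include participant and stimulus.
#' @param condition Optional named vector `stimulus_id -> condition`
#'   (e.g. `"static"` / `"dynamic"`) copied onto the records.
#' @return A tibble of RFD records: the keys, `condition` (if given),
#'   `aoi_label`, `rfd` and `total_ms`. A participant with zero on-screen
#'   time gets rows with `total_ms = 0` and `rfd = NA`.
#' @export
compute_rfd <- function(assigned, aoi,
                        keys = c("participant_id", "group", "stimulus_id"),
                        condition = NULL) {
  labels <- if (inherits(aoi, "aoi_map")) {
    unique(vapply(aoi$cells, `[[`, character(1), "label"))
  } else {
    unique(as.character(aoi))
  }
  stopifnot(all(c("participant_id", "stimulus_id") %in% keys),
            all(keys %in% names(assigned)))
  on <- assigned[assigned$aoi_label != "off_screen", , drop = FALSE]
  totals <- assigned |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::left_join(
      on |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::summarise(total_ms = sum(.data$duration), .groups = "drop"),
      by = keys
    ) |>
    dplyr::mutate(total_ms = dplyr::coalesce(.data$total_ms, 0))
  per_label <- on |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "aoi_label")))) |>
    dplyr::summarise(label_ms = sum(.data$duration), .groups = "drop")
  grid <- tidyr::crossing(totals, aoi_label = labels)
  out <- grid |>
    dplyr::left_join(per_label, by = c(keys, "aoi_label")) |>
    dplyr::mutate(
      label_ms = dplyr::coalesce(.data$label_ms, 0),
      rfd = dplyr::if_else(.data$total_ms > 0,
                           .data$label_ms / .data$total_ms, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(keys), "aoi_label", "rfd",
                  total_ms = "total_ms") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "aoi_label"))))
  if (!is.null(condition)) {
    out$condition <- unname(condition[out$stimulus_id])
    out <- dplyr::relocate(out, "condition", .after = "stimulus_id")
  }
  out
}

#' Export RFD records as a long-format analysis table
#'
#' One record per row, stable column and row order, missing RFD written as
#' the literal `NA`, so the table drops directly into mixed-model /
#' ANOVA-style group analyses and re-exports are byte-identical.
#'
#' @param records Tibble from [compute_rfd()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
export_long_table <- function(records, path) {
  if (!nrow(records)) stop("export_long_table: no records", call. = FALSE)
  key_cols <- setdiff(names(records), c("rfd", "total_ms"))
  records <- dplyr::arrange(records, dplyr::across(dplyr::all_of(key_cols)))
  readr::write_tsv(records, path, na = "NA")
  invisible(path)
}

#' Descriptive summaries of RFD by group
#'
#' Unweighted mean and n-1 standard deviation of RFD over records within
#' each key combination (missing RFD dropped). Feeds group-level plots and
#' sanity checks; inferential statistics stay downstream.
#'
#' @param records Tibble from [compute_rfd()].
#' @param by Key columns to summarise over.
#' @return Tibble with the keys, `mean_rfd`, `sd_rfd`, `n`.
#' @export
summarize_by_group <- function(records, by = c("group", "aoi_label")) {
  stopifnot(nrow(records) > 0, all(by %in% names(records)))
  records |>
    dplyr::filter(!is.na(.data$rfd)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_rfd = mean(.data$rfd),
      sd_rfd = stats::sd(.data$rfd),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
}
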