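# Cross-modality aggregation, cohort summaries (mean, SE, change from
# baseline), and the coverage / endpoint report bundle.

#' Aggregate per-modality outputs into one record per patient x timepoint
#'
#' Outer-joins activity endpoints, HRV summaries, speech features and
#' coverage counts on `(patient_id, timepoint_id)`. A modality missing for a
#' cell leaves that cell's fields `NA` — never imputed. Duplicate keys within
#' any input are an error.
#'
#' @param grid Expected patient × timepoint grid (`patient_id`,
#'   `timepoint_id`, optionally `week`).
#' @param activity,hrv,speech,coverage Optional per patient × timepoint
#'   tibbles keyed by `patient_id`, `timepoint_id`.
#' @return Tibble with one record per expected cell.
#' @export
aggregate_timepoints <- function(grid, activity = NULL, hrv = NULL,
                                 speech = NULL, coverage = NULL) {
  out <- grid |> distinct(dplyr::pick(dplyr::any_of(
    c("patient_id", "timepoint_id", "week"))))
  for (nm in c("activity", "hrv", "speech", "coverage")) {
    tab <- switch(nm, activity = activity, hrv = hrv, speech = speech,
                  coverage = coverage)
    if (is.null(tab)) next
    if (!all(c("patient_id", "timepoint_id") %in% names(tab))) {
      abort_validation(sprintf("`%s` must be keyed by patient_id, timepoint_id", nm), nm)
    }
    if (anyDuplicated(tab[c("patient_id", "timepoint_id")])) {
      abort(sprintf("key collision in `%s`: duplicate patient x timepoint", nm),
            class = "wearals_validation_error")
    }
    tab <- tab |> select(-dplyr::any_of("week"))
    out <- out |> left_join(tab, by = c("patient_id", "timepoint_id"))
  }
  out
}

#' Cohort summary: per-timepoint mean, SE and change from baseline
#'
#' For each endpoint and timepoint: the number of patients contributing a
#' value, their mean, the standard error (sample SD / sqrt(n); absent when
#' n < 2), and the change from baseline computed on cohort means. A
#' completers-only view restricts to patients with a value at the final
#' timepoint.
#'
#' @param records Record tibble from [aggregate_timepoints()].
#' @param endpoints Character vector of endpoint column names to summarize.
#' @param baseline_timepoint Baseline timepoint id (default the smallest).
#' @param completers_only Restrict to patients present (non-NA for the
#'   endpoint) at the final timepoint.
#' @return Tibble: `endpoint`, `timepoint_id`, `n`, `mean`, `se`,
#'   `change_from_baseline`.
#' @export
summarize_cohort <- function(records, endpoints,
                             baseline_timepoint = min(records$timepoint_id),
                             completers_only = FALSE) {
  present <- intersect(endpoints, names(records))
  dropped <- setdiff(endpoints, present)
  for (e in dropped) warn(paste0("endpoint absent everywhere, omitted: ", e))
  long <- records |>
    select("patient_id", "timepoint_id", dplyr::all_of(present)) |>
    tidyr::pivot_longer(dplyr::all_of(present), names_to = "endpoint",
                        values_to = "value") |>
    filter(!is.na(.data$value))
  if (completers_only) {
    final_tp <- max(records$timepoint_id)
    completers <- long |>
      filter(.data$timepoint_id == final_tp) |>
      distinct(.data$endpoint, .data$patient_id)
    long <- long |> semi_join(completers, by = c("endpoint", "patient_id"))
  }
  out <- long |>
    group_by(.data$endpoint, .data$timepoint_id) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
  base <- out |>
    filter(.data$timepoint_id == baseline_timepoint) |>
    select("endpoint", base_mean = "mean")
  out |>
    left_join(base, by = "endpoint") |>
    mutate(change_from_baseline = .data$mean - .data$base_mean) |>
    select(-"base_mean")
}

#' Per-patient paired change from baseline
#'
#' The companion view to [summarize_cohort()]: each patient's own change from
#' their baseline value, per endpoint and timepoint.
#'
#' @inheritParams summarize_cohort
#' @return Tibble: `endpoint`, `patient_id`, `timepoint_id`, `value`,
#'   `change_from_baseline`.
#' @export
paired_changes <- function(records, endpoints,
                           baseline_timepoint = min(records$timepoint_id)) {
  present <- intersect(endpoints, names(records))
  long <- records |>
    select("patient_id", "timepoint_id", dplyr::all_of(present)) |>
    tidyr::pivot_longer(dplyr::all_of(present), names_to = "endpoint",
                        values_to = "value") |>
    filter(!is.na(.data$value))
  base <- long |>
    filter(.data$timepoint_id == baseline_timepoint) |>
    select("endpoint", "patient_id", base_value = "value")
  long |>
    inner_join(base, by = c("endpoint", "patient_id")) |>
    mutate(change_from_baseline = .data$value - .data$base_value) |>
    select(-"base_value")
}

#' Emit the coverage + endpoint report bundle
#'
#' Writes, to `dir`: the patient × timepoint day-count matrix
#' (`coverage_cells.csv`), the per-timepoint percentage of patients providing
#' any data (`coverage_by_timepoint.csv`), the per-patient sufficient-HRV
#' window percentages (`hrv_sufficiency.csv`, when given), the per-record and
#' cohort endpoint tables (`records.csv`, `cohort_summary.csv`) and a
#' plain-text summary (`report.txt`). Output is deterministic: the same
#' inputs regenerate byte-identical files.
#'
#' @param records Record tibble from [aggregate_timepoints()].
#' @param coverage A `wearals_coverage` from [coverage_matrix()].
#' @param summary Cohort summary from [summarize_cohort()].
#' @param dir Output directory.
#' @param hrv_sufficiency Optional per-patient sufficiency tibble from
#'   [sufficiency_summary()].
#' @return Invisible character vector of files written.
#' @export
report_cohort <- function(records, coverage, summary, dir,
                          hrv_sufficiency = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p, progress = FALSE)
    files <<- c(files, p)
  }
  wr(coverage$cells, "coverage_cells.csv")
  wr(coverage$by_timepoint, "coverage_by_timepoint.csv")
  wr(records, "records.csv")
  wr(summary, "cohort_summary.csv")
  if (!is.null(hrv_sufficiency)) wr(hrv_sufficiency, "hrv_sufficiency.csv")

  txt <- c(
    "Cohort monitoring report",
    "========================",
    sprintf("Patient x timepoint cells expected: %d", coverage$summary$n_cells),
    sprintf("Cells with >= 3 (partial) days of data: %.1f%%",
            100 * coverage$summary$frac_ge_min_days),
    sprintf("Cells with >= 3 full (>= 18 h) days: %.1f%%",
            100 * coverage$summary$frac_ge_min_full_days),
    sprintf("Cells with no data: %.1f%%", 100 * coverage$summary$frac_no_data),
    "",
    "Per-timepoint percentage of patients providing any data:",
    sprintf("  t%02d: %5.1f%% (n=%d)", coverage$by_timepoint$timepoint_id,
            coverage$by_timepoint$pct_patients_with_data,
            coverage$by_timepoint$n_patients)
  )
  p <- file.path(dir, "report.txt")
  writeLines(txt, p)
  files <- c(files, p)
  invisible(files)
}
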