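# ggplot2 visualisations of the main result types.

#' Plot the home-monitoring coverage matrix
#'
#' Patient × timepoint tiles coloured by the number of (partial) days of data
#' captured, with zero-day cells distinguishable at a glance.
#'
#' @param object A `wearals_coverage` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wearals_coverage
#' @export
autoplot.wearals_coverage <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(
    x = factor(.data$timepoint_id), y = .data$patient_id,
    fill = .data$n_partial_days)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_partial_days), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Home-monitoring timepoint", y = "Patient",
                  fill = "Days of data",
                  title = "Days (or partial days) of data per patient and timepoint") +
    ggplot2::theme_minimal()
}

#' Plot a pooled leave-one-patient-out confusion matrix
#'
#' Row-normalised percentages of actual classes, as a heatmap.
#'
#' @param object A `wearals_lopo` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wearals_lopo
#' @export
autoplot.wearals_lopo <- function(object, ...) {
  cm <- object$confusion$counts
  df <- as_tibble(as.table(cm), .name_repair = ~ c("actual", "predicted", "n")) |>
    group_by(.data$actual) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%\n(n=%d)", .data$pct,
                                                    .data$n)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 100)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted class", y = "Actual class", fill = "% of actual",
                  title = "Pooled leave-one-patient-out confusion matrix") +
    ggplot2::theme_minimal()
}

#' Plot per-patient HRV data sufficiency
#'
#' Percentage of 5-min windows with enough retained beat coverage to compute
#' each HRV metric, per patient.
#'
#' @param sufficiency Tibble from [sufficiency_summary()] grouped by
#'   `patient_id`.
#' @return A ggplot.
#' @export
plot_hrv_sufficiency <- function(sufficiency) {
  stopifnot("patient_id" %in% names(sufficiency))
  df <- sufficiency |>
    tidyr::pivot_longer(c("pct_sufficient_rmssd", "pct_sufficient_lfhf"),
                        names_to = "metric", values_to = "pct") |>
    mutate(metric = ifelse(.data$metric == "pct_sufficient_rmssd",
                           "RMSSD", "LF/HF"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient_id, y = .data$pct,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Patient", y = "% windows with sufficient data",
                  fill = "Metric",
                  title = "HRV data sufficiency per patient") +
    ggplot2::theme_minimal()
}

#' Plot the missing-data sensitivity curve
#'
#' Fraction of replicates within the reliability tolerance as a function of
#' retained beat coverage, per metric, with the estimated thresholds marked.
#'
#' @param object A `wearals_sensitivity` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wearals_sensitivity
#' @export
autoplot.wearals_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$retention, y = .data$frac_within_tol,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$thresholds,
                        ggplot2::aes(xintercept = .data$threshold,
                                     colour = .data$metric),
                        linetype = "dashed", na.rm = TRUE) +
    ggplot2::labs(x = "Retention (fraction of window covered by beats)",
                  y = "Fraction of replicates within tolerance",
                  colour = "Metric",
                  title = "HRV metric reliability vs missing data",
                  subtitle = object$criterion) +
    ggplot2::theme_minimal()
}

#' Plot a cohort endpoint trajectory
#'
#' Cohort mean with standard-error ribbon over timepoints for one endpoint.
#'
#' @param summary Tibble from [summarize_cohort()].
#' @param endpoint Endpoint name to plot.
#' @return A ggplot.
#' @export
plot_cohort_trend <- function(summary, endpoint) {
  df <- summary |> filter(.data$endpoint == !!endpoint)
  if (!nrow(df)) abort_validation(paste0("endpoint not in summary: ", endpoint))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint_id, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Timepoint", y = endpoint,
                  title = paste0("Cohort mean (±SE): ", endpoint)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
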