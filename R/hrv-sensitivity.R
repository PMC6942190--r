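# Missing-data sensitivity analysis: how much of a 5-min window is needed
# before RMSSD / LF/HF become unreliable.

#' HRV missing-data sensitivity analysis
#'
#' Starting from complete windows (retention 1), beats are deleted at random
#' down to each retention level in `retention_grid`; the metric is recomputed
#' on the degraded window and compared with the complete-data value. The
#' estimated retention threshold for a metric is the smallest grid retention
#' from which the reliability criterion holds at every higher grid point
#' (default criterion: at least `reliability_prob` of replicates within
#' `rel_tol` relative error). The declared criterion is part of the result, so
#' thresholds are always reported with the rule that produced them.
#'
#' @param windows Window tibble from [window_rr()]; all windows must have
#'   retention 1 (complete data).
#' @param metric `"rmssd"` or `"lfhf"` (or both, the default).
#' @param retention_grid Retention levels to probe (default 0.70–1.00 by 0.01).
#' @param n_reps Replicate deletions per window per level.
#' @param rel_tol Relative-error tolerance of the criterion (default 0.05).
#' @param reliability_prob Required fraction of replicates within tolerance
#'   (default 0.95).
#' @param seed Seed.
#' @return List of class `wearals_sensitivity`: `curve` (tibble metric ×
#'   retention with mean/quantile relative error and `frac_within_tol`),
#'   `thresholds` (tibble metric, threshold), and `criterion`.
#' @export
missingness_sensitivity <- function(windows, metric = c("rmssd", "lfhf"),
                                    retention_grid = seq(0.70, 1.00, by = 0.01),
                                    n_reps = 30, rel_tol = 0.05,
                                    reliability_prob = 0.95, seed = 1) {
  metric <- match.arg(metric, several.ok = TRUE)
  if (any(windows$retention < 1 - 1e-9)) {
    abort_validation("sensitivity analysis requires complete windows (retention 1)",
                     "windows")
  }
  retention_grid <- sort(retention_grid)
  with_seed(seed, {
    recs <- list()
    for (wi in seq_len(nrow(windows))) {
      b <- windows$beats[[wi]]
      ref <- list(
        rmssd = as.numeric(rmssd(b$t_ms, b$rr_ms)),
        lfhf = lf_hf(b$t_ms, b$rr_ms)$lf_hf_ratio
      )
      for (p in retention_grid) {
        for (rep in seq_len(n_reps)) {
          keep <- if (p >= 1) rep(TRUE, nrow(b)) else runif(nrow(b)) < p
          bb <- b[keep, ]
          for (m in metric) {
            val <- if (m == "rmssd") as.numeric(rmssd(bb$t_ms, bb$rr_ms))
                   else lf_hf(bb$t_ms, bb$rr_ms)$lf_hf_ratio
            err <- if (is.na(val) || is.na(ref[[m]]) || ref[[m]] == 0) Inf
                   else abs(val - ref[[m]]) / abs(ref[[m]])
            recs[[length(recs) + 1L]] <-
              tibble(metric = m, retention = p, window = wi, rel_error = err)
          }
        }
      }
    }
    raw <- list_rbind(recs)
    curve <- raw |>
      group_by(.data$metric, .data$retention) |>
      summarise(
        mean_rel_error = mean(.data$rel_error[is.finite(.data$rel_error)]),
        q95_rel_error = quantile(.data$rel_error, 0.95, names = FALSE),
        frac_within_tol = mean(.data$rel_error <= rel_tol),
        .groups = "drop"
      )
    thresholds <- curve |>
      group_by(.data$metric) |>
      group_modify(function(d, key) {
        ok <- d$frac_within_tol >= reliability_prob
        # smallest retention from which the criterion holds onwards
        holds_from <- rev(cumprod(rev(ok))) == 1
        thr <- if (any(holds_from)) min(d$retention[holds_from]) else NA_real_
        tibble(threshold = thr)
      }) |>
      ungroup()
    structure(
      list(curve = curve, thresholds = thresholds,
           criterion = sprintf(">= %.0f%% of replicates within %.0f%% relative error",
                               100 * reliability_prob, 100 * rel_tol)),
      class = "wearals_sensitivity"
    )
  })
}

#' @export
print.wearals_sensitivity <- function(x, ...) {
  cat("<wearals_sensitivity: criterion ", x$criterion, ">\n", sep = "")
  print(as.data.frame(x$thresholds), row.names = FALSE)
  invisible(x)
}
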