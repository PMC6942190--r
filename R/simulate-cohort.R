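# Synthetic longitudinal cohort: monthly home-monitoring periods of ~3 days,
# bout-structured free-living activity with a programmed linear decline,
# per-day adherence, a daily charging gap, and per-timepoint dropout.

#' Simulate patient retention under a per-timepoint dropout hazard
#'
#' Every patient is present at baseline; between consecutive timepoints each
#' remaining patient independently leaves the study with probability
#' `hazard`, so the expected fraction still contributing at timepoint `k` is
#' `(1 - hazard)^(k - 1)`.
#'
#' @param n_patients Number of patients.
#' @param n_timepoints Number of timepoints.
#' @param hazard Per-transition dropout probability.
#' @return Integer vector: each patient's last timepoint with data.
#' @export
simulate_retention <- function(n_patients, n_timepoints, hazard) {
  check_number(hazard, "hazard", 0, 1)
  vapply(seq_len(n_patients), function(i) {
    last <- n_timepoints
    if (hazard > 0 && n_timepoints > 1) {
      fail <- which(runif(n_timepoints - 1) < hazard)
      if (length(fail)) last <- fail[1]
    }
    as.integer(last)
  }, integer(1))
}

# free-living tasks used for home-monitoring days
.freeliving_active <- c("walking", "climbing stairs")
.freeliving_sedentary <- c("sitting", "standing")

# one free-living day of bouts on [0, 86400) s, excluding the charging gap.
# stage_factor scales the daytime active-minute target.
.make_day_schedule <- function(spec, stage_factor, data_until_s = 86400) {
  adh <- spec$adherence_model
  charge0 <- adh$charge_start_hr * 3600
  charge1 <- charge0 + adh$charge_hours * 3600
  day_start <- 6 * 3600
  day_end <- 22 * 3600

  # night lying, split around the charging gap
  nstart <- numeric(0); ndur <- numeric(0)
  for (seg in list(c(0, day_start), c(day_end, 86400))) {
    a <- seg[1]; b <- seg[2]
    if (charge0 < b && charge1 > a) {
      if (charge0 > a) { nstart <- c(nstart, a); ndur <- c(ndur, charge0 - a) }
      if (charge1 < b) { nstart <- c(nstart, charge1); ndur <- c(ndur, b - charge1) }
    } else { nstart <- c(nstart, a); ndur <- c(ndur, b - a) }
  }
  night <- tibble(start_s = nstart, duration_s = ndur, task = "lying down")

  # daytime: active bouts interspersed with sedentary/lying filler
  target_active_s <- 60 * spec$baseline_active_min_per_day * stage_factor *
    runif(1, 0.85, 1.15)
  draw <- pmin(15, pmax(0.5, rgamma(ceiling(target_active_s / 60 / 1.3) + 8,
                                    shape = 2, scale = 1.3))) * 60
  k <- which(cumsum(draw) >= target_active_s)
  act_dur <- draw[seq_len(if (length(k)) k[1] else length(draw))]
  n_act <- length(act_dur)
  span <- day_end - day_start
  if (sum(act_dur) > 0.9 * span) act_dur <- act_dur * 0.9 * span / sum(act_dur)
  filler_total <- span - sum(act_dur)
  w <- rexp(n_act + 1)
  gap_len <- filler_total * w / sum(w)
  # each filler gap split into sedentary-scale bouts by a dirichlet weight
  fill <- vector("list", n_act + 1)
  for (i in seq_len(n_act + 1)) {
    L <- gap_len[i]
    m <- max(1L, round(L / (25 * 60)))
    wd <- rexp(m)
    fill[[i]] <- L * wd / sum(wd)
  }
  n_fill <- lengths(fill)
  fill_task <- sample(c("sitting", "standing", "lying down"), sum(n_fill),
                      replace = TRUE, prob = c(0.60, 0.25, 0.15))
  act_task <- sample(.freeliving_active, n_act, replace = TRUE,
                     prob = c(0.85, 0.15))
  # interleave: fill block i, then active bout i
  dur <- numeric(0); task <- character(0)
  fi <- 0L
  for (i in seq_len(n_act + 1)) {
    idx <- fi + seq_len(n_fill[i]); fi <- fi + n_fill[i]
    dur <- c(dur, fill[[i]]); task <- c(task, fill_task[idx])
    if (i <= n_act) { dur <- c(dur, act_dur[i]); task <- c(task, act_task[i]) }
  }
  day <- tibble(start_s = day_start + cumsum(dur) - dur, duration_s = dur,
                task = task)

  out <- bind_rows(night, day) |> arrange(.data$start_s)
  if (data_until_s < 86400) {
    out <- out |> filter(.data$start_s < data_until_s) |>
      mutate(duration_s = pmin(.data$duration_s, data_until_s - .data$start_s))
  }
  out$class <- map_task_to_class(out$task)
  out
}

#' Simulate a synthetic remote-monitoring cohort
#'
#' Generates a full cohort with known ground truth: per-patient retention
#' (dropout), per-day adherence (full, partial, or missing days), and a
#' bout-level activity schedule for every day with data. Activity declines
#' linearly with study week: at week `w` the daytime active-minute target is
#' `1 - decline_fraction_48wk * w/48` of baseline. The daily charging gap
#' (02:00–04:00 by default) contains no data. Identical `spec` (including its
#' seed) always reproduces the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param detail `"bouts"` (default) generates bout schedules for every day
#'   with data; `"days"` generates only retention/adherence (fast, for
#'   coverage-level studies).
#' @return A list of class `wearals_cohort` with elements `spec`, `patients`
#'   (patient_id, last_timepoint), `manifest` (patient × timepoint grid with
#'   `week` and `present`), `days` (per-day status and data extent), and
#'   `schedule` (ground-truth bout table, when `detail = "bouts"`).
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_patients = 2, n_timepoints = 2, seed = 7))
#' @export
simulate_cohort <- function(spec, detail = c("bouts", "days")) {
  if (!inherits(spec, "cohort_spec")) {
    abort_validation("`spec` must be a cohort_spec() object", "spec")
  }
  detail <- match.arg(detail)
  with_seed(spec$seed, {
    pids <- sprintf("P%02d", seq_len(spec$n_patients))
    last_tp <- simulate_retention(spec$n_patients, spec$n_timepoints,
                                  spec$dropout_hazard)
    patients <- tibble(patient_id = pids, last_timepoint = last_tp)
    weeks <- round((seq_len(spec$n_timepoints) - 1) * 48 /
                     max(1, spec$n_timepoints - 1))
    manifest <- tidyr::expand_grid(patient_id = pids,
                                   timepoint_id = seq_len(spec$n_timepoints)) |>
      left_join(patients, by = "patient_id") |>
      mutate(week = weeks[.data$timepoint_id],
             present = .data$timepoint_id <= .data$last_timepoint) |>
      select("patient_id", "timepoint_id", "week", "present")

    adh <- spec$adherence_model
    study_start <- as.Date("2016-01-04")
    days <- manifest |>
      filter(.data$present) |>
      tidyr::expand_grid(day_index = seq_len(spec$days_per_period)) |>
      mutate(date = study_start + (.data$timepoint_id - 1) * 28 + .data$day_index - 1)
    # adherence draws in a fixed row order for determinism
    u1 <- runif(nrow(days)); u2 <- runif(nrow(days)); u3 <- runif(nrow(days))
    days <- days |>
      mutate(
        status = case_when(
          u1 < adh$wear_prob ~ "full",
          u2 < adh$partial_prob ~ "partial",
          TRUE ~ "absent"
        ),
        data_until_s = case_when(
          .data$status == "full" ~ 86400,
          .data$status == "partial" ~ round(3600 * (1 + 16 * u3)),
          TRUE ~ 0
        )
      ) |>
      select("patient_id", "timepoint_id", "week", "day_index", "date",
             "status", "data_until_s")

    schedule <- NULL
    if (detail == "bouts") {
      with_data <- days |> filter(.data$status != "absent")
      schedule <- lapply(seq_len(nrow(with_data)), function(i) {
        d <- with_data[i, ]
        stage <- 1 - spec$decline_fraction_48wk * d$week / 48
        s <- .make_day_schedule(spec, stage, d$data_until_s)
        s$patient_id <- d$patient_id
        s$timepoint_id <- d$timepoint_id
        s$day_index <- d$day_index
        s$date <- d$date
        s
      }) |>
        list_rbind() |>
        select("patient_id", "timepoint_id", "day_index", "date",
               "start_s", "duration_s", "task", "class")
    }
    structure(
      list(spec = spec, patients = patients, manifest = manifest,
           days = days, schedule = schedule),
      class = "wearals_cohort"
    )
  })
}

#' @export
print.wearals_cohort <- function(x, ...) {
  cat(sprintf("<wearals_cohort: %d patients x %d timepoints, %d day records%s>\n",
              x$spec$n_patients, x$spec$n_timepoints, nrow(x$days),
              if (is.null(x$schedule)) "" else sprintf(", %d bouts", nrow(x$schedule))))
  invisible(x)
}

#' Ground-truth daytime activity summary of a simulated cohort
#'
#' Summarizes the generator's own bout schedule (no classification involved)
#' into per patient × timepoint daytime activity: minutes per class inside the
#' daytime clock window over days with data, and the percentage of daytime
#' wear spent active. This is the reference against which pipeline recovery of
#' the programmed decline is judged.
#'
#' @param cohort A `wearals_cohort` simulated with `detail = "bouts"`.
#' @param daytime Two-element numeric, daytime clock window in hours
#'   (default `c(6, 22)`).
#' @return Tibble: patient_id, timepoint_id, week, daytime minutes by class,
#'   `pct_daytime_active`.
#' @export
cohort_activity_truth <- function(cohort, daytime = c(6, 22)) {
  stopifnot(inherits(cohort, "wearals_cohort"))
  if (is.null(cohort$schedule)) {
    abort_validation("cohort was simulated with detail = \"days\"; bout schedule unavailable",
                     "cohort")
  }
  d0 <- daytime[1] * 3600; d1 <- daytime[2] * 3600
  cohort$schedule |>
    mutate(ov_s = pmax(0, pmin(.data$start_s + .data$duration_s, d1) -
                         pmax(.data$start_s, d0))) |>
    group_by(.data$patient_id, .data$timepoint_id, .data$class) |>
    summarise(minutes = sum(.data$ov_s) / 60, .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "minutes",
                       values_fill = 0) |>
    left_join(distinct(cohort$manifest, .data$patient_id, .data$timepoint_id,
                       .data$week),
              by = c("patient_id", "timepoint_id")) |>
    mutate(
      daytime_wear_min = .data$active + .data$sedentary_not_lying + .data$lying,
      # cells whose only data fall outside the daytime window (e.g. a partial
      # day truncated before 06:00) have no daytime denominator
      pct_daytime_active = ifelse(.data$daytime_wear_min > 0,
                                  100 * .data$active / .data$daytime_wear_min,
                                  NA_real_)
    )
}

#' Expand a day's bout schedule to per-minute ground-truth labels
#'
#' Each calendar minute is labelled with the activity class occupying the
#' majority of it; minutes with under 30 s of scheduled data are unlabelled
#' non-data minutes (e.g. the charging gap).
#'
#' @param day_schedule Bout tibble for one day (`start_s`, `duration_s`,
#'   `class`).
#' @return Tibble with `minute` (0–1439), `class` (NA where no data) and
#'   `wear` (logical, >= 30 s of data in the minute).
#' @export
schedule_minute_labels <- function(day_schedule) {
  classes <- c("active", "sedentary_not_lying", "lying")
  cover <- matrix(0, nrow = 1440, ncol = 3, dimnames = list(NULL, classes))
  for (i in seq_len(nrow(day_schedule))) {
    s <- day_schedule$start_s[i]
    e <- s + day_schedule$duration_s[i]
    cl <- day_schedule$class[i]
    m0 <- floor(s / 60); m1 <- min(1439, floor((e - 1e-9) / 60))
    for (m in m0:m1) {
      ov <- min(e, (m + 1) * 60) - max(s, m * 60)
      cover[m + 1, cl] <- cover[m + 1, cl] + ov
    }
  }
  tot <- rowSums(cover)
  cls <- classes[max.col(cover, ties.method = "first")]
  cls[tot < 30] <- NA_character_
  tibble(minute = 0:1439, class = cls, wear = tot >= 30)
}
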