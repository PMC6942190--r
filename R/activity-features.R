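# Per-epoch feature extraction and the task -> 3-class mapping.

#' Map a reference task to its 3-class activity label
#'
#' Walking, stair climbing and postural transitions are `active`; sitting,
#' standing and the nine-hole peg test (low-intensity movement) are
#' `sedentary_not_lying`; lying down is `lying`.
#'
#' @param task Character vector of task names (see [task_vocabulary()]).
#' @return Character vector of class labels.
#' @export
map_task_to_class <- function(task) {
  unknown <- setdiff(unique(task), .task_vocabulary)
  if (length(unknown)) {
    abort_validation(paste0("unknown task(s): ", paste(unknown, collapse = ", ")),
                     "task")
  }
  dplyr::case_when(
    task %in% c("walking", "climbing stairs") | task %in% .transition_tasks ~ "active",
    task %in% c("sitting", "standing", "nine-hole peg test") ~ "sedentary_not_lying",
    task == "lying down" ~ "lying"
  )
}

#' Activity class labels
#' @return The closed 3-class vocabulary, in canonical order.
#' @export
activity_classes <- function() c("active", "sedentary_not_lying", "lying")

# feature vector for one epoch's samples
.epoch_features <- function(seg, rate_hz) {
  a <- as.matrix(seg[, c("ax_g", "ay_g", "az_g")])
  vm <- sqrt(rowSums(a^2))
  bf <- signal::butter(4, 0.5 / (rate_hz / 2), type = "high")
  vm_hp <- if (nrow(seg) > 24) signal::filtfilt(bf, vm - mean(vm)) else vm - mean(vm)

  # dominant frequency of the gravity-removed magnitude in 0.5-5 Hz
  n <- length(vm_hp)
  sp <- Mod(fft(vm_hp - mean(vm_hp)))[seq_len(floor(n / 2))]^2
  fr <- (seq_len(floor(n / 2)) - 1) * rate_hz / n
  band <- fr >= 0.5 & fr <= 5
  if (any(band) && sum(sp[band]) > 0) {
    k <- which.max(sp[band])
    dom_freq <- fr[band][k]
    dom_share <- sp[band][k] / sum(sp[band])
  } else {
    dom_freq <- NA_real_; dom_share <- NA_real_
  }
  cors <- suppressWarnings(cor(a))
  score <- sum(abs(sqrt(rowSums(.hp_matrix(a, bf)^2)))) * 1000 / rate_hz
  tibble(
    mean_ax = mean(a[, 1]), mean_ay = mean(a[, 2]), mean_az = mean(a[, 3]),
    sd_ax = sd(a[, 1]), sd_ay = sd(a[, 2]), sd_az = sd(a[, 3]),
    vm_mean = mean(vm), vm_sd = sd(vm),
    dom_freq = dom_freq, dom_share = dom_share,
    cor_xy = cors[1, 2], cor_xz = cors[1, 3], cor_yz = cors[2, 3],
    score = score
  )
}

.hp_matrix <- function(a, bf) {
  if (nrow(a) > 24) {
    apply(a, 2, function(x) signal::filtfilt(bf, x - mean(x)))
  } else {
    sweep(a, 2, colMeans(a))
  }
}

#' Extract labelled 1-min epoch features from a reference-task session
#'
#' Cuts each labelled interval into complete epochs (epochs straddling a label
#' boundary, or left incomplete at the end of a label, are discarded) and
#' computes the feature vector per epoch: per-axis means (orientation),
#' per-axis standard deviations, vector-magnitude mean/sd, dominant frequency
#' of the gravity-removed magnitude in the 0.5–5 Hz band and its power share,
#' inter-axis correlations, and the epoch activity score.
#'
#' @param stream Accelerometer tibble.
#' @param labels Label track (`start_ms, end_ms, task`).
#' @param epoch_s Epoch length, seconds (default 60).
#' @param rate_hz Sampling rate; inferred when `NULL`.
#' @return Tibble: one row per complete labelled epoch, with `task`, `class`,
#'   `epoch_start_ms` and the feature columns.
#' @export
extract_features <- function(stream, labels, epoch_s = 60, rate_hz = NULL) {
  rate_hz <- rate_hz %||% infer_rate_hz(stream)
  validate_label_track(labels)
  rows <- list()
  for (i in seq_len(nrow(labels))) {
    l0 <- labels$start_ms[i]; l1 <- labels$end_ms[i]
    n_ep <- floor((l1 - l0) / (epoch_s * 1000))
    if (n_ep < 1) next
    for (k in seq_len(n_ep)) {
      e0 <- l0 + (k - 1) * epoch_s * 1000
      e1 <- e0 + epoch_s * 1000
      seg <- stream |> filter(.data$t_ms >= e0, .data$t_ms < e1)
      if (nrow(seg) < epoch_s * rate_hz * 0.5) next  # mostly-empty epoch
      rows[[length(rows) + 1L]] <- .epoch_features(seg, rate_hz) |>
        mutate(task = labels$task[i], epoch_start_ms = e0)
    }
  }
  if (!length(rows)) {
    abort_validation("no complete labelled epochs in stream", "labels")
  }
  list_rbind(rows) |>
    mutate(class = map_task_to_class(.data$task)) |>
    relocate("task", "class", "epoch_start_ms")
}

.feature_cols <- c("mean_ax", "mean_ay", "mean_az", "sd_ax", "sd_ay", "sd_az",
                   "vm_mean", "vm_sd", "dom_freq", "dom_share",
                   "cor_xy", "cor_xz", "cor_yz", "score")

#' Simulate an in-clinic reference-task corpus for several patients
#'
#' Each synthetic patient performs the full reference-task battery with
#' patient-specific parameter jitter (noise level, step frequency, sensor
#' tilt), and the session is cut into labelled 1-min epoch features. This is
#' the corpus used to train and validate the 3-class activity classifier.
#'
#' @param n_patients Number of patients.
#' @param minutes_per_task Named vector of task minutes; the default battery
#'   gives each patient lying/sitting/standing postures, walking and stair
#'   bouts and the nine-hole peg test.
#' @param noise_range Per-axis noise sd range (g), sampled per patient.
#' @param walk_freq_range Step-frequency range (Hz), sampled per patient.
#' @param tilt_range Sensor-tilt range (degrees), sampled per patient.
#' @param rate_hz Sampling rate.
#' @param seed Seed.
#' @return Feature tibble as from [extract_features()], with `patient_id`.
#' @export
simulate_reference_corpus <- function(n_patients = 24,
                                      minutes_per_task = c(
                                        "lying down" = 4, "sitting" = 4,
                                        "standing" = 3, "nine-hole peg test" = 2,
                                        "walking" = 4, "climbing stairs" = 3),
                                      noise_range = c(0.01, 0.03),
                                      walk_freq_range = c(1.8, 2.2),
                                      tilt_range = c(-8, 8),
                                      rate_hz = 50, seed = 1) {
  with_seed(seed, {
    out <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      noise <- runif(1, noise_range[1], noise_range[2])
      wf <- runif(1, walk_freq_range[1], walk_freq_range[2])
      tilt <- runif(1, tilt_range[1], tilt_range[2])
      bouts <- tibble(task = names(minutes_per_task),
                      duration_s = 60 * unname(minutes_per_task))
      # transitions between posture blocks, as performed in clinic
      bouts <- bind_rows(
        bouts[1, ],
        tibble(task = "lying to stand", duration_s = 3),
        bouts[-1, ],
        tibble(task = "sit to stand", duration_s = 3)
      )
      ses <- simulate_task_session(bouts, rate_hz = rate_hz, noise_sd_g = noise,
                                   walk_freq_hz = wf, tilt_deg = tilt)
      out[[p]] <- extract_features(ses$stream, ses$labels, rate_hz = rate_hz) |>
        mutate(patient_id = sprintf("P%02d", p))
    }
    list_rbind(out) |> relocate("patient_id")
  })
}
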