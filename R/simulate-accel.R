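# Reference-task vocabulary and accelerometer bout synthesis.
#
# Device frame (chest-worn): ax = lateral, ay = longitudinal (head-to-foot),
# az = anterior-posterior. Upright postures put gravity on ay; lying supine
# puts it on az.

.task_vocabulary <- c(
  "sitting", "standing", "lying down", "walking", "climbing stairs",
  "sit to stand", "stand to sit", "stand to lying", "lying to stand",
  "nine-hole peg test"
)

.transition_tasks <- c("sit to stand", "stand to sit", "stand to lying",
                       "lying to stand")

#' Reference-task vocabulary
#'
#' The in-clinic reference tasks supported by the bout simulator and the
#' task-to-class mapping: postures, gait tasks, postural transitions and the
#' nine-hole peg test of manual dexterity.
#'
#' @return Character vector of task names.
#' @export
task_vocabulary <- function() .task_vocabulary

check_task <- function(task) {
  if (!is.character(task) || length(task) != 1L || !task %in% .task_vocabulary) {
    abort_validation(
      paste0("unknown task ", deparse(task), "; supported tasks: ",
             paste(.task_vocabulary, collapse = ", ")),
      field = "task"
    )
  }
  invisible(task)
}

# unit gravity vector for a posture, optionally tilted by a few degrees
.posture_gravity <- function(posture, tilt_deg = 0, tilt_axis = c(1, 0, 0)) {
  g <- switch(posture,
    upright = c(0, 1, 0),
    supine  = c(0, 0, 1)
  )
  if (tilt_deg != 0) {
    th <- tilt_deg * pi / 180
    k <- tilt_axis / sqrt(sum(tilt_axis^2))
    # Rodrigues rotation
    g <- g * cos(th) + pracma_cross(k, g) * sin(th) + k * sum(k * g) * (1 - cos(th))
  }
  g
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Simulate one accelerometer bout for a reference task
#'
#' Generates a tri-axial acceleration stream (in g) for a single labelled
#' task bout. Static postures produce the gravity vector for that posture plus
#' noise (vector magnitude about 1 g); walking and stair climbing add a
#' periodic gait component (step frequency around 1.8–2.2 Hz for walking,
#' larger vertical amplitude for stairs); postural transitions ramp the
#' orientation smoothly between postures over the bout.
#'
#' @param task Task name; see [task_vocabulary()].
#' @param duration_s Bout duration in seconds.
#' @param rate_hz Sampling rate, Hz (default 50).
#' @param noise_sd_g Per-axis white-noise standard deviation, g.
#' @param walk_freq_hz Step frequency for gait tasks, Hz.
#' @param tilt_deg Constant postural tilt away from the nominal gravity axis,
#'   degrees (models inter-patient sensor placement variation).
#' @param seed Optional seed; when `NULL` the bout draws from the current RNG
#'   stream.
#' @return Tibble with columns `t_ms`, `ax_g`, `ay_g`, `az_g`, `task`.
#' @examples
#' b <- simulate_accel_bout("walking", 10, seed = 1)
#' head(b)
#' @export
simulate_accel_bout <- function(task, duration_s, rate_hz = 50,
                                noise_sd_g = 0.02, walk_freq_hz = 2.0,
                                tilt_deg = 0, seed = NULL) {
  check_task(task)
  check_number(duration_s, "duration_s", 1e-9)
  check_number(rate_hz, "rate_hz", 1e-9)
  check_number(noise_sd_g, "noise_sd_g", 0)
  with_seed(seed, {
    n <- max(1L, floor(duration_s * rate_hz))
    t_s <- (seq_len(n) - 1) / rate_hz
    base <- matrix(0, n, 3)

    static_posture <- switch(task,
      "sitting" = , "standing" = , "nine-hole peg test" = "upright",
      "lying down" = "supine",
      NULL
    )
    if (!is.null(static_posture)) {
      g <- .posture_gravity(static_posture, tilt_deg)
      base <- matrix(g, n, 3, byrow = TRUE)
      if (task == "nine-hole peg test" && noise_sd_g > 0) {
        # low-intensity arm movement: slow, small-amplitude wobble
        f <- runif(1, 0.5, 1.2)
        base[, 1] <- base[, 1] + 0.015 * sin(2 * pi * f * t_s + runif(1, 0, 2 * pi))
        base[, 3] <- base[, 3] + 0.015 * sin(2 * pi * 0.8 * f * t_s + runif(1, 0, 2 * pi))
      }
    } else if (task %in% c("walking", "climbing stairs")) {
      g <- .posture_gravity("upright", tilt_deg)
      amp <- if (task == "walking") 0.15 else 0.28
      f <- walk_freq_hz * if (task == "climbing stairs") 0.9 else 1
      ph <- runif(3, 0, 2 * pi)
      base <- matrix(g, n, 3, byrow = TRUE)
      base[, 2] <- base[, 2] + amp * sin(2 * pi * f * t_s + ph[1]) +
        0.3 * amp * sin(2 * pi * 2 * f * t_s + ph[2])
      base[, 3] <- base[, 3] + 0.45 * amp * sin(2 * pi * f * t_s + ph[3])
      base[, 1] <- base[, 1] + 0.25 * amp * sin(2 * pi * f / 2 * t_s + ph[1] / 2)
    } else if (task %in% .transition_tasks) {
      from <- if (startsWith(task, "lying")) "supine" else "upright"
      to <- if (endsWith(task, "lying")) "supine" else
        if (task == "stand to sit" || task == "sit to stand") "upright" else "upright"
      if (task == "stand to lying") { from <- "upright"; to <- "supine" }
      if (task == "lying to stand") { from <- "supine"; to <- "upright" }
      if (task %in% c("sit to stand", "stand to sit")) {
        # same end postures; model a forward pitch excursion mid-transition
        from <- "upright"; to <- "upright"
      }
      g0 <- .posture_gravity(from, tilt_deg)
      g1 <- .posture_gravity(to, tilt_deg)
      w <- (1 - cos(pi * t_s / duration_s)) / 2  # smooth 0 -> 1 ramp
      base <- outer(1 - w, g0) + outer(w, g1)
      # movement burst during the ramp
      burst <- 0.12 * sin(pi * t_s / duration_s)
      base[, 2] <- base[, 2] + burst * sin(2 * pi * 1.5 * t_s)
      base[, 3] <- base[, 3] + if (identical(g0, g1))
        0.5 * sin(pi * t_s / duration_s) else 0  # pitch excursion for sit<->stand
    }

    if (noise_sd_g > 0) base <- base + matrix(rnorm(3 * n, 0, noise_sd_g), n, 3)
    tibble(
      t_ms = round((t_s) * 1000),
      ax_g = base[, 1], ay_g = base[, 2], az_g = base[, 3],
      task = task
    )
  })
}

#' Concatenate labelled bouts into a session stream with a label track
#'
#' Utility joining a list of bout descriptions into one continuous
#' accelerometer stream plus the matching label track, as produced by an
#' in-clinic reference-task session.
#'
#' @param bouts Tibble with columns `task` and `duration_s` (one row per bout,
#'   performed back to back).
#' @param rate_hz Sampling rate, Hz.
#' @param noise_sd_g Per-axis noise sd, g.
#' @param walk_freq_hz Step frequency for gait tasks.
#' @param tilt_deg Postural tilt, degrees.
#' @param seed Optional seed.
#' @return List with `stream` (tibble `t_ms, ax_g, ay_g, az_g`) and `labels`
#'   (tibble `start_ms, end_ms, task`).
#' @export
simulate_task_session <- function(bouts, rate_hz = 50, noise_sd_g = 0.02,
                                  walk_freq_hz = 2.0, tilt_deg = 0,
                                  seed = NULL) {
  stopifnot(is.data.frame(bouts), all(c("task", "duration_s") %in% names(bouts)))
  with_seed(seed, {
    offset <- 0
    streams <- vector("list", nrow(bouts))
    labels <- vector("list", nrow(bouts))
    for (i in seq_len(nrow(bouts))) {
      b <- simulate_accel_bout(bouts$task[i], bouts$duration_s[i],
                               rate_hz = rate_hz, noise_sd_g = noise_sd_g,
                               walk_freq_hz = walk_freq_hz, tilt_deg = tilt_deg)
      b$t_ms <- b$t_ms + offset
      labels[[i]] <- tibble(start_ms = offset,
                            end_ms = offset + round(bouts$duration_s[i] * 1000),
                            task = bouts$task[i])
      offset <- offset + round(bouts$duration_s[i] * 1000)
      streams[[i]] <- b[, c("t_ms", "ax_g", "ay_g", "az_g")]
    }
    list(stream = list_rbind(streams), labels = list_rbind(labels))
  })
}
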