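test_that("accelerometer sessions round-trip exactly and reject bad files", {
  s <- tibble::tibble(t_ms = c(0, 20, 40), ax_g = c(0.1, -0.2, 0),
                      ay_g = c(1, 1.01, 0.99), az_g = c(0, 0.02, -0.01))
  p <- withr::local_tempfile(fileext = ".csv")
  write_accel_session(s, p)
  expect_equal(read_accel_session(p), s)

  # non-monotone timestamp cited with its line number (line 5 = 4th sample)
  bad <- tibble::tibble(t_ms = c(0, 20, 40, 30, 60), ax_g = 0, ay_g = 1, az_g = 0)
  pb <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, pb)
  expect_error(read_accel_session(pb), "line 5", class = "wearals_format_error")

  # missing column -> schema error
  pm <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad[, c("t_ms", "ax_g", "ay_g")], pm)
  expect_error(read_accel_session(pm), "missing column",
               class = "wearals_format_error")

  # 60-s 50 Hz session reads back with 3000 samples
  big <- simulate_accel_bout("sitting", 60, rate_hz = 50, seed = 1)
  pl <- withr::local_tempfile(fileext = ".csv")
  write_accel_session(big, pl)
  expect_equal(nrow(read_accel_session(pl)), 3000)
})

test_that("RR sessions round-trip and validate intervals", {
  rr <- tibble::tibble(t_ms = cumsum(rep(800, 10)), rr_ms = 800)
  p <- withr::local_tempfile(fileext = ".csv")
  write_rr_series(rr, p)
  back <- read_rr_series(p)
  expect_equal(back, rr)
  expect_true(all(diff(back$t_ms) == 800))

  bad <- tibble::tibble(t_ms = c(800, 1600), rr_ms = c(800, 0))
  pb <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, pb)
  expect_error(read_rr_series(pb), "rr_ms", class = "wearals_format_error")
})

test_that("label tracks reject overlap and inverted intervals", {
  lab <- tibble::tibble(start_ms = c(0, 60000), end_ms = c(60000, 120000),
                        task = c("sitting", "walking"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_label_track(lab, p)
  expect_equal(read_label_track(p), lab)
  expect_error(
    write_label_track(tibble::tibble(start_ms = 10, end_ms = 5, task = "x"), p),
    "exceed start"
  )
  expect_error(
    write_label_track(tibble::tibble(start_ms = c(0, 50), end_ms = c(100, 150),
                                     task = "sitting"), p),
    "overlap"
  )
})

test_that("session readers and writers fuzz round-trip", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    s <- tibble::tibble(
      t_ms = cumsum(sample(1:50, n, replace = TRUE)),
      ax_g = round(runif(n, -2, 2), 6),
      ay_g = round(runif(n, -2, 2), 6),
      az_g = round(runif(n, -2, 2), 6)
    )
    p <- tempfile(fileext = ".csv")
    write_accel_session(s, p)
    expect_equal(read_accel_session(p), s)
    unlink(p)
  }
})

test_that("WAV audio round-trips within 16-bit quantization", {
  a <- synthesize_speech("AH_SUSTAINED", voice_params(sample_rate_hz = 8000),
                         sustain_s = 1, seed = 1)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(a, p)
  b <- read_wav(p)
  expect_equal(b$sample_rate_hz, 8000)
  expect_equal(length(b$samples), length(a$samples))
  expect_lt(max(abs(b$samples - a$samples)), 1 / 32000)
  expect_error(read_wav(withr::local_tempfile()), class = "wearals_io_error")
})

test_that("manifest indexing is explicit about missing cells and strict about files", {
  spec <- cohort_spec(n_patients = 2, n_timepoints = 2, days_per_period = 1,
                      dropout_hazard = 0, accel_rate_hz = 2,
                      adherence_model = list(wear_prob = 1), seed = 31)
  coh <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort_dataset(coh, dir)
  ds <- load_manifest(file.path(dir, "manifest.json"))
  expect_equal(nrow(ds$grid), 4)
  expect_true(all(ds$grid$has_data))

  # drop one cell's sessions: indexed as missing, not an error
  m <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  keep <- !(m$sessions$patient_id == "P02" & m$sessions$timepoint_id == 2)
  m$sessions <- m$sessions[keep, ]
  p2 <- file.path(dir, "manifest2.json")
  jsonlite::write_json(m, p2, auto_unbox = TRUE, digits = NA)
  ds2 <- load_manifest(p2)
  expect_equal(sum(!ds2$grid$has_data), 1)

  # dangling file reference names the path
  m3 <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  m3$sessions$file[1] <- "sessions/nothere.csv"
  p3 <- file.path(dir, "manifest3.json")
  jsonlite::write_json(m3, p3, auto_unbox = TRUE, digits = NA)
  expect_error(load_manifest(p3), "nothere", class = "wearals_io_error")

  # duplicate session id is an error
  m4 <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  m4$sessions$session_id[2] <- m4$sessions$session_id[1]
  p4 <- file.path(dir, "manifest4.json")
  jsonlite::write_json(m4, p4, auto_unbox = TRUE, digits = NA)
  expect_error(load_manifest(p4), "duplicate", class = "wearals_format_error")
})
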