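make_wear_stream <- function(hours, rate_hz = 2, start_s = 0, noise = 0.05) {
  n <- round(hours * 3600 * rate_hz)
  t_s <- start_s + (seq_len(n) - 1) / rate_hz
  tibble::tibble(t_ms = round(t_s * 1000),
                 ax_g = rnorm(n, 0, noise), ay_g = 1 + rnorm(n, 0, noise),
                 az_g = rnorm(n, 0, noise))
}

test_that("nonwear detection flags recording gaps and still runs", {
  set.seed(1)
  # 24-h wear with a 2-h sample gap -> one nonwear interval of 120 min
  a <- make_wear_stream(2)
  b <- make_wear_stream(20, start_s = 4 * 3600)
  nw <- detect_nonwear(dplyr::bind_rows(a, b))
  expect_equal(nrow(nw), 1)
  expect_equal(nw$kind, "gap")
  expect_equal((nw$end_ms - nw$start_ms) / 60000, 120, tolerance = 0.01)

  # continuous noisy wear (sd 10x threshold): zero intervals
  noisy <- make_wear_stream(4, noise = 0.04)
  expect_equal(nrow(detect_nonwear(noisy, still_sd_g = 0.004)), 0)

  # constructed 40-min zero-variance block flagged exactly
  set.seed(2)
  w1 <- make_wear_stream(1)
  still <- tibble::tibble(t_ms = seq(3600 * 1000, (3600 + 40 * 60) * 1000 - 500,
                                     by = 500),
                          ax_g = 0, ay_g = 1, az_g = 0)
  w2 <- make_wear_stream(1, start_s = 3600 + 40 * 60)
  nw2 <- detect_nonwear(dplyr::bind_rows(w1, still, w2), min_gap_min = 30)
  expect_equal(nrow(nw2), 1)
  expect_equal(nw2$kind, "still")
  expect_equal(nw2$start_ms, 3600 * 1000)
  expect_equal((nw2$end_ms - nw2$start_ms) / 60000, 40)
})

test_that("day summaries implement the 18-hour validity rule exactly", {
  set.seed(3)
  # full-day wear minus the 2-h charging gap: 1320 wear minutes, valid
  a <- make_wear_stream(2)
  b <- make_wear_stream(20, start_s = 4 * 3600)
  stream <- dplyr::bind_rows(a, b)
  nw <- detect_nonwear(stream)
  d <- summarize_days(stream, nw, "2020-06-01T00:00:00")
  expect_equal(nrow(d), 1)
  expect_equal(d$wear_minutes, 1320)
  expect_equal(d$nonwear_minutes, 120)
  expect_true(d$valid_day)
  expect_true(d$partial_day)

  # 17 h wear: not valid, but partial
  s17 <- make_wear_stream(17)
  d17 <- summarize_days(s17, detect_nonwear(s17), "2020-06-01T00:00:00")
  expect_equal(d17$wear_minutes, 1020)
  expect_false(d17$valid_day)
  expect_true(d17$partial_day)

  # a spanned day with no samples: wear 0, partial FALSE
  two <- dplyr::bind_rows(
    make_wear_stream(1),
    make_wear_stream(1, start_s = 2 * 86400)
  )
  d3 <- summarize_days(two, detect_nonwear(two), "2020-06-01T00:00:00")
  mid <- d3[d3$calendar_day == as.Date("2020-06-02"), ]
  expect_equal(mid$wear_minutes, 0)
  expect_false(mid$partial_day)
})

test_that("every calendar day partitions into wear + nonwear + nodata = 1440", {
  set.seed(4)
  for (i in 1:5) {
    pieces <- list(make_wear_stream(runif(1, 1, 6)))
    off <- tail(pieces[[1]]$t_ms, 1) / 1000 + runif(1, 100, 7200)
    pieces[[2]] <- make_wear_stream(runif(1, 1, 10), start_s = off)
    stream <- dplyr::bind_rows(pieces)
    d <- summarize_days(stream, detect_nonwear(stream), "2020-06-01T03:12:00")
    expect_true(all(d$wear_minutes + d$nonwear_minutes + d$nodata_minutes == 1440))
  }
})

test_that("enlarging a nonwear interval never increases wear minutes", {
  set.seed(5)
  stream <- make_wear_stream(20)
  nw <- tibble::tibble(start_ms = 3600000, end_ms = 2 * 3600000, kind = "still")
  base <- summarize_days(stream, nw, "2020-06-01T00:00:00")$wear_minutes
  for (grow_h in c(0.5, 1, 3)) {
    nw2 <- tibble::tibble(start_ms = 3600000,
                          end_ms = (2 + grow_h) * 3600000, kind = "still")
    expect_lte(summarize_days(stream, nw2, "2020-06-01T00:00:00")$wear_minutes,
               base)
    base <- summarize_days(stream, nw2, "2020-06-01T00:00:00")$wear_minutes
  }
})

test_that("coverage matrix counts cells and reproduces the binomial oracle", {
  # 4 cells of which 3 have >= 3 days -> fraction 0.75
  cells <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = 6),
    timepoint_id = rep(rep(1:2, each = 3), 2),
    status = c(rep("full", 3), rep("full", 3),
               rep("full", 3), c("full", "absent", "absent"))
  )
  grid <- tidyr::expand_grid(patient_id = c("A", "B"), timepoint_id = 1:2)
  cov <- coverage_matrix(cells, grid)
  expect_equal(cov$summary$frac_ge_min_days, 0.75)
  expect_equal(cov$summary$frac_no_data, 0)

  # all cells empty -> no-data fraction 1
  cov0 <- coverage_matrix(cells |> dplyr::mutate(status = "absent"), grid)
  expect_equal(cov0$summary$frac_no_data, 1)

  # binomial oracle: P(3 full days) = wear_prob^3 over many cells
  spec <- cohort_spec(n_patients = 100, n_timepoints = 100, dropout_hazard = 0,
                      adherence_model = list(wear_prob = 0.9, partial_prob = 0),
                      seed = 77)
  coh <- simulate_cohort(spec, detail = "days")
  cov3 <- coverage_matrix(coh$days, coh$manifest)
  n <- nrow(cov3$cells)
  expect_equal(n, 10000)
  p3 <- 0.9^3
  expect_lt(abs(cov3$summary$frac_ge_min_full_days - p3),
            4 * sqrt(p3 * (1 - p3) / n) + 1e-3)
})
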