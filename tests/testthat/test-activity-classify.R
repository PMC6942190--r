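test_that("task-to-class mapping covers the reference vocabulary", {
  expect_equal(map_task_to_class("walking"), "active")
  expect_equal(map_task_to_class("climbing stairs"), "active")
  expect_equal(map_task_to_class("sit to stand"), "active")
  expect_equal(map_task_to_class("lying down"), "lying")
  expect_equal(map_task_to_class("nine-hole peg test"), "sedentary_not_lying")
  expect_equal(map_task_to_class("standing"), "sedentary_not_lying")
  expect_error(map_task_to_class("swimming"), "unknown task")
})

test_that("feature extraction honours the complete-epoch boundary rule", {
  ses <- simulate_task_session(
    tibble::tibble(task = c("walking", "sitting"), duration_s = c(600, 90)),
    seed = 1
  )
  f <- extract_features(ses$stream, ses$labels)
  expect_equal(sum(f$task == "walking"), 10)   # 10-min label -> 10 epochs
  expect_equal(sum(f$task == "sitting"), 1)    # 90 s -> second minute dropped
  # zero-noise lying: per-axis std features are exactly 0
  ly <- simulate_task_session(
    tibble::tibble(task = "lying down", duration_s = 120),
    noise_sd_g = 0, seed = 2
  )
  fl <- extract_features(ly$stream, ly$labels)
  expect_true(all(fl$sd_ax == 0 & fl$sd_ay == 0 & fl$sd_az == 0))
})

test_that("classifier is exact on separable data and survives serialization", {
  corpus <- simulate_reference_corpus(n_patients = 4, seed = 5)
  fit <- train_classifier(corpus)
  expect_equal(mean(predict(fit, corpus) == corpus$class), 1)

  p <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, p)
  fit2 <- readRDS(p)
  expect_identical(predict(fit2, corpus), predict(fit, corpus))

  # missing class -> error listing the absent class
  expect_error(train_classifier(dplyr::filter(corpus, class != "lying")),
               "lying")
})

test_that("permuted labels drive leave-one-patient-out accuracy to chance", {
  corpus <- simulate_reference_corpus(n_patients = 8, seed = 6)
  set.seed(123)
  corpus$class <- sample(corpus$class)
  corpus$task <- NULL
  lopo <- lopo_validate(corpus)
  acc <- glance(lopo)$overall_accuracy
  # chance for 3 classes with these priors is ~0.33-0.40; far below separable
  expect_lt(acc, 0.55)
  expect_gt(acc, 0.15)
})

test_that("confusion metrics follow the one-vs-rest definitions", {
  # hand-built perfectly diagonal matrix: all metrics 1
  cm <- confusion_matrix3(rep(activity_classes(), each = 50),
                          rep(activity_classes(), each = 50))
  expect_true(all(cm$metrics$accuracy == 1))
  expect_true(all(cm$metrics$sensitivity == 1))
  expect_true(all(cm$metrics$specificity == 1))

  # 2 of 100 active epochs predicted sedentary: active sensitivity 0.98
  actual <- c(rep("active", 100), rep("sedentary_not_lying", 80),
              rep("lying", 60))
  predicted <- c(rep("active", 98), rep("sedentary_not_lying", 2),
                 rep("sedentary_not_lying", 80), rep("lying", 60))
  cm2 <- confusion_matrix3(actual, predicted)
  m <- cm2$metrics
  expect_equal(m$sensitivity[m$class == "active"], 0.98)
  expect_equal(sum(cm2$counts), 240)
  # metrics recomputed from the raw matrix match exactly
  counts <- cm2$counts
  tp <- counts["active", "active"]
  fn <- sum(counts["active", ]) - tp
  expect_equal(m$sensitivity[m$class == "active"], tp / (tp + fn))
})

test_that("LOPO pools exactly the held-out epochs and supports train-only patients", {
  corpus <- simulate_reference_corpus(n_patients = 5, seed = 7)
  lopo <- lopo_validate(corpus)
  expect_equal(sum(lopo$confusion$counts), nrow(corpus))
  # healthy-volunteer augmentation: extra patients join training folds only
  vol <- simulate_reference_corpus(n_patients = 2, seed = 8) |>
    dplyr::mutate(patient_id = paste0("HV", patient_id))
  lopo2 <- lopo_validate(dplyr::bind_rows(corpus, vol),
                         train_only_patients = unique(vol$patient_id))
  expect_equal(lopo2$n_folds, 5)
  expect_equal(sum(lopo2$confusion$counts), nrow(corpus))
})

test_that("stream classification recovers ground truth and skips nonwear", {
  corpus <- simulate_reference_corpus(n_patients = 6, seed = 9)
  fit <- train_classifier(corpus)

  # 30-min low-noise lying bout: 30 lying labels
  ly <- simulate_accel_bout("lying down", 1800, noise_sd_g = 0.002, seed = 10)
  labs <- classify_stream(fit, ly)
  expect_equal(nrow(labs), 30)
  expect_true(all(labs$class == "lying"))

  # alternating 1-min walk/sit: >= 80% correct before smoothing
  ses <- simulate_task_session(
    tibble::tibble(task = rep(c("walking", "sitting"), 10), duration_s = 60),
    seed = 11
  )
  labs2 <- classify_stream(fit, ses$stream, smooth = FALSE)
  truth <- rep(c("active", "sedentary_not_lying"), 10)
  expect_gte(mean(labs2$class == truth), 0.8)

  # nonwear minutes are not labelled
  nw <- tibble::tibble(start_ms = 0, end_ms = 600000, kind = "still")
  labs3 <- classify_stream(fit, ly, nonwear = nw)
  expect_true(all(labs3$epoch_start_ms >= 600000))

  # tidiers return well-formed tables
  expect_true(all(c("class", "accuracy") %in% names(tidy(lopo_validate(corpus)))))
  expect_s3_class(glance(fit), "tbl_df")
  expect_true("feature" %in% names(tidy(fit)))
})
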