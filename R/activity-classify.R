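# Gradient-boosted 3-class activity classifier, leave-one-patient-out
# validation, and per-minute stream classification.

#' Train the 3-class activity classifier
#'
#' Fits a gradient-boosted decision-tree model (xgboost, single thread, fixed
#' seed — training is fully deterministic) on labelled epoch features, with
#' class-balanced instance weights. The fitted model is stored as serialized
#' booster bytes, so the object survives `saveRDS()`/`readRDS()` round trips
#' with identical predictions.
#'
#' @param corpus Feature tibble from [extract_features()] /
#'   [simulate_reference_corpus()], with `class` and `patient_id` columns.
#' @param nrounds Boosting rounds.
#' @param max_depth Tree depth.
#' @param eta Learning rate.
#' @param seed Seed passed to xgboost.
#' @return Object of class `wearals_activity_model`.
#' @export
train_classifier <- function(corpus, nrounds = 60, max_depth = 4, eta = 0.3,
                             seed = 1) {
  stopifnot(all(c("class", "patient_id") %in% names(corpus)))
  if (dplyr::n_distinct(corpus$patient_id) < 2) {
    abort_validation("training corpus needs >= 2 patients", "corpus")
  }
  classes <- activity_classes()
  missing <- setdiff(classes, unique(corpus$class))
  if (length(missing)) {
    abort_validation(
      paste0("training corpus is missing class(es): ",
             paste(missing, collapse = ", ")),
      "corpus"
    )
  }
  y <- match(corpus$class, classes) - 1L
  x <- as.matrix(corpus[, .feature_cols])
  tab <- table(factor(corpus$class, classes))
  w <- as.numeric(nrow(corpus) / (length(classes) * tab[corpus$class]))
  dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w)
  params <- list(objective = "multi:softprob", num_class = length(classes),
                 max_depth = max_depth, eta = eta, nthread = 1,
                 seed = as.integer(seed))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  structure(
    list(raw = xgboost::xgb.save.raw(booster), classes = classes,
         feature_cols = .feature_cols, nrounds = nrounds,
         params = params, n_train = nrow(corpus)),
    class = "wearals_activity_model"
  )
}

#' @export
print.wearals_activity_model <- function(x, ...) {
  cat(sprintf("<wearals_activity_model: %d-class gbt, %d rounds, %d training epochs>\n",
              length(x$classes), x$nrounds, x$n_train))
  invisible(x)
}

#' Predict activity classes for epoch features
#'
#' @param object A `wearals_activity_model`.
#' @param newdata Feature tibble.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of classes, or a probability matrix.
#' @export
predict.wearals_activity_model <- function(object, newdata,
                                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  booster <- xgboost::xgb.load.raw(object$raw)
  x <- as.matrix(newdata[, object$feature_cols])
  p <- predict(booster, xgboost::xgb.DMatrix(x))
  if (!is.matrix(p)) {
    p <- matrix(p, ncol = length(object$classes), byrow = TRUE)
  }
  dimnames(p) <- list(NULL, object$classes)
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' Confusion matrix and one-vs-rest metrics
#'
#' @param actual,predicted Character vectors of class labels.
#' @return Object of class `wearals_confusion`: 3x3 count matrix (actual in
#'   rows, predicted in columns) with per-class one-vs-rest accuracy,
#'   sensitivity (TP/(TP+FN)) and specificity (TN/(TN+FP)).
#' @export
confusion_matrix3 <- function(actual, predicted) {
  classes <- activity_classes()
  cm <- table(factor(actual, classes), factor(predicted, classes))
  structure(list(counts = unclass(cm), metrics = .confusion_metrics(cm)),
            class = "wearals_confusion")
}

.confusion_metrics <- function(cm) {
  classes <- rownames(cm)
  total <- sum(cm)
  list_rbind(lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    tibble(class = cl,
           n_actual = tp + fn,
           accuracy = (tp + tn) / total,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }))
}

#' @export
print.wearals_confusion <- function(x, ...) {
  print(x$counts)
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' Leave-one-patient-out validation of the activity classifier
#'
#' For each patient in turn, trains on all other patients and predicts the
#' held-out patient's epochs; all held-out predictions are pooled into a
#' single confusion matrix with per-class one-vs-rest accuracy, sensitivity
#' and specificity. Healthy-volunteer augmentation data may be supplied as
#' `train_only_patients`: those patients join every training fold but are
#' never held out.
#'
#' @param corpus Labelled feature tibble with `patient_id`.
#' @param train_only_patients Patient ids used for training only.
#' @param ... Passed to [train_classifier()].
#' @return Object of class `wearals_lopo`: `confusion` (a
#'   `wearals_confusion`), `predictions` tibble, `n_folds`.
#' @export
lopo_validate <- function(corpus, train_only_patients = character(), ...) {
  test_pats <- setdiff(unique(corpus$patient_id), train_only_patients)
  if (length(test_pats) < 3) {
    abort_validation("leave-one-patient-out needs >= 3 held-out patients", "corpus")
  }
  preds <- vector("list", length(test_pats))
  for (i in seq_along(test_pats)) {
    p <- test_pats[i]
    train <- corpus |> filter(.data$patient_id != p)
    test <- corpus |> filter(.data$patient_id == p)
    fit <- train_classifier(train, ...)
    preds[[i]] <- tibble(patient_id = p, actual = test$class,
                         predicted = predict(fit, test))
  }
  predictions <- list_rbind(preds)
  structure(
    list(confusion = confusion_matrix3(predictions$actual, predictions$predicted),
         predictions = predictions, n_folds = length(test_pats)),
    class = "wearals_lopo"
  )
}

#' @export
print.wearals_lopo <- function(x, ...) {
  cat(sprintf("<wearals_lopo: %d folds, %d held-out epochs>\n",
              x$n_folds, nrow(x$predictions)))
  print(x$confusion)
  invisible(x)
}

#' @rdname lopo_validate
#' @param x A `wearals_lopo` object.
#' @method tidy wearals_lopo
#' @export
tidy.wearals_lopo <- function(x, ...) x$confusion$metrics

#' @rdname lopo_validate
#' @method glance wearals_lopo
#' @export
glance.wearals_lopo <- function(x, ...) {
  m <- x$confusion$metrics
  tibble(
    n_epochs = nrow(x$predictions),
    n_folds = x$n_folds,
    overall_accuracy = mean(x$predictions$actual == x$predictions$predicted),
    min_class_metric = min(c(m$accuracy, m$sensitivity, m$specificity))
  )
}

#' @rdname train_classifier
#' @param x A `wearals_activity_model`.
#' @param ... Unused.
#' @method tidy wearals_activity_model
#' @export
tidy.wearals_activity_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = xgboost::xgb.load.raw(x$raw))
  as_tibble(imp) |> rename_with(tolower)
}

#' @rdname train_classifier
#' @method glance wearals_activity_model
#' @export
glance.wearals_activity_model <- function(x, ...) {
  tibble(n_train = x$n_train, nrounds = x$nrounds,
         max_depth = x$params$max_depth, eta = x$params$eta)
}

#' Classify a home-monitoring stream into per-minute activity labels
#'
#' Computes epoch features for each wear-time minute, predicts its class, and
#' applies a 3-minute majority smoother (a minute flanked by two minutes of an
#' agreeing different class adopts that class). Minutes overlapping nonwear
#' intervals, and minutes with insufficient samples, are not labelled.
#'
#' @param model A `wearals_activity_model`.
#' @param stream Accelerometer tibble.
#' @param nonwear Optional nonwear intervals from [detect_nonwear()].
#' @param epoch_s Epoch length, seconds.
#' @param rate_hz Sampling rate; inferred when `NULL`.
#' @param smooth Apply the 3-min majority filter (default TRUE).
#' @return Tibble: `epoch_start_ms`, `class`, plus the epoch `score`.
#' @export
classify_stream <- function(model, stream, nonwear = NULL, epoch_s = 60,
                            rate_hz = NULL, smooth = TRUE) {
  stopifnot(inherits(model, "wearals_activity_model"))
  rate_hz <- rate_hz %||% infer_rate_hz(stream)
  t0 <- floor(min(stream$t_ms) / (epoch_s * 1000)) * epoch_s * 1000
  t1 <- max(stream$t_ms)
  starts <- seq(t0, t1, by = epoch_s * 1000)
  if (!is.null(nonwear) && nrow(nonwear)) {
    bad <- vapply(starts, function(s) {
      any(pmin(nonwear$end_ms, s + epoch_s * 1000) - pmax(nonwear$start_ms, s) > 0)
    }, logical(1))
    starts <- starts[!bad]
  }
  rows <- list()
  for (s in starts) {
    seg <- stream |> filter(.data$t_ms >= s, .data$t_ms < s + epoch_s * 1000)
    if (nrow(seg) < epoch_s * rate_hz * 0.5) next
    rows[[length(rows) + 1L]] <- .epoch_features(seg, rate_hz) |>
      mutate(epoch_start_ms = s)
  }
  if (!length(rows)) {
    return(tibble(epoch_start_ms = numeric(), class = character(),
                  score = numeric()))
  }
  feats <- list_rbind(rows)
  cls <- predict(model, feats)
  if (smooth && length(cls) >= 3) cls <- .majority3(cls, feats$epoch_start_ms, epoch_s)
  tibble(epoch_start_ms = feats$epoch_start_ms, class = cls,
         score = feats$score)
}

# 3-min majority filter over temporally adjacent minutes only
.majority3 <- function(cls, starts, epoch_s) {
  out <- cls
  for (i in 2:(length(cls) - 1)) {
    if (starts[i] - starts[i - 1] == epoch_s * 1000 &&
        starts[i + 1] - starts[i] == epoch_s * 1000 &&
        cls[i - 1] == cls[i + 1] && cls[i - 1] != cls[i]) {
      out[i] <- cls[i - 1]
    }
  }
  out
}
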