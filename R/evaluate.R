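#' Confusion counts for the two yield classes
#'
#' Class 0 is low kernel weight (< 25 g), class 1 high (>= 25 g).
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 labels of the same length.
#' @return a `confusion_matrix`: counts `n_low_correct`,
#'   `n_low_misclassified`, `n_high_correct`, `n_high_misclassified`,
#'   `total`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop_hcadbn("labels and predictions differ in length",
                "hcadbn_validation_error")
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop_hcadbn("labels and predictions must be 0/1",
                "hcadbn_validation_error")
  }
  confusion_matrix(
    n_low_correct = sum(labels == 0 & predictions == 0),
    n_low_misclassified = sum(labels == 0 & predictions == 1),
    n_high_correct = sum(labels == 1 & predictions == 1),
    n_high_misclassified = sum(labels == 1 & predictions == 0)
  )
}

#' @rdname confusion
#' @param n_low_correct,n_low_misclassified,n_high_correct,n_high_misclassified
#'   non-negative cell counts.
#' @export
confusion_matrix <- function(n_low_correct, n_low_misclassified,
                             n_high_correct, n_high_misclassified) {
  cells <- c(n_low_correct, n_low_misclassified, n_high_correct,
             n_high_misclassified)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_hcadbn("confusion cells must be non-negative integers",
                "hcadbn_validation_error")
  }
  structure(list(n_low_correct = n_low_correct,
                 n_low_misclassified = n_low_misclassified,
                 n_high_correct = n_high_correct,
                 n_high_misclassified = n_high_misclassified,
                 total = sum(cells)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$n_low_correct, x$n_low_misclassified,
                x$n_high_misclassified, x$n_high_correct),
              2, 2, byrow = TRUE,
              dimnames = list(c("true low", "true high"),
                              c("pred low", "pred high")))
  print(m)
  invisible(x)
}

#' Class-wise classification metrics
#'
#' Computes accuracy, error rate, per-class recall, precision and F1, the
#' support-weighted averages, and specificity. The high-yield class is
#' treated as positive, so specificity equals the recall of the low class.
#' Values are kept at full precision; `display` columns apply half-up
#' rounding to two decimals, the tabulation convention. An empty predicted
#' class yields an undefined (NA) precision, excluded from the weighted
#' averages with a warning.
#'
#' @param cm a `confusion_matrix`.
#' @return a `metrics_report` list: `accuracy`, `error_rate`,
#'   `specificity`, `per_class` data frame (precision/recall/f1/support),
#'   `weighted` (precision/recall/f1), `support`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0) {
    stop_hcadbn("empty confusion matrix", "hcadbn_validation_error")
  }
  n_low <- cm$n_low_correct + cm$n_low_misclassified
  n_high <- cm$n_high_correct + cm$n_high_misclassified
  pred_low <- cm$n_low_correct + cm$n_high_misclassified
  pred_high <- cm$n_high_correct + cm$n_low_misclassified
  accuracy <- (cm$n_low_correct + cm$n_high_correct) / cm$total
  error_rate <- (cm$n_low_misclassified + cm$n_high_misclassified) / cm$total
  recall_low <- if (n_low > 0) cm$n_low_correct / n_low else NA_real_
  recall_high <- if (n_high > 0) cm$n_high_correct / n_high else NA_real_
  precision_low <- if (pred_low > 0) {
    cm$n_low_correct / pred_low
  } else {
    warning("no samples predicted low: precision_low undefined")
    NA_real_
  }
  precision_high <- if (pred_high > 0) {
    cm$n_high_correct / pred_high
  } else {
    warning("no samples predicted high: precision_high undefined")
    NA_real_
  }
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  per_class <- data.frame(
    class = c("low", "high"),
    precision = c(precision_low, precision_high),
    recall = c(recall_low, recall_high),
    f1 = c(f1(precision_low, recall_low), f1(precision_high, recall_high)),
    support = c(n_low, n_high),
    stringsAsFactors = FALSE
  )
  wmean <- function(x) {
    ok <- !is.na(x) & per_class$support > 0
    sum(x[ok] * per_class$support[ok]) / sum(per_class$support[ok])
  }
  structure(list(
    accuracy = accuracy, error_rate = error_rate,
    specificity = recall_low,
    per_class = per_class,
    weighted = c(precision = wmean(per_class$precision),
                 recall = wmean(per_class$recall),
                 f1 = wmean(per_class$f1)),
    support = c(low = n_low, high = n_high)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f  error rate %.2f  specificity %.2f\n",
              round_half_up(x$accuracy), round_half_up(x$error_rate),
              round_half_up(x$specificity)))
  disp <- x$per_class
  disp[c("precision", "recall", "f1")] <-
    lapply(disp[c("precision", "recall", "f1")], round_half_up)
  print(disp, row.names = FALSE)
  cat(sprintf("weighted avg  precision %.2f  recall %.2f  f1 %.2f  (n=%d)\n",
              round_half_up(x$weighted["precision"]),
              round_half_up(x$weighted["recall"]),
              round_half_up(x$weighted["f1"]), sum(x$support)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps every observed score threshold, computing the true/false positive
#' rates for the high class, and integrates by the trapezoidal rule. With
#' tied scores this equals the rank (Mann-Whitney) formulation with ties
#' averaged.
#'
#' @param scores numeric class-1 scores.
#' @param labels true 0/1 labels; both classes must be present.
#' @return list with `curve` (data frame of threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    stop_hcadbn("ROC requires both classes", "hcadbn_validation_error")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 1) / pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 0) / neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
       auc = auc)
}

## Stratified fold assignment: within each class, shuffled indices are dealt
## round-robin to folds, so fold sizes and class fractions differ by <= 1.
stratified_folds <- function(labels, k, seed) {
  old <- .Random.seed_exists()
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  .Random.seed_restore(old)
  fold
}

#' Stratified k-fold cross-validation
#'
#' Each fold serves once as the test set; `model_factory(train_ds)` must
#' return a prediction function `features -> 0/1 labels` (or an object with
#' a `predict` method returning `$labels`).
#'
#' @param model_factory function of a `labeled_dataset` returning a
#'   predictor.
#' @param ds a `labeled_dataset`; every class needs at least `k` members.
#' @param k number of folds (default 10).
#' @param seed integer RNG seed for fold assignment.
#' @return a `resampling_summary`: per-replicate accuracies, mean, sd and
#'   percentile 95% CI.
#' @export
stratified_kfold_cv <- function(model_factory, ds, k = 10, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  seed <- assert_seed(seed)
  counts <- table(ds$labels)
  if (length(counts) < 2 || any(counts < k)) {
    stop_hcadbn(sprintf("each class needs >= %d members for %d-fold CV",
                        k, k), "hcadbn_stratification_error")
  }
  fold <- stratified_folds(ds$labels, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    train <- subset_dataset(ds, which(fold != f))
    test <- subset_dataset(ds, which(fold == f))
    predictor <- model_factory(train)
    pred <- predict_labels(predictor, test$features)
    mean(pred == test$labels)
  }, numeric(1))
  resampling_summary(acc, scheme = "stratified_kfold", folds = fold)
}

predict_labels <- function(predictor, features) {
  out <- if (is.function(predictor)) {
    predictor(features)
  } else {
    predict(predictor, features)
  }
  if (is.list(out)) out <- out$labels
  as.integer(out)
}

resampling_summary <- function(accuracies, scheme, ...) {
  ci <- stats::quantile(accuracies, c(0.025, 0.975), type = 7, names = FALSE)
  structure(list(accuracies = accuracies, mean = mean(accuracies),
                 sd = stats::sd(accuracies),
                 ci_lower = ci[1], ci_upper = ci[2],
                 n_replicates = length(accuracies), scheme = scheme, ...),
            class = "resampling_summary")
}

#' @export
print.resampling_summary <- function(x, ...) {
  cat(sprintf(
    "<resampling_summary:%s> %d replicates, mean %.4f (sd %.4f), 95%% CI [%.2f, %.2f]\n",
    x$scheme, x$n_replicates, x$mean, x$sd, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Bootstrap validation with out-of-bag scoring
#'
#' Each of the `B` replicates resamples n observations with replacement as
#' the training set and scores accuracy on the out-of-bag samples. The 95%
#' confidence interval is the 2.5/97.5 percentile band of the replicate
#' accuracies. Replicates with an empty out-of-bag set or a single-class
#' training draw are redrawn (counted in `n_redrawn`).
#'
#' @inheritParams stratified_kfold_cv
#' @param B number of bootstrap replicates (default 200).
#' @return a `resampling_summary` with `n_redrawn`.
#' @export
bootstrap_validation <- function(model_factory, ds, B = 200, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (B < 2) stop_hcadbn("B must be at least 2", "hcadbn_config_error")
  n <- length(ds$labels)
  if (n < 10) {
    stop_hcadbn("bootstrap validation requires n >= 10",
                "hcadbn_validation_error")
  }
  old <- .Random.seed_exists()
  set.seed(assert_seed(seed))
  acc <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(oob) > 0 && length(unique(ds$labels[idx])) == 2) break
      redrawn <- redrawn + 1L
    }
    train <- subset_dataset(ds, idx)
    test <- subset_dataset(ds, oob)
    predictor <- model_factory(train)
    pred <- predict_labels(predictor, test$features)
    acc[b] <- mean(pred == test$labels)
  }
  .Random.seed_restore(old)
  resampling_summary(acc, scheme = "bootstrap_oob", n_redrawn = redrawn)
}

#' Permutation-based feature sensitivity
#'
#' importance_f = baseline accuracy minus the mean accuracy after shuffling
#' feature f's column, averaged over `n_iterations` independent shuffles.
#' Negative values are permitted (inverse sensitivity); no normalization is
#' applied.
#'
#' @param model a fitted `dbn_model` (or any predictor accepted by the
#'   resampling functions).
#' @param ds a `labeled_dataset` to score on.
#' @param n_iterations shuffles per feature (default 50).
#' @param seed integer RNG seed.
#' @return data frame of feature, importance (sorted descending), baseline
#'   accuracy attached as an attribute.
#' @export
permutation_sensitivity <- function(model, ds, n_iterations = 50, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (inherits(model, "dbn_model") && !isTRUE(model$fitted)) {
    stop_hcadbn("model must be fitted before sensitivity analysis",
                "hcadbn_state_error")
  }
  baseline <- mean(predict_labels(model, ds$features) == ds$labels)
  old <- .Random.seed_exists()
  set.seed(assert_seed(seed))
  n <- nrow(ds$features)
  imp <- vapply(seq_len(ncol(ds$features)), function(f) {
    drop_acc <- vapply(seq_len(n_iterations), function(i) {
      X <- ds$features
      X[, f] <- X[sample.int(n), f]
      mean(predict_labels(model, X) == ds$labels)
    }, numeric(1))
    baseline - mean(drop_acc)
  }, numeric(1))
  .Random.seed_restore(old)
  out <- data.frame(feature = ds$feature_codes, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_accuracy") <- baseline
  out
}
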