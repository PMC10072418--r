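# Fold-level classification metrics, matching the reporting convention
# AUC / accuracy / per-class accuracy (recall) / macro F1.

#' AUC via the Mann-Whitney rank formulation
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted half (midranks).
#'
#' @param labels 0/1 vector (both classes present).
#' @param probabilities predicted scores.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(labels, probabilities) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Compute fold metrics
#'
#' AUC (Mann-Whitney), overall accuracy, per-class accuracy (recall of each
#' class), and macro-averaged F1 at the given probability threshold.
#'
#' @param labels 0/1 slide labels (both classes present).
#' @param probabilities predicted slide probabilities.
#' @param threshold decision threshold, default 0.5.
#' @return one-row data.frame: `auc`, `accuracy`, `class0_accuracy`,
#'   `class1_accuracy`, `f1`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(probabilities))
    stop("labels and probabilities must have equal length")
  auc <- auc_mann_whitney(labels, probabilities)
  pred <- as.integer(probabilities >= threshold)
  acc <- mean(pred == labels)
  rec0 <- mean(pred[labels == 0L] == 0L)
  rec1 <- mean(pred[labels == 1L] == 1L)
  f1_class <- function(cls) {
    tp <- sum(pred == cls & labels == cls)
    fp <- sum(pred == cls & labels != cls)
    fn <- sum(pred != cls & labels == cls)
    if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  data.frame(auc = auc, accuracy = acc, class0_accuracy = rec0,
             class1_accuracy = rec1, f1 = (f1_class(0L) + f1_class(1L)) / 2)
}

#' Aggregate fold metrics
#'
#' `mode = "mean_sd"` reports per-metric mean and sample standard deviation
#' across folds. `mode = "bootstrap"` pools the folds' slide-level
#' predictions, resamples slides with replacement B times, recomputes the
#' metrics on each resample, and reports the mean with a percentile 95% CI.
#'
#' @param fold_metrics data.frame of per-fold metric rows
#'   ([compute_metrics()] output, row-bound).
#' @param mode `"mean_sd"` or `"bootstrap"`.
#' @param predictions pooled predictions (`label`, `probability` columns),
#'   required for bootstrap mode.
#' @param B bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for resampling.
#' @return data.frame with one row per metric: mean plus either `sd` or
#'   `ci_lower`/`ci_upper`.
#' @export
aggregate_folds <- function(fold_metrics, mode = c("mean_sd", "bootstrap"),
                            predictions = NULL, B = 2000L, conf = 0.95,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (!nrow(fold_metrics)) stop("no fold metrics to aggregate")
  metric_names <- c("auc", "accuracy", "class0_accuracy", "class1_accuracy", "f1")
  if (mode == "mean_sd") {
    if (nrow(fold_metrics) < 2L)
      stop("mean_sd aggregation needs at least 2 folds")
    return(data.frame(metric = metric_names,
                      mean = vapply(metric_names, function(m) mean(fold_metrics[[m]]), numeric(1)),
                      sd = vapply(metric_names, function(m) sd(fold_metrics[[m]]), numeric(1)),
                      row.names = NULL))
  }
  if (is.null(predictions)) stop("bootstrap aggregation requires predictions")
  bt <- bootstrap_metrics(predictions$label, predictions$probability,
                          B = B, conf = conf, seed = seed)
  data.frame(metric = metric_names,
             mean = vapply(metric_names, function(m) mean(fold_metrics[[m]]), numeric(1)),
             ci_lower = bt$ci_lower[metric_names],
             ci_upper = bt$ci_upper[metric_names], row.names = NULL)
}

#' Bootstrap percentile confidence intervals for fold metrics
#'
#' Resamples slides (not folds) with replacement from the pooled predictions.
#' Resamples that lose one class entirely are redrawn.
#'
#' @param labels 0/1 labels of the pooled predictions.
#' @param probabilities pooled predicted probabilities.
#' @param B number of resamples.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @param threshold decision threshold.
#' @return list with `ci_lower`, `ci_upper` (named per metric) and the
#'   B x 5 matrix of resampled metrics.
#' @export
bootstrap_metrics <- function(labels, probabilities, B = 2000L, conf = 0.95,
                              seed = 1L, threshold = 0.5) {
  set.seed(seed)
  n <- length(labels)
  res <- matrix(NA_real_, B, 5L,
                dimnames = list(NULL, c("auc", "accuracy", "class0_accuracy",
                                        "class1_accuracy", "f1")))
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    res[b, ] <- as.numeric(compute_metrics(labels[idx], probabilities[idx],
                                           threshold))
  }
  alpha <- (1 - conf) / 2
  list(ci_lower = apply(res, 2, quantile, probs = alpha, names = FALSE),
       ci_upper = apply(res, 2, quantile, probs = 1 - alpha, names = FALSE),
       samples = res)
}

#' Subgroup error rates
#'
#' Error rate per covariate group: misclassified / total within the group.
#' Groups with zero members are reported as `NA` (undefined), never zero.
#'
#' @param predictions data.frame with `slide_id`, `label`,
#'   `predicted_label`.
#' @param covariates data.frame with `slide_id` plus covariate columns
#'   (e.g. a recurrence-score range or grade).
#' @param grouping name of the covariate column to group by.
#' @return data.frame `group`, `n`, `n_misclassified`, `error_rate`.
#' @export
subgroup_error_rates <- function(predictions, covariates, grouping) {
  if (!grouping %in% names(covariates))
    stop("unknown grouping key: ", grouping)
  merged <- merge(predictions, covariates, by = "slide_id")
  groups <- if (is.factor(covariates[[grouping]]))
    levels(covariates[[grouping]]) else unique(covariates[[grouping]])
  out <- lapply(groups, function(g) {
    rows <- merged[merged[[grouping]] == g, , drop = FALSE]
    n <- nrow(rows)
    miss <- sum(rows$predicted_label != rows$label)
    data.frame(group = as.character(g), n = n, n_misclassified = miss,
               error_rate = if (n == 0L) NA_real_ else miss / n)
  })
  do.call(rbind, out)
}
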