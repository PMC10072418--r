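# Metric computation against brute-force oracles, aggregation, bootstrap,
# and subgroup error rates.

test_that("AUC matches the O(n^2) pairwise oracle", {
  set.seed(40)
  expect_equal(auc_mann_whitney(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_mann_whitney(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(auc_mann_whitney(c(1, 1), c(0.2, 0.4)), "both classes")
  for (rep in 1:1000) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    probs <- round(runif(n), 2)  # rounding forces ties
    expect_lte(abs(auc_mann_whitney(labels, probs) -
                     auc_pairwise(labels, probs)), 1e-10)
  }
})

test_that("AUC agrees with an established independent implementation", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(8:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    probs <- runif(n)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_mann_whitney(labels, probs), ref, tolerance = 1e-12)
  }
})

test_that("fold metrics derive from explicit confusion counts", {
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  probs <- c(0.1, 0.2, 0.6, 0.4, 0.9, 0.8, 0.3, 0.7)
  m <- compute_metrics(labels, probs)
  # confusion at 0.5: TN=3 FP=1 FN=1 TP=3
  expect_equal(m$accuracy, 6 / 8)
  expect_equal(m$class0_accuracy, 3 / 4)
  expect_equal(m$class1_accuracy, 3 / 4)
  expect_equal(m$f1, 0.75)  # both classes: 2*3/(2*3+1+1)
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(6:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    probs <- runif(n)
    m <- compute_metrics(labels, probs)
    pred <- as.integer(probs >= 0.5)
    f1c <- function(cls) {
      tp <- sum(pred == cls & labels == cls)
      fp <- sum(pred == cls & labels != cls)
      fn <- sum(pred != cls & labels == cls)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }
    expect_equal(m$f1, (f1c(0) + f1c(1)) / 2)
    expect_equal(m$accuracy, mean(pred == labels))
    # accuracy is the prevalence-weighted combination of class accuracies
    w1 <- mean(labels == 1)
    expect_equal(m$accuracy,
                 (1 - w1) * m$class0_accuracy + w1 * m$class1_accuracy)
  }
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.8)), "both classes")
})

test_that("fold aggregation: mean/sd and degenerate bootstrap", {
  fm <- rbind(compute_metrics(c(0, 1), c(0.1, 0.9)),
              compute_metrics(c(0, 1), c(0.1, 0.9)))
  agg <- aggregate_folds(fm, "mean_sd")
  expect_true(all(agg$sd == 0))
  fm2 <- data.frame(auc = c(0.7, 0.9), accuracy = c(0.7, 0.9),
                    class0_accuracy = c(0.7, 0.9),
                    class1_accuracy = c(0.7, 0.9), f1 = c(0.7, 0.9))
  expect_equal(aggregate_folds(fm2, "mean_sd")$mean, rep(0.8, 5))
  expect_error(aggregate_folds(fm2[0, ], "mean_sd"), "no fold")
  # all-correct predictions: every resample yields the same metrics, CI width 0
  preds <- data.frame(label = rep(c(0, 1), each = 10),
                      probability = rep(c(0.1, 0.9), each = 10))
  agg_b <- aggregate_folds(fm, "bootstrap", predictions = preds, B = 200)
  expect_true(all(agg_b$ci_upper - agg_b$ci_lower == 0))
})

test_that("bootstrap resamples slides and honors the seed", {
  set.seed(43)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.5, 0.5))
  labels[1:2] <- 0:1
  probs <- ifelse(rbinom(60, 1, 0.75) == 1, labels, 1 - labels) * 0.8 + 0.1
  b1 <- bootstrap_metrics(labels, probs, B = 100, seed = 9)
  b2 <- bootstrap_metrics(labels, probs, B = 100, seed = 9)
  expect_identical(b1$samples, b2$samples)
  expect_true(all(b1$ci_lower <= b1$ci_upper))
})

test_that("subgroup error rates equal an independent tally", {
  preds <- data.frame(slide_id = sprintf("s%02d", 1:8),
                      label = c(0, 0, 0, 0, 1, 1, 1, 1),
                      predicted_label = c(0, 0, 0, 1, 1, 1, 1, 1))
  cov <- data.frame(slide_id = sprintf("s%02d", 1:8),
                    grade = c(1, 1, 2, 2, 2, 2, 3, 3))
  out <- subgroup_error_rates(preds, cov, "grade")
  expect_equal(out$error_rate[out$group == "1"], 0)
  expect_equal(out$error_rate[out$group == "2"], 0.25)
  expect_equal(out$error_rate[out$group == "3"], 0)
  expect_error(subgroup_error_rates(preds, cov, "stage"), "unknown grouping")
  # zero-member group reported as undefined, not zero
  cov$grade <- factor(cov$grade, levels = c(1, 2, 3, 4))
  out4 <- subgroup_error_rates(preds, cov, "grade")
  expect_true(is.na(out4$error_rate[out4$group == "4"]))
  # random instances vs independent tally
  set.seed(44)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    preds <- data.frame(slide_id = sprintf("r%03d", 1:n),
                        label = sample(0:1, n, replace = TRUE),
                        predicted_label = sample(0:1, n, replace = TRUE))
    cov <- data.frame(slide_id = preds$slide_id,
                      g = sample(letters[1:3], n, replace = TRUE))
    out <- subgroup_error_rates(preds, cov, "g")
    for (g in unique(cov$g)) {
      ix <- cov$g == g
      expect_equal(out$error_rate[out$group == g],
                   sum(preds$predicted_label[ix] != preds$label[ix]) / sum(ix))
    }
  }
})
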