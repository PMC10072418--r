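# Cross-validation split plans. Both schemes first balance the cohort by
# subsampling the majority class (sampling an equal number of slides from the
# larger cohort), then split:
#   kfold_holdout — one stratified hold-out test set shared by every fold;
#     the remaining slides are randomly re-split into training/validation
#     once per fold (the validation draws are independent across folds).
#   ltocv — leave-two-out: each fold's validation set holds exactly one slide
#     per class; fold count equals the per-class count; no test set (metrics
#     are computed on the validation pairs).

#' Build a cross-validation split plan
#'
#' @param slide_ids character slide ids.
#' @param labels 0/1 labels aligned to `slide_ids`.
#' @param scheme `"kfold_holdout"` or `"ltocv"`.
#' @param n_folds number of folds (kfold_holdout only).
#' @param holdout_frac fraction of the balanced cohort held out for testing
#'   (kfold_holdout; default 0.2, stratified).
#' @param val_frac fraction of the remaining slides used for validation in
#'   each fold (default 0.1, stratified, at least one slide per class).
#' @param seed RNG seed; plans are identical across runs for a fixed seed.
#' @return an object of class `split_plan`: `scheme`, `seed`,
#'   `balanced_ids`, and `folds`, a list of lists with `train`,
#'   `validation`, `test` id vectors.
#' @export
make_splits <- function(slide_ids, labels, scheme = c("kfold_holdout", "ltocv"),
                        n_folds = 5L, holdout_frac = 0.2, val_frac = 0.1,
                        seed = 1L) {
  scheme <- match.arg(scheme)
  labels <- as.integer(labels)
  ids0 <- slide_ids[labels == 0L]
  ids1 <- slide_ids[labels == 1L]
  if (!length(ids0) || !length(ids1))
    stop("both classes must be present")
  set.seed(seed)
  n_bal <- min(length(ids0), length(ids1))
  ids0 <- sort(sample(ids0, n_bal))
  ids1 <- sort(sample(ids1, n_bal))

  if (scheme == "ltocv") {
    ord0 <- sample(ids0)
    ord1 <- sample(ids1)
    folds <- lapply(seq_len(n_bal), function(i) {
      val <- c(ord0[i], ord1[i])
      list(train = setdiff(c(ids0, ids1), val), validation = val,
           test = character(0))
    })
  } else {
    if (n_folds < 1L) stop("n_folds must be >= 1")
    n_test_pc <- round(holdout_frac * n_bal)
    if (n_bal - n_test_pc < 2L)
      stop("too few slides per class for the requested hold-out fraction")
    test <- c(sample(ids0, n_test_pc), sample(ids1, n_test_pc))
    rest0 <- setdiff(ids0, test); rest1 <- setdiff(ids1, test)
    n_val_pc <- max(1L, round(val_frac * (length(rest0) + length(rest1)) / 2))
    if (n_val_pc >= length(rest0))
      stop("too few slides per class for the requested validation fraction")
    folds <- lapply(seq_len(n_folds), function(i) {
      val <- c(sample(rest0, n_val_pc), sample(rest1, n_val_pc))
      list(train = setdiff(c(rest0, rest1), val), validation = val,
           test = test)
    })
  }
  structure(list(scheme = scheme, seed = as.integer(seed),
                 balanced_ids = c(ids0, ids1), folds = folds),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  f1 <- x$folds[[1]]
  cat(sprintf("<split_plan> %s: %d folds (train %d / validation %d / test %d)\n",
              x$scheme, length(x$folds), length(f1$train),
              length(f1$validation), length(f1$test)))
  invisible(x)
}
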