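# End-to-end experiment driver: tile -> (per fold) train scorer -> score ->
# top-K sample -> embed bags -> train MIL -> evaluate on the fold's
# evaluation set (hold-out test for kfold_holdout, validation pair for
# ltocv), then aggregate across folds.

#' Run the full two-stage pipeline over a cohort
#'
#' For every fold of the split plan: trains the patch scorer on the fold's
#' training slides only, scores every ROI patch of every slide with the
#' early-stopped checkpoint, selects each slide's top-K patches by
#' discrimination score, embeds them into bags, trains the gated attention
#' MIL model on the training bags (monitoring validation accuracy for
#' `kfold_holdout`, training accuracy for `ltocv`, as in the respective
#' protocols), and evaluates on the fold's evaluation slides.
#'
#' @param slides list of [slide_record()]s.
#' @param scheme `"kfold_holdout"` or `"ltocv"`.
#' @param k bag size K (top-K patches per slide; `Inf` = no sampling).
#' @param patch_size patch side in pixels.
#' @param stride tiling stride; defaults to `patch_size`.
#' @param n_folds folds for `kfold_holdout`.
#' @param scorer_cfg a [scorer_config()]; its seed is re-derived per fold.
#' @param mil_cfg a [mil_config()]; monitor is forced per scheme.
#' @param seed experiment seed (splits and per-fold model seeds derive
#'   from it).
#' @param holdout_frac,val_frac split fractions, see [make_splits()].
#' @param keep_models keep per-fold models in the result (default FALSE).
#' @return an object of class `mil_experiment`: `splits`, `fold_metrics`
#'   (data.frame, one row per fold), `predictions` (pooled evaluation-set
#'   predictions with `fold`, `slide_id`, `label`, `probability`,
#'   `predicted_label`), `attention` (list per fold of per-slide attention
#'   vectors with refs, for all slides), `summary` (mean +/- sd across
#'   folds).
#' @export
run_pipeline <- function(slides, scheme = c("kfold_holdout", "ltocv"),
                         k = 16L, patch_size = 64L, stride = patch_size,
                         n_folds = 5L, scorer_cfg = scorer_config(),
                         mil_cfg = mil_config(), seed = 1L,
                         holdout_frac = 0.2, val_frac = 0.1,
                         keep_models = FALSE) {
  scheme <- match.arg(scheme)
  ids <- vapply(slides, `[[`, character(1), "slide_id")
  labels <- vapply(slides, `[[`, integer(1), "label")
  names(slides) <- ids
  manifest <- tile_cohort(slides, patch_size, stride)
  splits <- make_splits(ids, labels, scheme, n_folds = n_folds,
                        holdout_frac = holdout_frac, val_frac = val_frac,
                        seed = seed)
  slides <- slides[splits$balanced_ids]
  labels <- setNames(labels[match(splits$balanced_ids, ids)],
                     splits$balanced_ids)
  mil_cfg$monitor <- if (scheme == "kfold_holdout")
    "validation_accuracy" else "training_accuracy"

  fold_metrics <- list()
  predictions <- list()
  attention <- list()
  models <- list()
  for (f in seq_along(splits$folds)) {
    fold <- splits$folds[[f]]
    scfg <- scorer_cfg; scfg$seed <- slide_seed(seed, 1000L + f)
    mcfg <- mil_cfg;    mcfg$seed <- slide_seed(seed, 2000L + f)
    scorer <- fit_scorer(slides[fold$train], manifest, scfg)
    bags <- build_bags(scorer, slides, manifest, k = k)
    mil <- train_mil(bags[fold$train], mcfg,
                     validation_bags = bags[fold$validation])
    eval_ids <- if (scheme == "kfold_holdout") fold$test else fold$validation
    preds <- lapply(bags[eval_ids], function(b) predict_slide(mil, b))
    probs <- vapply(preds, `[[`, numeric(1), "probability")
    fold_metrics[[f]] <- cbind(fold = f,
                               compute_metrics(labels[eval_ids], probs))
    predictions[[f]] <- data.frame(
      fold = f, slide_id = eval_ids, label = as.integer(labels[eval_ids]),
      probability = probs,
      predicted_label = as.integer(probs >= 0.5), row.names = NULL)
    attention[[f]] <- lapply(bags, function(b) {
      pr <- predict_slide(mil, b)
      list(slide_id = b$slide_id, label = b$label,
           attention = pr$attention, refs = b$refs,
           probability = pr$probability)
    })
    if (keep_models) models[[f]] <- list(scorer = scorer, mil = mil)
  }
  fold_metrics <- do.call(rbind, fold_metrics)
  structure(list(
    scheme = scheme, k = k, patch_size = patch_size, seed = seed,
    splits = splits, fold_metrics = fold_metrics,
    predictions = do.call(rbind, predictions), attention = attention,
    summary = aggregate_folds(fold_metrics,
                              if (nrow(fold_metrics) >= 2L) "mean_sd"
                              else "bootstrap",
                              predictions = do.call(rbind, predictions)),
    models = if (keep_models) models else NULL
  ), class = "mil_experiment")
}

#' @export
print.mil_experiment <- function(x, ...) {
  cat(sprintf("<mil_experiment> %s, K=%s, %d folds\n", x$scheme,
              format(x$k), nrow(x$fold_metrics)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Bag-size (K) ablation harness
#'
#' Re-runs the MIL stage for each K with a shared per-fold scorer: the scorer
#' is trained once per fold, every slide is scored once, and only the
#' sampling + MIL training are repeated per K. Emits the AUC-versus-K table.
#'
#' @param slides list of [slide_record()]s.
#' @param k_values bag sizes to sweep; use `Inf` for the no-sampling limit.
#' @param scheme,patch_size,n_folds,scorer_cfg,mil_cfg,seed,holdout_frac,val_frac
#'   as in [run_pipeline()].
#' @return data.frame `k`, `mean_auc`, `sd_auc` (one row per K value).
#' @export
ablate_k <- function(slides, k_values, scheme = c("kfold_holdout", "ltocv"),
                     patch_size = 64L, n_folds = 5L,
                     scorer_cfg = scorer_config(), mil_cfg = mil_config(),
                     seed = 1L, holdout_frac = 0.2, val_frac = 0.1) {
  scheme <- match.arg(scheme)
  ids <- vapply(slides, `[[`, character(1), "slide_id")
  labels <- vapply(slides, `[[`, integer(1), "label")
  names(slides) <- ids
  manifest <- tile_cohort(slides, patch_size)
  splits <- make_splits(ids, labels, scheme, n_folds = n_folds,
                        holdout_frac = holdout_frac, val_frac = val_frac,
                        seed = seed)
  slides <- slides[splits$balanced_ids]
  labels <- setNames(labels[match(splits$balanced_ids, ids)],
                     splits$balanced_ids)
  mil_cfg$monitor <- if (scheme == "kfold_holdout")
    "validation_accuracy" else "training_accuracy"
  aucs <- matrix(NA_real_, length(splits$folds), length(k_values))
  for (f in seq_along(splits$folds)) {
    fold <- splits$folds[[f]]
    scfg <- scorer_cfg; scfg$seed <- slide_seed(seed, 1000L + f)
    scorer <- fit_scorer(slides[fold$train], manifest, scfg)
    scores <- do.call(rbind, lapply(slides, function(sl)
      score_slide(scorer, sl, manifest)))
    for (j in seq_along(k_values)) {
      mcfg <- mil_cfg
      mcfg$seed <- slide_seed(seed, 2000L + f * 100L + j)
      bags <- build_bags(scorer, slides, manifest, k = k_values[j],
                         scores = scores)
      mil <- train_mil(bags[fold$train], mcfg,
                       validation_bags = bags[fold$validation])
      eval_ids <- if (scheme == "kfold_holdout") fold$test else fold$validation
      probs <- vapply(bags[eval_ids],
                      function(b) predict_slide(mil, b)$probability,
                      numeric(1))
      aucs[f, j] <- auc_mann_whitney(labels[eval_ids], probs)
    }
  }
  data.frame(k = k_values, mean_auc = colMeans(aucs),
             sd_auc = apply(aucs, 2, sd))
}
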