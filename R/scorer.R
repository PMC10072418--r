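# Patch-level CNN scorer: trained under slide-level weak labels, it maps each
# patch to a class probability; the discrimination score (DS) is the patch's
# normalized distance from the 0.5 decision boundary and drives sampling.

#' Scorer configuration
#'
#' @param backbone `"small_cnn"` (a 3-conv-block network, embedding dimension
#'   64, trainable on CPU) or `"paper_backbone"` (ImageNet-pretrained ResNet50
#'   truncated after its third residual stage, embedding dimension 1024;
#'   requires a user-supplied weights file, none is bundled).
#' @param embed_dim embedding dimension; defaults to 64 for `small_cnn` and
#'   1024 for `paper_backbone`.
#' @param learning_rate Adam learning rate (default 0.0002).
#' @param max_epochs maximum training epochs (default 150).
#' @param early_stop_patience epochs without training-accuracy improvement
#'   before stopping (default 15); the checkpoint kept is the last
#'   improvement. Ties do not count as improvement.
#' @param patches_per_slide patches sampled per training slide (default 200).
#' @param batch_size minibatch size (default 32).
#' @param seed RNG seed for initialization and shuffling.
#' @return an object of class `scorer_config`.
#' @export
scorer_config <- function(backbone = c("small_cnn", "paper_backbone"),
                          embed_dim = NULL, learning_rate = 2e-4,
                          max_epochs = 150L, early_stop_patience = 15L,
                          patches_per_slide = 200L, batch_size = 32L,
                          seed = 1L) {
  backbone <- match.arg(backbone)
  if (is.null(embed_dim))
    embed_dim <- if (backbone == "paper_backbone") 1024L else 64L
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (early_stop_patience >= max_epochs)
    stop("early_stop_patience must be < max_epochs")
  structure(list(backbone = backbone, embed_dim = as.integer(embed_dim),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 patches_per_slide = as.integer(patches_per_slide),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "scorer_config")
}

#' Discrimination score of a class probability
#'
#' `DS = |p - 0.5| / 0.5`, in \[0, 1\]: 0 at the decision boundary (a patch
#' the scorer finds uninformative), 1 at a confident prediction for either
#' class. Patches are ranked by DS for sampling.
#'
#' @param probability probabilities in \[0, 1\].
#' @return numeric vector of discrimination scores.
#' @export
discrimination_score <- function(probability) {
  if (any(is.na(probability)) || any(probability < 0 | probability > 1))
    stop("probability must lie in [0, 1]")
  abs(probability - 0.5) / 0.5
}

#' Build the weakly labeled patch training set
#'
#' Samples up to `per_slide` ROI patches uniformly without replacement from
#' each training slide and labels every patch with its slide-level label.
#'
#' @param slides list of [slide_record()]s (the training slides).
#' @param manifest patch manifest from [tile_cohort()].
#' @param per_slide patches per slide (capped at availability).
#' @param seed RNG seed.
#' @return manifest rows plus a `label` column.
#' @export
build_patch_training_set <- function(slides, manifest, per_slide = 200L,
                                     seed = 1L) {
  if (!nrow(manifest)) stop("empty manifest")
  labels <- setNames(vapply(slides, `[[`, integer(1), "label"),
                     vapply(slides, `[[`, character(1), "slide_id"))
  set.seed(seed)
  out <- lapply(names(labels), function(id) {
    rows <- manifest[manifest$slide_id == id, , drop = FALSE]
    if (!nrow(rows)) stop("slide ", id, " has no ROI patches in the manifest")
    take <- min(per_slide, nrow(rows))
    rows <- rows[sample.int(nrow(rows), take), , drop = FALSE]
    rows$label <- labels[[id]]
    rows
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Load labeled patch refs into a pixel batch, reading each slide image once.
load_patches <- function(slides, refs) {
  s <- refs$size[1]
  x <- array(0, dim = c(s, s, 3, nrow(refs)))
  by_slide <- split(seq_len(nrow(refs)), refs$slide_id)
  images <- setNames(lapply(slides, function(sl) sl$image_path),
                     vapply(slides, `[[`, character(1), "slide_id"))
  for (id in names(by_slide)) {
    if (is.null(images[[id]])) stop("manifest slide ", id, " not in slide list")
    img <- read_image(images[[id]])
    for (i in by_slide[[id]]) x[, , , i] <- read_patch(img, refs[i, ])
  }
  x
}

#' Train the patch scorer
#'
#' Minimizes binary cross-entropy with Adam over minibatches. The early-stop
#' monitor is the training accuracy accumulated across the epoch's minibatch
#' predictions; the returned parameters are the checkpoint saved at the last
#' strict improvement of that monitor.
#'
#' @param x patch batch, array `(side, side, 3, N)` with values in 0-255;
#'   side must be a multiple of 8.
#' @param y 0/1 patch labels (both classes must be present).
#' @param config a [scorer_config()].
#' @return an object of class `scorer_model` with elements `params`,
#'   `config`, `history` (per-epoch loss and accuracy), `best_epoch`,
#'   `epochs_run`.
#' @export
train_scorer <- function(x, y, config = scorer_config()) {
  if (config$backbone == "paper_backbone")
    stop("backbone='paper_backbone' requires externally supplied pretrained ",
         "ResNet50 weights; none are bundled. Use backbone='small_cnn'.")
  n <- dim(x)[4]
  if (length(y) != n) stop("length(y) must match the batch size")
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the patch training set")
  set.seed(config$seed)
  params <- nn_init_params(config$embed_dim, in_channels = dim(x)[3])
  opt <- adam_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  hist_loss <- hist_acc <- numeric(0)
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    ord <- sample.int(n)
    correct <- 0L
    losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- nn_forward(params, xb, cache = TRUE)
      correct <- correct + sum((fw$prob >= 0.5) == (yb == 1L))
      losses <- c(losses, bce_loss(fw$prob, yb))
      dlogit <- (fw$prob - yb) / length(idx)
      grads <- nn_backward(params, fw, dlogit)
      st <- adam_step(params, grads, opt, lr = config$learning_rate)
      params <- st$params; opt <- st$state
    }
    acc <- correct / n
    hist_loss <- c(hist_loss, mean(losses))
    hist_acc <- c(hist_acc, acc)
    if (acc > best$acc) best <- list(acc = acc, params = params, epoch = epoch)
    if (epoch - best$epoch >= config$early_stop_patience) break
    if (epoch >= config$max_epochs) break
  }
  structure(list(params = best$params, config = config,
                 history = list(loss = hist_loss, accuracy = hist_acc),
                 best_epoch = best$epoch, epochs_run = epoch),
            class = "scorer_model")
}

#' Train a scorer from slides and a manifest
#'
#' Convenience wrapper: samples the weakly labeled patch set
#' ([build_patch_training_set()]), loads pixels, and calls [train_scorer()].
#' @inheritParams build_patch_training_set
#' @param config a [scorer_config()].
#' @export
fit_scorer <- function(slides, manifest, config = scorer_config()) {
  refs <- build_patch_training_set(slides, manifest,
                                   per_slide = config$patches_per_slide,
                                   seed = config$seed)
  x <- load_patches(slides, refs)
  train_scorer(x, refs$label, config)
}

# Batched inference helpers ---------------------------------------------------

scorer_probability <- function(model, x, batch_size = 64L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- nn_forward(model$params, x[, , , idx, drop = FALSE])$prob
  }
  out
}

scorer_embed <- function(model, x, batch_size = 64L) {
  n <- dim(x)[4]
  out <- matrix(0, n, model$config$embed_dim)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- t(nn_forward(model$params,
                               x[, , , idx, drop = FALSE])$embedding)
  }
  out
}

#' Score every ROI patch of a slide
#'
#' Runs the trained scorer over all manifest patches of one slide and attaches
#' the discrimination score. Batch evaluation order does not affect values.
#'
#' @param model a trained `scorer_model`.
#' @param slide a [slide_record()].
#' @param manifest cohort manifest (rows for other slides are ignored).
#' @param image optional pre-decoded image array.
#' @return data.frame `slide_id, x, y, size, probability, ds`.
#' @export
score_slide <- function(model, slide, manifest, image = NULL) {
  refs <- manifest[manifest$slide_id == slide$slide_id, , drop = FALSE]
  if (!nrow(refs)) stop("manifest has no patches for slide ", slide$slide_id)
  if (is.null(image)) image <- read_image(slide$image_path)
  xb <- read_patch_batch(image, refs)
  p <- scorer_probability(model, xb)
  refs$probability <- p
  refs$ds <- discrimination_score(p)
  rownames(refs) <- NULL
  refs
}

#' Save / load a scorer checkpoint
#'
#' Single-file archive holding the parameters together with the JSON-encoded
#' configuration.
#' @param model a `scorer_model`.
#' @param path checkpoint file.
#' @export
save_scorer <- function(model, path) {
  obj <- list(format = "attnmil-scorer-v1",
              config_json = jsonlite::toJSON(unclass(model$config),
                                             auto_unbox = TRUE, digits = NA),
              params = model$params, history = model$history,
              best_epoch = model$best_epoch, epochs_run = model$epochs_run)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_scorer
#' @param path checkpoint file.
#' @export
load_scorer <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "attnmil-scorer-v1"))
    stop("not an attnmil scorer checkpoint: ", path)
  cfg <- jsonlite::fromJSON(obj$config_json)
  cfg <- do.call(scorer_config, cfg[names(cfg) %in% names(formals(scorer_config))])
  structure(list(params = obj$params, config = cfg, history = obj$history,
                 best_epoch = obj$best_epoch, epochs_run = obj$epochs_run),
            class = "scorer_model")
}
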