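# Gated attention-based multiple instance learning.
#
# For a bag of K instance embeddings x_k (rows of a K x D matrix), attention
# logits are w^T (tanh(V x_k^T) * sigm(U x_k^T)) with element-wise product,
# normalized across the bag by a softmax; the meta-instance is the attention-
# weighted sum M = sum_k a_k x_k, classified by a single fully connected
# layer with sigmoid output. V and U (L x D) are weight-normalized: each row
# is stored as a direction vector plus a strictly positive scale, and the
# effective row is scale * direction / ||direction||. Gradients are derived
# in closed form; Adam optimizes one bag per step.

#' Gated attention parameters
#'
#' Initializes the two gated attention layers (in weight-normalized storage)
#' and the attention head. Uses the caller's RNG state.
#'
#' @param d instance embedding dimension D.
#' @param l attention hidden dimension L (512 in the reference configuration
#'   where D = 1024).
#' @return an object of class `attention_params` with `V_dir`, `V_scale`,
#'   `U_dir`, `U_scale` (L x D directions, length-L scales) and `w` (L).
#' @export
attention_params <- function(d, l) {
  V <- matrix(rnorm(l * d, sd = sqrt(1 / d)), l, d)
  U <- matrix(rnorm(l * d, sd = sqrt(1 / d)), l, d)
  structure(list(
    V_dir = V, V_scale = sqrt(rowSums(V * V)),
    U_dir = U, U_scale = sqrt(rowSums(U * U)),
    w = matrix(rnorm(l, sd = sqrt(1 / l)), l, 1)
  ), class = "attention_params")
}

# Effective weight matrix from weight-normalized storage.
wn_effective <- function(dir, scale) {
  dir * (scale / sqrt(rowSums(dir * dir)))
}

# Backward through the weight-norm reparameterization: given dW (gradient
# w.r.t. the effective matrix), return gradients w.r.t. direction and scale.
wn_backward <- function(dir, scale, dW) {
  nrm <- sqrt(rowSums(dir * dir))
  unit <- dir / nrm
  dscale <- rowSums(dW * unit)
  ddir <- (scale / nrm) * (dW - unit * dscale)
  list(ddir = ddir, dscale = dscale)
}

#' Gated attention weights for a bag
#'
#' Softmax-normalized gated attention: `a_k = softmax_k(w^T (tanh(V x_k^T)
#' \* sigm(U x_k^T)))`, stabilized by max-subtraction before exponentiation.
#'
#' @param bag a `mil_bag` or a K x D instance matrix.
#' @param params an [attention_params()].
#' @return numeric vector `a` of length K on the probability simplex.
#' @export
attention_weights <- function(bag, params) {
  x <- if (inherits(bag, "mil_bag")) bag$instances else as.matrix(bag)
  if (!nrow(x)) stop("bag is empty")
  V <- wn_effective(params$V_dir, params$V_scale)
  U <- wn_effective(params$U_dir, params$U_scale)
  if (ncol(x) != ncol(V)) stop("instance dimension ", ncol(x),
                               " does not match attention D = ", ncol(V))
  z <- drop((tanh(x %*% t(V)) * sigmoid(x %*% t(U))) %*% params$w)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Attention-pool a bag into its meta-instance
#'
#' `M = sum_k a_k x_k`, a convex combination of the bag's instances.
#'
#' @param bag a `mil_bag` or K x D matrix.
#' @param a attention weights (nonnegative, summing to 1 within 1e-6).
#' @return 1 x D meta-instance matrix.
#' @export
attention_pool <- function(bag, a) {
  x <- if (inherits(bag, "mil_bag")) bag$instances else as.matrix(bag)
  if (length(a) != nrow(x)) stop("length(a) must equal the bag size")
  if (any(a < -1e-9) || abs(sum(a) - 1) > 1e-6)
    stop("attention weights must lie on the probability simplex")
  matrix(drop(crossprod(x, a)), 1, ncol(x))
}

#' MIL training configuration
#'
#' @param l attention hidden dimension; default 512 when D = 1024 (the
#'   reference configuration), otherwise D/2.
#' @param learning_rate Adam learning rate (default 0.0002).
#' @param max_epochs maximum epochs (default 150).
#' @param early_stop_patience epochs without strict monitor improvement
#'   before stopping (default 15; ties never reset it). The checkpoint kept
#'   is the epoch with the best monitor value, ties broken by lower mean
#'   training loss.
#' @param monitor `"validation_accuracy"` (requires validation bags) or
#'   `"training_accuracy"`.
#' @param n_restarts independent random initializations; the model kept is
#'   the restart with the best monitor value (ties broken by lower training
#'   loss at the checkpoint). Small-cohort MIL is initialization-sensitive —
#'   an occasional start never leaves the flat plateau within the patience
#'   window, which the monitor itself flags — so a few restarts make
#'   training robust. Restarting stops early once a run attains the maximal
#'   monitor value. Default 1 (single run).
#' @param seed RNG seed for initialization and bag shuffling.
#' @return an object of class `mil_config`.
#' @export
mil_config <- function(l = NULL, learning_rate = 2e-4, max_epochs = 150L,
                       early_stop_patience = 15L,
                       monitor = c("validation_accuracy", "training_accuracy"),
                       n_restarts = 1L, seed = 1L) {
  monitor <- match.arg(monitor)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (early_stop_patience >= max_epochs)
    stop("early_stop_patience must be < max_epochs")
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  structure(list(l = l, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 monitor = monitor, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "mil_config")
}

default_attention_l <- function(d) if (d == 1024L) 512L else max(2L, d %/% 2L)

# Construct a MIL model (attention + linear classifier head) with fresh
# parameters; uses the caller's RNG state.
mil_init_model <- function(d, l = NULL, config = NULL) {
  if (is.null(l)) l <- default_attention_l(d)
  structure(list(
    attention = attention_params(d, l),
    classifier = list(w = matrix(rnorm(d, sd = sqrt(1 / d)), d, 1), b = 0),
    d = as.integer(d), l = as.integer(l), config = config, trained = FALSE
  ), class = "mil_model")
}

#' Classify a meta-instance
#'
#' Applies the fully connected classifier head and sigmoid; the slide is
#' called high risk when the probability reaches the 0.5 threshold.
#'
#' @param meta 1 x D meta-instance.
#' @param model a `mil_model`.
#' @return probability in (0, 1).
#' @export
classify <- function(meta, model) {
  if (is.null(model$classifier) || is.null(model$classifier$w))
    stop("model has no classifier head (untrained model?)")
  meta <- matrix(meta, 1)
  if (ncol(meta) != model$d)
    stop("meta-instance dimension does not match the model")
  drop(sigmoid(meta %*% model$classifier$w + model$classifier$b))
}

#' Predict a slide from its bag
#'
#' @param model a trained `mil_model`.
#' @param bag a `mil_bag`.
#' @return list with `slide_id`, `probability`, `predicted_label`,
#'   `attention` (aligned to bag rows), `meta_instance`, `refs`.
#' @export
predict_slide <- function(model, bag) {
  x <- bag$instances
  if (ncol(x) != model$d)
    stop("bag dimension ", ncol(x), " does not match model D = ", model$d)
  a <- attention_weights(x, model$attention)
  m <- attention_pool(x, a)
  p <- classify(m, model)
  list(slide_id = bag$slide_id, probability = p,
       predicted_label = as.integer(p >= 0.5), attention = a,
       meta_instance = m, refs = bag$refs)
}

# Forward + closed-form gradients of the single-bag BCE loss with respect to
# every stored parameter (weight-norm directions/scales, attention head w,
# classifier w and b). Returns the loss, probability, attention, and grads.
mil_bag_gradients <- function(model, bag, y) {
  x <- if (inherits(bag, "mil_bag")) bag$instances else as.matrix(bag)
  at <- model$attention
  V <- wn_effective(at$V_dir, at$V_scale)
  U <- wn_effective(at$U_dir, at$U_scale)
  H <- x %*% t(V)          # K x L
  G <- x %*% t(U)
  Tm <- tanh(H)
  S <- sigmoid(G)
  Z <- Tm * S
  z <- drop(Z %*% at$w)
  e <- exp(z - max(z))
  a <- e / sum(e)
  M <- drop(crossprod(x, a))            # D
  logit <- sum(M * model$classifier$w) + model$classifier$b
  p <- sigmoid(logit)
  loss <- bce_loss(p, y)

  dlogit <- p - y
  dwc <- matrix(M * dlogit, ncol = 1)
  dbc <- dlogit
  dM <- drop(model$classifier$w) * dlogit          # D
  da <- drop(x %*% dM)                             # K
  dz <- a * (da - sum(a * da))                     # softmax backward
  dw <- matrix(drop(crossprod(Z, dz)), ncol = 1)   # L
  dZ <- dz %*% t(at$w)                             # K x L
  dH <- dZ * S * (1 - Tm * Tm)
  dG <- dZ * Tm * S * (1 - S)
  dV <- crossprod(dH, x)                           # L x D
  dU <- crossprod(dG, x)
  gv <- wn_backward(at$V_dir, at$V_scale, dV)
  gu <- wn_backward(at$U_dir, at$U_scale, dU)
  list(loss = loss, probability = p, attention = a,
       grads = list(V_dir = gv$ddir, V_scale = gv$dscale,
                    U_dir = gu$ddir, U_scale = gu$dscale,
                    w = dw, cls_w = dwc, cls_b = dbc))
}

mil_flatten_params <- function(model) {
  list(V_dir = model$attention$V_dir, V_scale = model$attention$V_scale,
       U_dir = model$attention$U_dir, U_scale = model$attention$U_scale,
       w = model$attention$w, cls_w = model$classifier$w,
       cls_b = model$classifier$b)
}

mil_unflatten_params <- function(model, params) {
  model$attention$V_dir <- params$V_dir
  model$attention$V_scale <- params$V_scale
  model$attention$U_dir <- params$U_dir
  model$attention$U_scale <- params$U_scale
  model$attention$w <- params$w
  model$classifier$w <- params$cls_w
  model$classifier$b <- params$cls_b
  model
}

mil_accuracy <- function(model, bags) {
  preds <- vapply(bags, function(b) predict_slide(model, b)$probability,
                  numeric(1))
  labels <- vapply(bags, `[[`, integer(1), "label")
  mean((preds >= 0.5) == (labels == 1L))
}

#' Train the gated attention MIL model
#'
#' Jointly optimizes the attention layers (through the softmax and pooling)
#' and the classifier head by backpropagation of the per-bag binary
#' cross-entropy, one bag per Adam step. The early-stop monitor (validation
#' or training accuracy, per the configuration) is evaluated once per epoch;
#' training stops when it has not strictly improved for
#' `early_stop_patience` epochs (ties never reset the patience). The
#' checkpoint kept is the epoch attaining the best monitor value; among
#' monitor-tied epochs, the one with the lowest mean training loss.
#'
#' @param bags named list of training `mil_bag`s (labels inside the bags;
#'   both classes must be present).
#' @param config a [mil_config()].
#' @param validation_bags validation bags; required when the monitor is
#'   `"validation_accuracy"`.
#' @return a trained `mil_model` with `history` (per-epoch loss and monitor),
#'   `best_epoch`, `epochs_run`.
#' @export
train_mil <- function(bags, config = mil_config(), validation_bags = NULL) {
  labels <- vapply(bags, `[[`, integer(1), "label")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present among the training bags")
  if (config$monitor == "validation_accuracy" && !length(validation_bags))
    stop("monitor='validation_accuracy' requires validation bags")
  n_restarts <- if (is.null(config$n_restarts)) 1L else config$n_restarts
  best_run <- NULL
  for (r in seq_len(n_restarts)) {
    seed_r <- if (r == 1L) config$seed else slide_seed(config$seed, r)
    run <- train_mil_once(bags, labels, config, validation_bags, seed_r)
    if (is.null(best_run) || run$best_acc > best_run$best_acc ||
        (run$best_acc == best_run$best_acc &&
         run$best_loss < best_run$best_loss)) {
      best_run <- run
      best_run$model$restart <- r
    }
    if (best_run$best_acc >= 1) break  # no later restart can rank higher
  }
  best_run$model
}

train_mil_once <- function(bags, labels, config, validation_bags, seed) {
  d <- ncol(bags[[1]]$instances)
  set.seed(seed)
  model <- mil_init_model(d, config$l, config)
  params <- mil_flatten_params(model)
  opt <- adam_init(params)
  best <- list(acc = -Inf, loss = Inf, params = params, epoch = 0L,
               anchor = 0L)
  hist_loss <- hist_mon <- numeric(0)
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    losses <- numeric(0)
    for (i in sample.int(length(bags))) {
      model <- mil_unflatten_params(model, params)
      fg <- mil_bag_gradients(model, bags[[i]], labels[i])
      losses <- c(losses, fg$loss)
      st <- adam_step(params, fg$grads, opt, lr = config$learning_rate)
      params <- st$params; opt <- st$state
    }
    model <- mil_unflatten_params(model, params)
    mon <- if (config$monitor == "validation_accuracy")
      mil_accuracy(model, validation_bags) else mil_accuracy(model, bags)
    mloss <- mean(losses)
    hist_loss <- c(hist_loss, mloss)
    hist_mon <- c(hist_mon, mon)
    # Patience counts epochs since the last strict monitor improvement
    # (monitor ties never reset it). Among monitor-tied epochs the
    # checkpoint kept is the one with the lowest training loss, so the
    # saved model is the best-optimized one attaining the best accuracy.
    if (mon > best$acc) {
      best <- list(acc = mon, loss = mloss, params = params, epoch = epoch,
                   anchor = epoch)
    } else if (mon == best$acc && mloss < best$loss) {
      best$loss <- mloss; best$params <- params; best$epoch <- epoch
    }
    if (epoch - best$anchor >= config$early_stop_patience) break
    if (epoch >= config$max_epochs) break
  }
  model <- mil_unflatten_params(model, best$params)
  model$trained <- TRUE
  model$history <- list(loss = hist_loss, monitor = hist_mon)
  model$best_epoch <- best$epoch
  model$epochs_run <- epoch
  list(model = model, best_acc = best$acc, best_loss = best$loss)
}

#' Save / load a MIL model checkpoint
#'
#' @param model a `mil_model`.
#' @param path checkpoint file.
#' @export
save_mil <- function(model, path) {
  cfg <- if (is.null(model$config)) NULL else unclass(model$config)
  saveRDS(list(format = "attnmil-mil-v1", model = model,
               config_json = jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                              digits = NA, null = "null")),
          path)
  invisible(path)
}

#' @rdname save_mil
#' @export
load_mil <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "attnmil-mil-v1"))
    stop("not an attnmil MIL checkpoint: ", path)
  obj$model
}
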