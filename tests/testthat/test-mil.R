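# Gated attention MIL: pooling algebra, oracle agreement, gradients,
# weight normalization, and training contracts.

random_attention_setup <- function(k = NULL, d = NULL, l = NULL) {
  if (is.null(k)) k <- sample(1:8, 1)
  if (is.null(d)) d <- sample(2:16, 1)
  if (is.null(l)) l <- sample(2:8, 1)
  list(x = matrix(rnorm(k * d), k, d), params = attention_params(d, l))
}

test_that("attention agrees with the direct element-wise oracle", {
  set.seed(30)
  worst <- 0
  for (rep in 1:1000) {
    su <- random_attention_setup()
    a <- attention_weights(su$x, su$params)
    V <- attnmil:::wn_effective(su$params$V_dir, su$params$V_scale)
    U <- attnmil:::wn_effective(su$params$U_dir, su$params$U_scale)
    a0 <- gated_attention_direct(su$x, V, U, drop(su$params$w))
    worst <- max(worst, max(abs(a - a0)))
    expect_equal(sum(a), 1, tolerance = 1e-6)
  }
  expect_lte(worst, 1e-6)
})

test_that("attention softmax limits: singleton and identical instances", {
  set.seed(31)
  su <- random_attention_setup(k = 1)
  expect_equal(attention_weights(su$x, su$params), 1)
  d <- 6; x1 <- matrix(rnorm(d), 1, d)
  params <- attention_params(d, 4)
  xk <- x1[rep(1, 5), , drop = FALSE]
  expect_equal(attention_weights(xk, params), rep(1 / 5, 5), tolerance = 1e-12)
  expect_error(attention_weights(matrix(rnorm(8), 2, 4), params), "dimension")
  expect_error(attention_weights(matrix(0, 0, d), params), "empty")
})

test_that("attention pooling is a convex combination of the instances", {
  set.seed(32)
  # identical instances: M = x for any simplex weights
  x1 <- matrix(rnorm(6), 1, 6)
  xk <- x1[rep(1, 4), ]
  a <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(drop(attention_pool(xk, a)), drop(x1))
  # one-hot: M = x_k
  x <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(drop(attention_pool(x, c(0, 0, 1, 0, 0))), x[3, ])
  expect_error(attention_pool(x, c(0.5, 0.5, 0.5, 0, 0)), "simplex")
  expect_error(attention_pool(x, c(0.5, 0.5)), "bag size")
  # support-function hull oracle: for every direction u,
  # min_k u.x_k <= u.M <= max_k u.x_k
  for (rep in 1:50) {
    k <- sample(2:8, 1); d <- sample(2:10, 1)
    x <- matrix(rnorm(k * d), k, d)
    a <- as.vector(stats::rexp(k)); a <- a / sum(a)
    m <- drop(attention_pool(x, a))
    for (j in 1:100) {
      u <- rnorm(d)
      proj <- x %*% u
      expect_lte(sum(m * u), max(proj) + 1e-9)
      expect_gte(sum(m * u), min(proj) - 1e-9)
    }
  }
})

test_that("the classifier head is a calibrated sigmoid", {
  set.seed(33)
  model <- attnmil:::mil_init_model(6, 4)
  model$classifier$w <- matrix(0, 6, 1); model$classifier$b <- 0
  meta <- matrix(rnorm(6), 1)
  expect_equal(classify(meta, model), 0.5)
  expect_identical(classify(meta, model), classify(meta, model))
  # strictly increasing in the logit
  model$classifier$w <- matrix(1, 6, 1)
  m1 <- matrix(rep(0.1, 6), 1); m2 <- matrix(rep(0.2, 6), 1)
  expect_gt(classify(m2, model), classify(m1, model))
  broken <- model; broken$classifier <- NULL
  expect_error(classify(meta, broken), "classifier")
  expect_error(classify(matrix(0, 1, 3), model), "dimension")
})

test_that("predictions are permutation and duplication invariant", {
  set.seed(34)
  for (rep in 1:20) {
    su <- random_attention_setup(k = sample(3:8, 1))
    model <- attnmil:::mil_init_model(ncol(su$x), 4)
    model$attention <- su$params
    refs <- data.frame(slide_id = "s", x = seq_len(nrow(su$x)) * 10L,
                       y = 0L, size = 10L)
    bag <- attnmil:::new_bag("s", su$x, refs, 1L)
    base <- predict_slide(model, bag)
    for (sh in 1:100) {
      perm <- sample(nrow(su$x))
      pbag <- attnmil:::new_bag("s", su$x[perm, , drop = FALSE],
                                refs[perm, ], 1L)
      pp <- predict_slide(model, pbag)
      expect_equal(pp$probability, base$probability, tolerance = 1e-6)
      expect_equal(pp$attention, base$attention[perm], tolerance = 1e-6)
    }
    # duplicating every instance halves each weight, M and p unchanged
    dbag <- attnmil:::new_bag("s", su$x[rep(seq_len(nrow(su$x)), 2), , drop = FALSE],
                              refs[rep(seq_len(nrow(su$x)), 2), ], 1L)
    dp <- predict_slide(model, dbag)
    expect_equal(dp$probability, base$probability, tolerance = 1e-6)
    expect_equal(dp$meta_instance, base$meta_instance, tolerance = 1e-6)
    expect_equal(dp$attention, rep(base$attention / 2, 2), tolerance = 1e-6)
  }
})

test_that("analytic bag-loss gradients match finite differences", {
  set.seed(35)
  for (rep in 1:5) {
    k <- sample(2:6, 1); d <- sample(3:8, 1); l <- sample(2:6, 1)
    x <- matrix(rnorm(k * d), k, d)
    y <- sample(0:1, 1)
    model <- attnmil:::mil_init_model(d, l)
    fg <- attnmil:::mil_bag_gradients(model, x, y)
    pars <- attnmil:::mil_flatten_params(model)
    lossfn <- function(pp)
      attnmil:::mil_bag_gradients(attnmil:::mil_unflatten_params(model, pp),
                                  x, y)$loss
    for (nm in names(pars)) {
      for (probe in seq_len(min(4, length(pars[[nm]])))) {
        i <- sample(length(pars[[nm]]), 1)
        eps <- 1e-6
        p1 <- pars; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- pars; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
        an <- fg$grads[[nm]][i]
        if (abs(num) > 1e-8) {
          expect_lte(abs(an - num) / abs(num), 1e-4)
        } else {
          expect_lte(abs(an - num), 1e-8)
        }
      }
    }
  }
})

test_that("weight normalization is preserved through optimization", {
  set.seed(36)
  bags <- make_embedding_bags(n_per_class = 5, k = 6, d = 8)
  cfg <- mil_config(learning_rate = 1e-3, max_epochs = 5,
                    early_stop_patience = 3, monitor = "training_accuracy",
                    seed = 1)
  model <- train_mil(bags, cfg)
  for (side in c("V", "U")) {
    dir <- model$attention[[paste0(side, "_dir")]]
    scale <- model$attention[[paste0(side, "_scale")]]
    eff <- attnmil:::wn_effective(dir, scale)
    # every effective row reconstructs as scale x unit-direction
    expect_lte(max(abs(sqrt(rowSums(eff^2)) - abs(scale))), 1e-6)
    unit <- dir / sqrt(rowSums(dir^2))
    expect_lte(max(abs(eff - unit * scale)), 1e-6)
    expect_true(all(scale > 0))
  }
})

test_that("MIL training fits separable bags and honors its contracts", {
  set.seed(37)
  bags <- make_embedding_bags(n_per_class = 10, k = 8, d = 12)
  cfg <- mil_config(learning_rate = 2e-3, max_epochs = 60,
                    early_stop_patience = 15, monitor = "training_accuracy",
                    seed = 2)
  model <- train_mil(bags, cfg)
  expect_gte(attnmil:::mil_accuracy(model, bags), 0.95)
  # patience 0: exactly one epoch
  cfg0 <- mil_config(max_epochs = 5, early_stop_patience = 0,
                     monitor = "training_accuracy", seed = 3)
  expect_equal(train_mil(bags, cfg0)$epochs_run, 1L)
  # fixed seed: reproducible loss trace
  cfgr <- mil_config(learning_rate = 1e-3, max_epochs = 8,
                     early_stop_patience = 5, monitor = "training_accuracy",
                     seed = 4)
  expect_identical(train_mil(bags, cfgr)$history$loss,
                   train_mil(bags, cfgr)$history$loss)
  # degenerate inputs
  pos_only <- Filter(function(b) b$label == 1L, bags)
  expect_error(train_mil(pos_only, cfgr), "both classes")
  cfgv <- mil_config(monitor = "validation_accuracy", seed = 5)
  expect_error(train_mil(bags, cfgv), "validation bags")
})

test_that("MIL checkpoints round-trip through disk", {
  set.seed(38)
  bags <- make_embedding_bags(n_per_class = 4, k = 5, d = 6)
  cfg <- mil_config(learning_rate = 1e-3, max_epochs = 4,
                    early_stop_patience = 2, monitor = "training_accuracy",
                    seed = 6)
  model <- train_mil(bags, cfg)
  path <- tempfile(fileext = ".rds")
  save_mil(model, path)
  back <- load_mil(path)
  expect_equal(predict_slide(back, bags[[1]]),
               predict_slide(model, bags[[1]]))
})
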