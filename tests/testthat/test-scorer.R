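# Patch scorer: discrimination score, weak-label training set, CNN training
# contracts, and slide scoring.

test_that("discrimination score matches its closed form", {
  expect_equal(discrimination_score(0.5), 0)
  expect_equal(discrimination_score(0), 1)
  expect_equal(discrimination_score(1), 1)
  expect_equal(discrimination_score(0.3), 0.4)
  grid <- seq(0, 1, length.out = 101)
  expect_equal(discrimination_score(grid), discrimination_score(1 - grid))
  expect_true(all(discrimination_score(grid) >= 0 &
                    discrimination_score(grid) <= 1))
  expect_error(discrimination_score(1.2), "\\[0, 1\\]")
  expect_error(discrimination_score(-0.1), "\\[0, 1\\]")
})

test_that("weak-label patch training sets sample per slide, capped, seeded", {
  slides <- load_cohort(shared_cohort_dir())
  manifest <- tile_cohort(slides, 24L)
  ts <- build_patch_training_set(slides, manifest, per_slide = 4, seed = 1)
  expect_equal(nrow(ts), 4L * length(slides))
  expect_equal(as.integer(table(ts$slide_id)), rep(4L, length(slides)))
  # labels are the slide-level labels
  lab <- setNames(vapply(slides, `[[`, integer(1), "label"),
                  vapply(slides, `[[`, character(1), "slide_id"))
  expect_equal(ts$label, unname(lab[ts$slide_id]))
  # capped sampling: more requested than available -> all, no duplicates
  full <- build_patch_training_set(slides, manifest, per_slide = 1000, seed = 1)
  expect_equal(nrow(full), nrow(manifest))
  expect_false(any(duplicated(full[, c("slide_id", "x", "y")])))
  # deterministic under seed
  expect_identical(ts, build_patch_training_set(slides, manifest, 4, seed = 1))
  expect_error(build_patch_training_set(slides, manifest[0, ], 4, 1), "empty")
})

make_toy_patches <- function(n_per_class = 12, s = 16L) {
  x <- array(0, dim = c(s, s, 3, 2 * n_per_class))
  for (i in seq_len(n_per_class)) {
    x[, , , i] <- 40 + rnorm(s * s * 3, sd = 5)                 # dark
    x[, , , n_per_class + i] <- 210 + rnorm(s * s * 3, sd = 5)  # bright
  }
  list(x = pmin(pmax(x, 0), 255), y = rep(c(0L, 1L), each = n_per_class))
}

test_that("the scorer fits linearly separable toy patches to accuracy 1", {
  set.seed(10)
  toy <- make_toy_patches()
  cfg <- scorer_config(embed_dim = 8, max_epochs = 40, early_stop_patience = 10,
                       learning_rate = 2e-3, batch_size = 8, seed = 3)
  model <- train_scorer(toy$x, toy$y, cfg)
  expect_equal(max(model$history$accuracy), 1)
  expect_lte(model$epochs_run, 40L)
})

test_that("training contracts: patience boundary, determinism, degeneracy", {
  set.seed(11)
  toy <- make_toy_patches(6)
  cfg <- scorer_config(embed_dim = 8, max_epochs = 5, early_stop_patience = 0,
                       batch_size = 8, seed = 4)
  m <- train_scorer(toy$x, toy$y, cfg)
  expect_equal(m$epochs_run, 1L)  # patience 0: exactly one epoch
  cfg2 <- scorer_config(embed_dim = 8, max_epochs = 6, early_stop_patience = 3,
                        batch_size = 8, seed = 5)
  m1 <- train_scorer(toy$x, toy$y, cfg2)
  m2 <- train_scorer(toy$x, toy$y, cfg2)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)
  expect_error(train_scorer(toy$x, rep(1L, length(toy$y)), cfg2),
               "both classes")
  expect_error(scorer_config(early_stop_patience = 150, max_epochs = 150),
               "patience")
})

test_that("the reference backbone is declared but needs external weights", {
  cfg <- scorer_config("paper_backbone")
  expect_equal(cfg$embed_dim, 1024L)
  toy <- make_toy_patches(2)
  expect_error(train_scorer(toy$x, toy$y, cfg), "pretrained")
})

test_that("score_slide composes probability and DS deterministically", {
  set.seed(12)
  slides <- load_cohort(shared_cohort_dir())
  manifest <- tile_cohort(slides, 24L)
  cfg <- scorer_config(embed_dim = 8, max_epochs = 3, early_stop_patience = 2,
                       patches_per_slide = 9, batch_size = 8, seed = 6)
  model <- fit_scorer(slides, manifest, cfg)
  sc1 <- score_slide(model, slides[[1]], manifest)
  sc2 <- score_slide(model, slides[[1]], manifest)
  expect_identical(sc1, sc2)
  expect_equal(sc1$ds, discrimination_score(sc1$probability))
  expect_true(all(sc1$ds >= 0 & sc1$ds <= 1))
  expect_equal(nrow(sc1), sum(manifest$slide_id == slides[[1]]$slide_id))
  # batch evaluation order does not affect values
  probs_small <- attnmil:::scorer_probability(
    model, attnmil:::load_patches(slides, sc1[, 1:4]), batch_size = 3)
  expect_equal(probs_small, sc1$probability, tolerance = 1e-12)
  other <- slides[[2]]
  expect_error(score_slide(model, other, manifest[manifest$slide_id ==
                                                    slides[[1]]$slide_id, ]),
               "no patches")
})

test_that("scorer checkpoints round-trip through disk", {
  set.seed(13)
  toy <- make_toy_patches(4)
  cfg <- scorer_config(embed_dim = 8, max_epochs = 3, early_stop_patience = 2,
                       batch_size = 8, seed = 7)
  model <- train_scorer(toy$x, toy$y, cfg)
  path <- tempfile(fileext = ".rds")
  save_scorer(model, path)
  back <- load_scorer(path)
  expect_equal(back$params, model$params)
  expect_equal(attnmil:::scorer_probability(back, toy$x),
               attnmil:::scorer_probability(model, toy$x))
})

test_that("the scorer separates synthetic density classes (patch-level AUC)", {
  aucs <- ds_gaps <- numeric(2)
  for (s in 1:2) {
    dir <- file.path(tempdir(), paste0("sc-auc-", s))
    cfg <- cohort_config(n_slides_per_class = 8, patches_per_slide = 16,
                         positive_instance_fraction = 0.4,
                         patch_size_px = 32, seed = 60 + s)
    if (!dir.exists(dir)) generate_cohort(cfg, dir)
    slides <- load_cohort(dir)
    manifest <- tile_cohort(slides, 32L)
    scfg <- scorer_config(max_epochs = 10, early_stop_patience = 6,
                          patches_per_slide = 16, seed = s)
    model <- fit_scorer(slides, manifest, scfg)
    scores <- do.call(rbind, lapply(slides, function(sl)
      score_slide(model, sl, manifest)))
    truth <- read.csv(file.path(dir, "truth_sidecar.csv"))
    key <- function(df) paste(df$slide_id, df$x, df$y)
    kind <- truth[match(key(scores), key(truth)), "kind"]
    aucs[s] <- auc_mann_whitney(kind == "discriminative_positive",
                                scores$probability)
    ds_gaps[s] <- mean(scores$ds[kind != "nondiscriminative"]) -
      mean(scores$ds[kind == "nondiscriminative"])
  }
  expect_gte(mean(aucs), 0.9)   # probability ranks true dense patches highly
  expect_gt(mean(ds_gaps), 0)   # discriminative patches get higher DS
})
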