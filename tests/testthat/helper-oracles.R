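# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Even-odd ray-crossing point-in-polygon test (horizontal ray to +x).
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# O(n^2) pairwise AUC with half-credit for ties.
auc_pairwise <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Direct, unstabilized evaluation of the gated attention weights:
# element-by-element loops, plain exp ratio.
gated_attention_direct <- function(x, V, U, w) {
  k <- nrow(x); l <- nrow(V)
  z <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (j in seq_len(l)) {
      hv <- sum(V[j, ] * x[i, ])
      hu <- sum(U[j, ] * x[i, ])
      acc <- acc + w[j] * tanh(hv) * (1 / (1 + exp(-hu)))
    }
    z[i] <- acc
  }
  exp(z) / sum(exp(z))
}

# Random convex polygon (simple by construction) around a center.
random_convex_polygon <- function(cx, cy, rmin, rmax, n_vertices = 7) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, rmin, rmax)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# Bags in embedding space: positive bags carry a cluster of shifted-mean
# instances; negatives are pure noise.
make_embedding_bags <- function(n_per_class = 10, k = 8, d = 12,
                                shift = 2.5, n_pos_instances = 3) {
  bags <- list()
  for (i in seq_len(2 * n_per_class)) {
    label <- as.integer(i > n_per_class)
    x <- matrix(rnorm(k * d), k, d)
    if (label == 1L)
      x[seq_len(n_pos_instances), ] <- x[seq_len(n_pos_instances), ] + shift
    refs <- data.frame(slide_id = sprintf("bag_%02d", i),
                       x = (seq_len(k) - 1L) * 10L, y = 0L, size = 10L)
    bags[[i]] <- attnmil:::new_bag(sprintf("bag_%02d", i), x, refs, label)
  }
  names(bags) <- vapply(bags, `[[`, character(1), "slide_id")
  bags
}

# Shared tiny cohort on disk, built once per test run.
shared_cohort_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "attnmil-shared-cohort")
      if (!dir.exists(dir)) {
        cfg <- cohort_config(n_slides_per_class = 3, patches_per_slide = 9,
                             positive_instance_fraction = 0.4,
                             patch_size_px = 24, seed = 99)
        generate_cohort(cfg, dir)
      }
    }
    dir
  }
})

# Attention gap between true discriminative-positive instances and the rest,
# averaged over an experiment's positive slides and fold models.
attention_gap <- function(experiment, truth) {
  key <- function(df) paste(df$slide_id, df$x, df$y)
  fold_gaps <- vapply(experiment$attention, function(att) {
    gaps <- vapply(Filter(function(a) a$label == 1L, att), function(a) {
      kind <- truth[match(key(a$refs), key(truth)), "kind"]
      pos <- kind == "discriminative_positive"
      if (!any(pos) || all(pos)) return(NA_real_)
      mean(a$attention[pos]) - mean(a$attention[!pos])
    }, numeric(1))
    mean(gaps, na.rm = TRUE)
  }, numeric(1))
  mean(fold_gaps)
}
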