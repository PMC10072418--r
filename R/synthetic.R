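#' Patch specification for the synthetic generator
#'
#' Describes one synthetic patch kind. Discriminative-positive patches carry a
#' higher expected density of disc-shaped "stained" blobs than
#' discriminative-negative ones, emulating the proliferating-cell density
#' contrast between high- and low-risk tissue; nondiscriminative patches draw
#' their blob count from a mixture straddling both class densities; background
#' patches carry no blobs at all.
#'
#' @param kind one of `"discriminative_positive"`, `"discriminative_negative"`,
#'   `"nondiscriminative"`, `"background"`.
#' @param size_px side of the square patch in pixels (> 0).
#' @param blob_density expected number of blobs per patch (Poisson mean).
#' @param noise_sd standard deviation of additive Gaussian pixel noise, on the
#'   0-255 intensity scale.
#' @return an object of class `patch_spec`.
#' @export
patch_spec <- function(kind = c("discriminative_positive",
                                "discriminative_negative",
                                "nondiscriminative", "background"),
                       size_px = 64L, blob_density = 0, noise_sd = 8) {
  kind <- match.arg(kind)
  size_px <- as.integer(size_px)
  if (is.na(size_px) || size_px <= 0L)
    stop("size_px must be a positive integer, got ", size_px)
  if (blob_density < 0) stop("blob_density must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(kind = kind, size_px = size_px,
                 blob_density = blob_density, noise_sd = noise_sd),
            class = "patch_spec")
}

#' Cohort configuration for the synthetic generator
#'
#' Defines a weakly labeled two-class cohort. Positive (high-risk) slides mix
#' discriminative-positive patches with negative-looking and nondiscriminative
#' ones; negative (low-risk) slides never contain a discriminative-positive
#' patch — the standard MIL bag assumption.
#'
#' @param n_slides_per_class slides per class.
#' @param patches_per_slide tumor-region (ROI) patches per slide.
#' @param positive_instance_fraction fraction of a positive slide's ROI patches
#'   that are discriminative-positive, in (0, 1].
#' @param nondiscriminative_fraction fraction of ROI patches (both classes)
#'   that are nondiscriminative, in \[0, 1).
#' @param background_margin_patches width of the background margin around the
#'   ROI, in patch units.
#' @param patch_size_px pixel side of each generated patch.
#' @param density_pos,density_neg expected blob counts of discriminative
#'   positive/negative patches (`density_pos > density_neg`).
#' @param noise_sd pixel noise standard deviation (0-255 scale).
#' @param seed root RNG seed; per-slide substreams are derived from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_slides_per_class = 10L, patches_per_slide = 16L,
                          positive_instance_fraction = 0.3,
                          nondiscriminative_fraction = 0.2,
                          background_margin_patches = 1L,
                          patch_size_px = 64L,
                          density_pos = 12, density_neg = 3,
                          noise_sd = 8, seed = 1L) {
  if (n_slides_per_class < 1L) stop("n_slides_per_class must be >= 1")
  if (patches_per_slide < 1L) stop("patches_per_slide must be >= 1")
  if (positive_instance_fraction <= 0 || positive_instance_fraction > 1)
    stop("positive_instance_fraction must be in (0, 1]")
  if (nondiscriminative_fraction < 0 || nondiscriminative_fraction >= 1)
    stop("nondiscriminative_fraction must be in [0, 1)")
  if (positive_instance_fraction + nondiscriminative_fraction > 1)
    stop("positive_instance_fraction + nondiscriminative_fraction must be <= 1")
  if (density_pos <= density_neg)
    stop("density_pos must exceed density_neg")
  structure(list(
    n_slides_per_class = as.integer(n_slides_per_class),
    patches_per_slide = as.integer(patches_per_slide),
    positive_instance_fraction = positive_instance_fraction,
    nondiscriminative_fraction = nondiscriminative_fraction,
    background_margin_patches = as.integer(background_margin_patches),
    patch_size_px = as.integer(patch_size_px),
    density_pos = density_pos, density_neg = density_neg,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Per-slide RNG substream: a documented counter scheme so each slide's pixels
# are reproducible independently of generation order.
slide_seed <- function(root_seed, slide_index) {
  as.integer((as.double(root_seed) * 10007 + slide_index) %% 2147483647)
}

# Tissue / background / blob palette (0-255). Blobs are brown-like, mimicking
# chromogen-stained proliferating cells; tissue is a pale pink counterstain.
.col_tissue <- c(232, 203, 212)
.col_background <- c(246, 246, 244)
.col_blob <- c(135, 85, 50)

#' Generate one synthetic patch
#'
#' Renders a single patch image from a [patch_spec()] using the current RNG
#' state. Discriminative patches draw `Poisson(blob_density)` anti-aliased
#' brown discs (radius 5-10% of the side) over a noisy tissue background;
#' nondiscriminative patches draw their count from a Poisson whose mean is
#' uniform between the two class densities; background patches are uniform
#' bright tissue-free pixels plus noise.
#'
#' @param spec a [patch_spec()].
#' @param density_pos,density_neg class densities used only for
#'   `kind = "nondiscriminative"` mixture draws.
#' @return numeric array `size_px x size_px x 3` in \[0, 255\], with attribute
#'   `n_blobs` recording the ground-truth blob count.
#' @export
generate_patch <- function(spec, density_pos = 12, density_neg = 3) {
  if (!inherits(spec, "patch_spec")) spec <- do.call(patch_spec, spec)
  s <- spec$size_px
  base <- if (spec$kind == "background") .col_background else .col_tissue
  img <- array(rep(base, each = s * s), dim = c(s, s, 3))
  n_blobs <- switch(spec$kind,
    background = 0L,
    discriminative_positive = rpois(1L, spec$blob_density),
    discriminative_negative = rpois(1L, spec$blob_density),
    nondiscriminative = {
      # ambiguity band: blob intensity drawn from the central range between
      # the class densities, so the patch is genuinely hard to attribute
      lo <- min(density_neg, density_pos); hi <- max(density_neg, density_pos)
      rpois(1L, runif(1L, lo + 0.25 * (hi - lo), lo + 0.75 * (hi - lo)))
    }
  )
  if (n_blobs > 0L) {
    xs <- runif(n_blobs, 1, s)
    ys <- runif(n_blobs, 1, s)
    rs <- runif(n_blobs, 0.05 * s, 0.10 * s)
    gx <- matrix(seq_len(s), s, s, byrow = TRUE)  # column coordinate
    gy <- matrix(seq_len(s), s, s)                # row coordinate
    for (b in seq_len(n_blobs)) {
      dist <- sqrt((gx - xs[b])^2 + (gy - ys[b])^2)
      alpha <- pmin(pmax(rs[b] + 0.5 - dist, 0), 1)  # anti-aliased edge
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] * (1 - alpha) + .col_blob[ch] * alpha
      }
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + array(rnorm(s * s * 3, sd = spec$noise_sd), dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 255)
  dim(img) <- c(s, s, 3)
  attr(img, "n_blobs") <- n_blobs
  img
}

# ROI lattice geometry: nc columns, full rows plus a possibly partial last
# row, so any patches_per_slide maps to a rectilinear ROI polygon.
roi_layout <- function(n_patches) {
  nc <- ceiling(sqrt(n_patches))
  full <- n_patches %/% nc
  rem <- n_patches - full * nc
  list(nc = as.integer(nc), full_rows = as.integer(full), rem = as.integer(rem),
       nr = as.integer(full + (rem > 0L)))
}

# ROI polygon in 0-based pixel coordinates given the lattice and origin.
roi_polygon <- function(layout, origin_px, s) {
  ox <- origin_px[1]; oy <- origin_px[2]
  if (layout$rem == 0L) {
    m <- rbind(c(0, 0), c(layout$nc * s, 0),
               c(layout$nc * s, layout$full_rows * s),
               c(0, layout$full_rows * s))
  } else {
    m <- rbind(c(0, 0), c(layout$nc * s, 0),
               c(layout$nc * s, layout$full_rows * s),
               c(layout$rem * s, layout$full_rows * s),
               c(layout$rem * s, (layout$full_rows + 1) * s),
               c(0, (layout$full_rows + 1) * s))
  }
  sweep(m, 2, c(ox, oy), "+")
}

# ROI cell origins (0-based, pixels), row-major over the lattice.
roi_cell_origins <- function(layout, origin_px, s) {
  rows <- integer(0); cols <- integer(0)
  if (layout$full_rows > 0L) {
    rows <- rep(seq_len(layout$full_rows) - 1L, each = layout$nc)
    cols <- rep(seq_len(layout$nc) - 1L, times = layout$full_rows)
  }
  if (layout$rem > 0L) {
    rows <- c(rows, rep(layout$full_rows, layout$rem))
    cols <- c(cols, seq_len(layout$rem) - 1L)
  }
  data.frame(x = origin_px[1] + cols * s, y = origin_px[2] + rows * s)
}

# Draw the per-patch kind assignment for one slide's ROI.
assign_kinds <- function(config, positive) {
  n <- config$patches_per_slide
  n_nd <- round(config$nondiscriminative_fraction * n)
  if (positive) {
    n_pos <- round(config$positive_instance_fraction * n)
    n_pos <- max(1L, min(n_pos, n - n_nd))
    kinds <- c(rep("discriminative_positive", n_pos),
               rep("nondiscriminative", n_nd),
               rep("discriminative_negative", n - n_pos - n_nd))
  } else {
    kinds <- c(rep("nondiscriminative", n_nd),
               rep("discriminative_negative", n - n_nd))
  }
  sample(kinds)
}

# Build one synthetic slide in memory. Returns the image, ROI polygon, and
# the per-cell truth table. Used by generate_cohort() and directly by tests.
generate_slide <- function(config, slide_id, positive, seed) {
  set.seed(seed)
  s <- config$patch_size_px
  m <- config$background_margin_patches
  lay <- roi_layout(config$patches_per_slide)
  W <- (lay$nc + 2L * m) * s
  H <- (lay$nr + 2L * m) * s
  img <- array(0, dim = c(H, W, 3))
  bg_spec <- patch_spec("background", size_px = s, noise_sd = config$noise_sd)
  for (r in seq_len(H / s) - 1L) {
    for (cc in seq_len(W / s) - 1L) {
      p <- generate_patch(bg_spec)
      img[r * s + 1:s, cc * s + 1:s, ] <- p
    }
  }
  kinds <- assign_kinds(config, positive)
  cells <- roi_cell_origins(lay, c(m * s, m * s), s)
  n_blobs <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    dens <- switch(kinds[i],
      discriminative_positive = config$density_pos,
      discriminative_negative = config$density_neg,
      nondiscriminative = 0)
    sp <- patch_spec(kinds[i], size_px = s, blob_density = dens,
                     noise_sd = config$noise_sd)
    p <- generate_patch(sp, config$density_pos, config$density_neg)
    n_blobs[i] <- attr(p, "n_blobs")
    img[cells$y[i] + 1:s, cells$x[i] + 1:s, ] <- p
  }
  truth <- data.frame(slide_id = slide_id, x = cells$x, y = cells$y,
                      kind = kinds, n_blobs = n_blobs,
                      stringsAsFactors = FALSE)
  list(slide_id = slide_id, image = img,
       polygon = roi_polygon(lay, c(m * s, m * s), s),
       label = as.integer(positive), truth = truth,
       patch_size = s)
}

#' Generate a synthetic weakly labeled cohort on disk
#'
#' Writes slide images (PNG or TIFF), per-slide GeoJSON ROI polygons, a
#' slide-level label table, and a ground-truth sidecar giving every ROI
#' patch's generative kind. The sidecar exists only for oracle testing; the
#' analysis pipeline never reads it (weak supervision).
#'
#' Regeneration with the same config is byte-identical: each slide uses an
#' RNG substream seeded by `slide_seed(config$seed, slide_index)`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @return invisibly, a data.frame of slide records (see [load_cohort()]).
#' @export
generate_cohort <- function(config, out_dir, format = c("png", "tiff")) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  n <- config$n_slides_per_class
  ids <- sprintf("slide_%03d", seq_len(2L * n))
  labels <- rep(c(0L, 1L), each = n)
  truth_all <- vector("list", 2L * n)
  records <- data.frame(slide_id = ids, label = labels,
                        image_path = file.path(out_dir, paste0(ids, ".", format)),
                        annotation_path = file.path(out_dir, "annotations",
                                                    paste0(ids, ".geojson")),
                        stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    sl <- generate_slide(config, ids[i], positive = labels[i] == 1L,
                         seed = slide_seed(config$seed, i))
    write_image(sl$image / 255, records$image_path[i], format)
    write_roi_geojson(sl$polygon, records$annotation_path[i],
                      slide_id = ids[i])
    truth_all[[i]] <- sl$truth
  }
  write.csv(records[, c("slide_id", "label")],
            file.path(out_dir, "labels.csv"), row.names = FALSE)
  truth <- do.call(rbind, truth_all)
  write.csv(truth[, c("slide_id", "x", "y", "kind")],
            file.path(out_dir, "truth_sidecar.csv"), row.names = FALSE)
  cfg <- config; class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(records)
}

#' Load a cohort directory into slide records
#'
#' @param dir a directory written by [generate_cohort()] (or following the
#'   same layout: `labels.csv` plus per-slide image and GeoJSON annotation).
#' @return a list of [slide_record()] objects.
#' @export
load_cohort <- function(dir) {
  labels <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$slide_id[i]
    img <- Filter(file.exists,
                  file.path(dir, paste0(id, c(".png", ".tiff", ".tif"))))[1]
    slide_record(slide_id = id, image_path = img,
                 roi_polygons = read_roi_geojson(
                   file.path(dir, "annotations", paste0(id, ".geojson"))),
                 label = labels$label[i], stain = "synthetic")
  })
}
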