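# Slide records, image/annotation I/O, and annotation-driven tiling.
# Coordinate convention used everywhere: 0-based pixel coordinates, x = column
# (rightwards), y = row (downwards), half-open patch windows
# [x, x + size) x [y, y + size). Fixed so attention heatmaps align exactly.

#' Slide record
#'
#' Binds a slide's image source, tumor-region (ROI) polygon annotations, and
#' binary risk label. Labels follow the recurrence-score cutoff rule used
#' throughout: score below 25 is low risk (0), 25 or above is high risk (1).
#'
#' @param slide_id character id.
#' @param image_path path to a PNG or TIFF image.
#' @param roi_polygons a single n x 2 matrix or a list of such matrices,
#'   closed simple polygons in 0-based pixel coordinates (x, y columns).
#' @param label 0 (low risk) or 1 (high risk).
#' @param stain `"HE"`, `"Ki67"`, or `"synthetic"`.
#' @return an object of class `slide_record`.
#' @export
slide_record <- function(slide_id, image_path, roi_polygons, label,
                         stain = c("synthetic", "HE", "Ki67")) {
  stain <- match.arg(stain)
  if (is.matrix(roi_polygons)) roi_polygons <- list(roi_polygons)
  if (!length(roi_polygons)) stop("slide ", slide_id, " has no ROI polygons")
  roi_polygons <- lapply(roi_polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("ROI polygons must be n x 2 matrices with n >= 3")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  structure(list(slide_id = slide_id, image_path = image_path,
                 roi_polygons = roi_polygons, label = as.integer(label),
                 stain = stain),
            class = "slide_record")
}

#' Label a slide from a recurrence score
#'
#' Applies the score cutoff rule: below `cutoff` is low risk (0), at or above
#' is high risk (1). Default cutoff 25.
#' @param score numeric recurrence score(s) in 0-100.
#' @param cutoff threshold, default 25.
#' @return integer vector of 0/1 labels.
#' @export
risk_label <- function(score, cutoff = 25) as.integer(score >= cutoff)

# ---- image I/O -------------------------------------------------------------

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

write_image <- function(img01, path, format = tolower(tools::file_ext(path))) {
  img01 <- pmin(pmax(img01, 0), 1)
  switch(format,
    png = png::writePNG(img01, path),
    tif = , tiff = tiff::writeTIFF(img01, path, bits.per.sample = 8L),
    stop("unsupported image format: ", format))
  invisible(path)
}

# ---- GeoJSON ROI annotations ----------------------------------------------

#' Write ROI polygons to a GeoJSON FeatureCollection
#'
#' Pixel coordinates, 0-based. Each polygon becomes one Feature; rings are
#' closed on write (first vertex repeated) per the GeoJSON convention.
#' @param polygons an n x 2 matrix or list of matrices (x, y columns).
#' @param path output file.
#' @param slide_id optional id stored in feature properties.
#' @export
write_roi_geojson <- function(polygons, path, slide_id = NULL) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  features <- lapply(polygons, function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = if (is.null(slide_id)) structure(list(), names = character(0))
                      else list(slide_id = slide_id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) c(ring[i, 1], ring[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROI polygons from a GeoJSON FeatureCollection
#'
#' Accepts Polygon and MultiPolygon geometries; only exterior rings are used.
#' @param path GeoJSON file.
#' @return list of n x 2 polygon matrices (closing vertex dropped).
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt)[1:2])))
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  }
  polys <- list()
  for (f in gj$features) {
    g <- f$geometry
    if (g$type == "Polygon") {
      polys <- c(polys, list(ring_to_matrix(g$coordinates[[1]])))
    } else if (g$type == "MultiPolygon") {
      polys <- c(polys, lapply(g$coordinates, function(p) ring_to_matrix(p[[1]])))
    } else stop("unsupported geometry type: ", g$type)
  }
  polys
}

# ---- tiling ----------------------------------------------------------------

point_in_polygons <- function(px, py, polygons) {
  inside <- rep(FALSE, length(px))
  pts <- cbind(px, py)
  for (poly in polygons) {
    inside <- inside | mgcv::in.out(poly, pts)
  }
  inside
}

#' Tile a slide's ROI into fixed-size patches
#'
#' Lays a regular grid (origin at pixel (0,0), spacing `stride`) over the
#' slide and keeps every patch whose center lies inside at least one ROI
#' polygon; background patches (outside all polygons) are excluded. Ordering
#' is row-major (y, then x) and deterministic.
#'
#' @param slide a [slide_record()].
#' @param patch_size patch side in pixels.
#' @param stride grid spacing; defaults to `patch_size` (non-overlapping).
#' @param image_dim optional `c(height, width)` to avoid re-reading the image.
#' @return a data.frame manifest: `slide_id`, `x`, `y`, `size` (0-based
#'   origins).
#' @export
tile_roi <- function(slide, patch_size, stride = patch_size, image_dim = NULL) {
  if (patch_size <= 0L || stride <= 0L) stop("patch_size and stride must be > 0")
  if (!length(slide$roi_polygons)) stop("slide has no ROI polygons")
  if (is.null(image_dim)) image_dim <- dim(read_image(slide$image_path))[1:2]
  H <- image_dim[1]; W <- image_dim[2]
  xs <- seq(0L, W - patch_size, by = stride)
  ys <- seq(0L, H - patch_size, by = stride)
  if (!length(xs) || !length(ys))
    return(data.frame(slide_id = character(0), x = integer(0),
                      y = integer(0), size = integer(0)))
  grid <- expand.grid(x = xs, y = ys)[, c("x", "y")]  # row-major: y outer
  grid <- grid[order(grid$y, grid$x), ]
  keep <- point_in_polygons(grid$x + patch_size / 2, grid$y + patch_size / 2,
                            slide$roi_polygons)
  out <- grid[keep, , drop = FALSE]
  data.frame(slide_id = rep(slide$slide_id, nrow(out)),
             x = as.integer(out$x), y = as.integer(out$y),
             size = rep(as.integer(patch_size), nrow(out)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a patch manifest for a whole cohort
#'
#' @param slides list of [slide_record()]s.
#' @inheritParams tile_roi
#' @return row-bound manifest over all slides.
#' @export
tile_cohort <- function(slides, patch_size, stride = patch_size) {
  do.call(rbind, lapply(slides, tile_roi, patch_size = patch_size,
                        stride = stride))
}

#' Read one patch's pixel window
#'
#' Returns the exact pixel window of a manifest row — no resampling.
#' @param image a decoded image array (H x W x 3, values 0-255) from
#'   `read_image`, or a [slide_record()] whose image will be read.
#' @param ref a one-row manifest data.frame (`x`, `y`, `size`, 0-based).
#' @return `size x size x 3` numeric array in \[0, 255\].
#' @export
read_patch <- function(image, ref) {
  if (inherits(image, "slide_record")) image <- read_image(image$image_path)
  H <- dim(image)[1]; W <- dim(image)[2]
  x <- ref$x[1]; y <- ref$y[1]; s <- ref$size[1]
  if (x < 0 || y < 0 || x + s > W || y + s > H)
    stop(sprintf("patch ref (x=%d, y=%d, size=%d) out of bounds for %dx%d image",
                 x, y, s, W, H))
  image[(y + 1):(y + s), (x + 1):(x + s), , drop = FALSE]
}

# Load a set of manifest rows from one decoded image into a (s, s, 3, N) batch.
read_patch_batch <- function(image, refs) {
  s <- refs$size[1]
  n <- nrow(refs)
  out <- array(0, dim = c(s, s, 3, n))
  for (i in seq_len(n)) out[, , , i] <- read_patch(image, refs[i, ])
  out
}
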