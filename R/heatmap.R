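# Attention heatmaps: paint each sampled patch's attention weight back onto
# slide coordinates for interpretability.

#' Render an attention heatmap
#'
#' Produces a downsampled grayscale image in which every sampled patch
#' footprint carries its attention weight; regions never sampled (background
#' or unselected patches) are 0. Overlapping footprints (stride < size) are
#' averaged per pixel. Optional contrast enhancement is a percentile stretch:
#' clip at the 1st/99th percentile of the nonzero footprint values, then
#' min-max rescale to \[0, 1\].
#'
#' @param slide_dim `c(height, width)` of the slide in pixels.
#' @param refs manifest rows of the bag's patches (`x`, `y`, `size`).
#' @param attention attention weights aligned to `refs` rows.
#' @param downsample integer downsampling factor (default 32).
#' @param enhance apply the percentile stretch (default TRUE).
#' @return numeric matrix `ceiling(height/downsample) x
#'   ceiling(width/downsample)`.
#' @export
render_heatmap <- function(slide_dim, refs, attention, downsample = 32L,
                           enhance = TRUE) {
  if (nrow(refs) != length(attention))
    stop("refs and attention must be aligned")
  h <- ceiling(slide_dim[1] / downsample)
  w <- ceiling(slide_dim[2] / downsample)
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (i in seq_len(nrow(refs))) {
    r0 <- floor(refs$y[i] / downsample) + 1L
    r1 <- min(h, ceiling((refs$y[i] + refs$size[i]) / downsample))
    c0 <- floor(refs$x[i] / downsample) + 1L
    c1 <- min(w, ceiling((refs$x[i] + refs$size[i]) / downsample))
    acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + attention[i]
    cnt[r0:r1, c0:c1] <- cnt[r0:r1, c0:c1] + 1L
  }
  hm <- acc
  hm[cnt > 0L] <- acc[cnt > 0L] / cnt[cnt > 0L]
  if (enhance && any(cnt > 0L)) {
    v <- hm[cnt > 0L]
    lo <- quantile(v, 0.01, names = FALSE)
    hi <- quantile(v, 0.99, names = FALSE)
    if (hi > lo) {
      hm[cnt > 0L] <- (pmin(pmax(v, lo), hi) - lo) / (hi - lo)
    } else if (any(v > 0)) {
      hm[cnt > 0L] <- 1
    }
  }
  hm
}

#' Write a heatmap matrix as a grayscale PNG
#'
#' @param heatmap matrix from [render_heatmap()].
#' @param path output PNG path.
#' @export
write_heatmap_png <- function(heatmap, path) {
  png::writePNG(pmin(pmax(heatmap, 0), 1), path)
  invisible(path)
}
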