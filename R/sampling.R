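# "Intelligent sampling": rank a slide's patches by discrimination score,
# keep the top K, and embed them with the scorer's feature extractor into a
# bag of instance vectors for MIL.

#' Rank scored patches by discrimination score
#'
#' Orders patches by DS descending. Ties are broken by row-major patch
#' coordinate order (y, then x), making the ranking stable and deterministic
#' across platforms. A per-slide ranking (rather than a global DS threshold)
#' is essential because DS distributions differ between slides.
#'
#' @param scored a data.frame from [score_slide()] (needs `ds`, `x`, `y`).
#' @return integer permutation of `seq_len(nrow(scored))`.
#' @export
rank_patches <- function(scored) {
  if (!nrow(scored)) stop("cannot rank an empty patch list")
  order(-scored$ds, scored$y, scored$x)
}

#' Select the top-K ranked patches
#'
#' Returns the first `min(K, n)` entries of the ranking. When a slide has
#' fewer than K patches, all patches are kept and the shortfall reported via
#' a message.
#'
#' @param ranked an index permutation from [rank_patches()].
#' @param k bag size K (>= 1).
#' @return integer vector of selected indices, in rank order.
#' @export
select_top_k <- function(ranked, k) {
  if (k < 1L) stop("K must be >= 1")
  n <- length(ranked)
  if (k >= n) {
    if (k > n) message("requested K=", k, " but only ", n,
                       " patches available; using all")
    return(ranked)
  }
  ranked[seq_len(k)]
}

#' Embed selected patches into a bag
#'
#' Feeds the selected patches through the scorer's feature extractor (the
#' network without its classification head) to obtain one D-dimensional
#' instance vector per patch. Rows follow the DS ranking order.
#'
#' @param model trained `scorer_model`.
#' @param slide a [slide_record()].
#' @param refs manifest rows of the selected patches, in rank order.
#' @param image optional pre-decoded image.
#' @return an object of class `mil_bag`: `slide_id`, `instances` (K x D
#'   matrix), `refs`, `label`.
#' @export
embed_bag <- function(model, slide, refs, image = NULL) {
  if (!nrow(refs)) stop("cannot embed an empty selection")
  if (is.null(image)) image <- read_image(slide$image_path)
  xb <- read_patch_batch(image, refs)
  inst <- scorer_embed(model, xb)
  new_bag(slide$slide_id, inst, refs, slide$label)
}

new_bag <- function(slide_id, instances, refs, label) {
  stopifnot(nrow(instances) == nrow(refs))
  structure(list(slide_id = slide_id, instances = instances,
                 refs = refs[, c("slide_id", "x", "y", "size")],
                 label = as.integer(label)),
            class = "mil_bag")
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("<mil_bag> %s: %d instances x %d dims, label=%d\n",
              x$slide_id, nrow(x$instances), ncol(x$instances), x$label))
  invisible(x)
}

#' Build bags for a set of slides
#'
#' For each slide: score all ROI patches, rank by DS, keep the top K, embed.
#' `k = Inf` (or any K at least the slide's patch count) disables sampling —
#' every ROI patch enters the bag.
#'
#' @param model trained `scorer_model`.
#' @param slides list of [slide_record()]s.
#' @param manifest cohort manifest.
#' @param k bag size.
#' @param scores optional precomputed [score_slide()] output for all slides
#'   (row-bound); when supplied, probabilities are not recomputed.
#' @return named list of `mil_bag` objects.
#' @export
build_bags <- function(model, slides, manifest, k, scores = NULL) {
  bags <- lapply(slides, function(slide) {
    image <- read_image(slide$image_path)
    sc <- if (is.null(scores)) {
      score_slide(model, slide, manifest, image = image)
    } else {
      scores[scores$slide_id == slide$slide_id, , drop = FALSE]
    }
    sel <- select_top_k(rank_patches(sc), min(k, nrow(sc)))
    embed_bag(model, slide, sc[sel, , drop = FALSE], image = image)
  })
  names(bags) <- vapply(slides, `[[`, character(1), "slide_id")
  bags
}

#' Persist / restore bags
#'
#' Bags are written once after embedding so MIL training never re-touches
#' pixels — this is the efficiency mechanism of the sampling stage. The
#' archive is a single versioned RDS file, one entry per slide holding the
#' instance matrix, aligned patch refs, and the slide label.
#'
#' @param bags named list of `mil_bag`s.
#' @param path archive file.
#' @export
write_bags <- function(bags, path) {
  saveRDS(list(format = "attnmil-bags-v1", bags = bags), path)
  invisible(path)
}

#' @rdname write_bags
#' @export
read_bags <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "attnmil-bags-v1"))
    stop("not an attnmil bag archive: ", path)
  obj$bags
}
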