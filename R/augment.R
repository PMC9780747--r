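# Dataset augmentation with consistent label transforms. A variant is a
# list of transform specs drawn from flips, quarter-turn rotations,
# Gaussian blur and brightness scaling; geometric transforms are applied to
# boxes and masks as well as pixels, photometric ones to pixels only, so
# per-image label counts are conserved exactly.

geom_transform_box <- function(box, op, size) {
  switch(op,
         "identity" = box,
         "flip-h" = c(size - box[3], box[2], size - box[1], box[4]),
         "flip-v" = c(box[1], size - box[4], box[3], size - box[2]),
         "rot90" = rotate_box(box, 1L, size),
         "rot180" = rotate_box(box, 2L, size),
         "rot270" = rotate_box(box, 3L, size),
         stop("unknown transform: ", op))
}

geom_transform_image <- function(m, op) {
  switch(op,
         "identity" = m,
         "flip-h" = m[, rev(seq_len(ncol(m))), drop = FALSE],
         "flip-v" = m[rev(seq_len(nrow(m))), , drop = FALSE],
         "rot90" = rotate_image(m, 1L),
         "rot180" = rotate_image(m, 2L),
         "rot270" = rotate_image(m, 3L),
         stop("unknown transform: ", op))
}

geom_transform_mask <- function(mask, op, size) {
  full <- matrix(FALSE, size, size)
  bb <- pm_bbox(mask)
  full[(mask$y0 + 1):bb[4], (mask$x0 + 1):bb[3]] <- mask$m
  full <- geom_transform_image(full, op)
  pos <- which(full, arr.ind = TRUE)
  y0 <- min(pos[, 1]) - 1L; x0 <- min(pos[, 2]) - 1L
  pixmask(x0, y0, full[(y0 + 1):max(pos[, 1]), (x0 + 1):max(pos[, 2]),
                       drop = FALSE])
}

apply_one_transform <- function(sample, spec, size) {
  if (is.character(spec)) spec <- list(op = spec)
  op <- spec$op
  if (op %in% c("identity", "flip-h", "flip-v", "rot90", "rot180", "rot270")) {
    sample$image <- geom_transform_image(sample$image, op)
    if (nrow(sample$cells)) {
      bx <- t(apply(as.matrix(sample$cells[, c("x0", "y0", "x1", "y1")]), 1,
                    geom_transform_box, op = op, size = size))
      sample$cells[, c("x0", "y0", "x1", "y1")] <- bx
    }
    sample$tubules <- lapply(sample$tubules, function(t) {
      t$mask <- geom_transform_mask(t$mask, op, size)
      t
    })
  } else if (op == "blur") {
    sample$image <- EBImage::gblur(sample$image, sigma = spec$sigma %||% 1.5)
  } else if (op == "brightness") {
    sample$image <- pmin(sample$image * (spec$factor %||% 1.2), 255)
  } else {
    stop("unknown transform: ", op)
  }
  sample
}

#' Augment an annotated image set
#'
#' Emits `length(variants)` outputs per input sample, each labeled
#' consistently with the applied geometric transforms; the total label
#' count scales exactly by the number of variants.
#'
#' @param samples List of samples; each is a list with `image` (square
#'   matrix), `cells` (data frame with box columns and `class`) and
#'   optionally `tubules` (list of `mask`/`stage` records).
#' @param variants List of variants; each variant is a list of transform
#'   specs (a character op name, or `list(op=, sigma=/factor=)` for the
#'   photometric ops).
#' @return List of `length(samples) * length(variants)` samples, each
#'   carrying `variant` (index) and `origin` (source sample index).
#' @export
augment_dataset <- function(samples, variants) {
  out <- vector("list", length(samples) * length(variants))
  k <- 0L
  for (si in seq_along(samples)) {
    for (vi in seq_along(variants)) {
      s <- samples[[si]]
      size <- nrow(s$image)
      if (is.null(s$tubules)) s$tubules <- list()
      for (spec in variants[[vi]]) s <- apply_one_transform(s, spec, size)
      s$variant <- vi; s$origin <- si
      k <- k + 1L
      out[[k]] <- s
    }
  }
  out
}

#' Shipped augmentation presets
#'
#' `augment_variants_cells()` is the 12-variant preset used for the
#' cell-annotation dataset (4 geometric orientations x plain / brightness /
#' blur); `augment_variants_tubules()` is the 9-variant preset for the
#' tubule dataset (3 orientations x 3 photometric settings). Applied to the
#' historical dataset sizes they reproduce the published bookkeeping:
#' 424 images -> 5088, 52807 labels -> 633684, and 3097 images -> 27873.
#'
#' @return List of variants suitable for [augment_dataset()].
#' @export
augment_variants_cells <- function() {
  geoms <- c("identity", "flip-h", "flip-v", "rot90")
  photos <- list(list(), list(list(op = "brightness", factor = 1.15)),
                 list(list(op = "blur", sigma = 1.2)))
  out <- list()
  for (g in geoms) for (p in photos) out[[length(out) + 1L]] <- c(list(g), p)
  out
}

#' @rdname augment_variants_cells
#' @export
augment_variants_tubules <- function() {
  geoms <- c("identity", "flip-h", "flip-v")
  photos <- list(list(), list(list(op = "brightness", factor = 1.15)),
                 list(list(op = "blur", sigma = 1.2)))
  out <- list()
  for (g in geoms) for (p in photos) out[[length(out) + 1L]] <- c(list(g), p)
  out
}

#' Augmentation bookkeeping
#'
#' Image and label counts produced by augmenting a dataset of `n_images`
#' images carrying `n_labels` labels with the given variants (labels scale
#' exactly with the variant count because geometric transforms conserve
#' per-image label counts).
#'
#' @param n_images,n_labels Input dataset size.
#' @param variants Variant list, e.g. [augment_variants_cells()].
#' @return Named numeric vector `c(images =, labels =)`.
#' @export
#' @examples
#' augmentation_bookkeeping(424, 52807, augment_variants_cells())
augmentation_bookkeeping <- function(n_images, n_labels, variants) {
  c(images = n_images * length(variants),
    labels = n_labels * length(variants))
}
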