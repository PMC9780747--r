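#' Seminiferous epithelial cell classes
#'
#' The nine cell classes emitted by the pipeline, in canonical report order:
#' Sertoli cells (`Sert`), spermatogonia (`Spg`), prepachytene spermatocytes
#' (`Spc-prePach`), pachytene/diplotene spermatocytes (`Spc-Pach`), secondary
#' spermatocytes (`Spc-sec`), meiotic metaphase plates (`m2m`), round
#' spermatids (`RS`), and early/late elongating spermatids (`elSpt-early`,
#' `elSpt-late`).
#'
#' The annotation dialect additionally admits `Spc-Pach-early` and
#' `Spc-Pach-late`, which must be fused to `Spc-Pach` (see
#' [fuse_pachytene()]) before any pipeline output.
#'
#' @return Character vector of the 9 class labels.
#' @export
#' @examples
#' cell_classes()
cell_classes <- function() {
  c("Sert", "Spg", "Spc-prePach", "Spc-Pach", "Spc-sec", "m2m", "RS",
    "elSpt-early", "elSpt-late")
}

#' Pachytene annotation-dialect subclasses fused by [fuse_pachytene()]
#' @return Character vector of the two subclass labels.
#' @export
pachytene_subclasses <- function() c("Spc-Pach-early", "Spc-Pach-late")

#' Seminiferous epithelial stage classes
#'
#' The five pooled stage categories of the mouse seminiferous epithelial
#' cycle used by the tubule classifier, in cycle order.
#'
#' @return Character vector `c("I-V", "VI-VIII", "IX", "X-XI", "XII")`.
#' @export
#' @examples
#' stage_classes()
stage_classes <- function() c("I-V", "VI-VIII", "IX", "X-XI", "XII")

#' Construct a grayscale slide image
#'
#' @param pixels Numeric matrix of intensities (rows = y, cols = x). 8- or
#'   16-bit ranges are accepted; the synthetic generator uses 0-255.
#' @param microns_per_px Physical pixel size; the nominal scanner scale is
#'   0.161 um/px at x400 magnification.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, microns_per_px = 0.161) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  structure(list(pixels = pixels, microns_per_px = microns_per_px),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image> %d x %d px (%.3f um/px)\n",
              ncol(x$pixels), nrow(x$pixels), x$microns_per_px))
  invisible(x)
}

#' Construct a table of cell detections
#'
#' A `cell_detections` object is a data frame with one row per detected
#' nucleus: half-open box coordinates (`x0`, `y0`, `x1`, `y1`), top and
#' second-best class, top confidence, provenance (`source`), the number of
#' raw detections merged into the row (`n_merged`), and a matrix column
#' `conf` holding the full per-class confidence vector.
#'
#' @param boxes Numeric matrix n x 4 (columns x0, y0, x1, y1, half-open).
#' @param conf Numeric matrix n x K with column names naming cell classes;
#'   rows must sum to at most 1 plus a small tolerance.
#' @param source Character provenance tags (tile id + rotation), recycled.
#' @param n_merged Integer count of merged raw detections, recycled.
#' @param second_class Optional character vector of runner-up classes
#'   (`NA` when a detection carries a single voted class).
#' @return A `cell_detections` data frame.
#' @export
cell_detections <- function(boxes, conf, source = "", n_merged = 1L,
                            second_class = NULL) {
  boxes <- matrix(as.numeric(boxes), ncol = 4L,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  n <- nrow(boxes)
  if (n == 0L) return(empty_cell_detections(colnames(conf)))
  stopifnot(is.matrix(conf), nrow(conf) == n, !is.null(colnames(conf)))
  if (any(rowSums(conf) > 1 + 1e-6))
    stop("confidence vectors must lie in the probability simplex")
  top_i <- max.col(conf, ties.method = "first")
  df <- data.frame(x0 = boxes[, 1], y0 = boxes[, 2],
                   x1 = boxes[, 3], y1 = boxes[, 4],
                   class = colnames(conf)[top_i],
                   top_conf = conf[cbind(seq_len(n), top_i)],
                   source = rep_len(as.character(source), n),
                   n_merged = rep_len(as.integer(n_merged), n),
                   stringsAsFactors = FALSE)
  df$second_class <- if (is.null(second_class)) NA_character_ else
    rep_len(as.character(second_class), n)
  df$conf <- conf
  class(df) <- c("cell_detections", "data.frame")
  df
}

empty_cell_detections <- function(classes = cell_classes()) {
  df <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                   y1 = numeric(0), class = character(0),
                   top_conf = numeric(0), source = character(0),
                   n_merged = integer(0), second_class = character(0),
                   stringsAsFactors = FALSE)
  df$conf <- matrix(numeric(0), nrow = 0, ncol = length(classes),
                    dimnames = list(NULL, classes))
  class(df) <- c("cell_detections", "data.frame")
  df
}

det_boxes <- function(cells) {
  as.matrix(cells[, c("x0", "y0", "x1", "y1"), drop = FALSE])
}

#' Construct a tubule mask fragment
#'
#' One predicted tubule mask on one tile, expressed in slide coordinates,
#' together with its per-stage confidence vector.
#'
#' @param mask A [pixmask()].
#' @param stage_conf Named numeric vector over [stage_classes()].
#' @return An object of class `tubule_fragment`.
#' @export
tubule_fragment <- function(mask, stage_conf) {
  stopifnot(inherits(mask, "pixmask"))
  sc <- stage_classes()
  stopifnot(all(sc %in% names(stage_conf)))
  stage_conf <- stage_conf[sc]
  area <- pm_area(mask)
  if (area <= 0L) stop("tubule fragment mask must be non-empty")
  structure(list(mask = mask, stage_conf = stage_conf,
                 area_px = area),
            class = "tubule_fragment")
}
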