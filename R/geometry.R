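# Geometric primitives shared by all modules. Boxes are 0-based, half-open
# [x0, x1) x [y0, y1); masks are pixel sets stored as a bounding window plus
# a logical matrix. IOU is always computed on the discrete pixel lattice so
# box IOU and mask IOU agree exactly when masks are filled boxes.

check_box <- function(b) {
  if (length(b) != 4L || any(!is.finite(b)))
    stop("a box is a finite numeric vector (x0, y0, x1, y1)")
  if (b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box: x1 must exceed x0 and y1 must exceed y0")
  invisible(b)
}

#' Intersection-over-union of two boxes
#'
#' Jaccard index of the two half-open pixel rectangles.
#'
#' @param a,b Numeric vectors `(x0, y0, x1, y1)`.
#' @return Ratio in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
box_iou <- function(a, b) {
  check_box(a); check_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# Vectorized IOU between every row of A (n x 4) and every row of B (m x 4).
box_iou_matrix <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(matrix(0, nrow(A), nrow(B)))
  ix0 <- outer(A[, 1], B[, 1], pmax)
  iy0 <- outer(A[, 2], B[, 2], pmax)
  ix1 <- outer(A[, 3], B[, 3], pmin)
  iy1 <- outer(A[, 4], B[, 4], pmin)
  inter <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (outer(areaA, areaB, `+`) - inter)
}

#' Rotate a box by quarter turns within a square tile
#'
#' Applies the pixel map of a rotation by `k * 90` degrees about the tile
#' centre lattice; one quarter turn sends pixel `(x, y)` to
#' `(y, size - 1 - x)`. Applying `k` then `4 - k` turns is the identity.
#'
#' @param box Numeric `(x0, y0, x1, y1)` inside `[0, size)^2`.
#' @param k Number of quarter turns, in `0:3`.
#' @param size Tile side length in pixels.
#' @return The rotated box.
#' @export
rotate_box <- function(box, k, size) {
  check_box(box)
  stopifnot(k %in% 0:3, size > 0)
  if (box[1] < 0 || box[2] < 0 || box[3] > size || box[4] > size)
    stop("box out of tile bounds")
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) {
    box <- c(box[2], size - box[3], box[4], size - box[1])
  }
  box
}

# Rotate a square image matrix by k quarter turns, consistently with
# rotate_box: new[y'+1, x'+1] = old[y+1, x+1] with (x', y') = (y, s-1-x).
rotate_image <- function(m, k) {
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) {
    m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  }
  m
}

#' Pixel mask over a bounding window
#'
#' A pixel set stored as its window origin `(x0, y0)` (0-based slide
#' coordinates) plus a logical matrix (rows = y, cols = x).
#'
#' @param x0,y0 Window origin.
#' @param m Logical matrix.
#' @return An object of class `pixmask`.
#' @export
pixmask <- function(x0, y0, m) {
  stopifnot(is.matrix(m))
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 m = m & TRUE),
            class = "pixmask")
}

#' @rdname pixmask
#' @param mask A `pixmask`.
#' @return `pm_area()`: the number of set pixels.
#' @export
pm_area <- function(mask) sum(mask$m)

pm_bbox <- function(mask) {
  c(mask$x0, mask$y0, mask$x0 + ncol(mask$m), mask$y0 + nrow(mask$m))
}

# Intersection pixel count of two pixmasks.
pm_intersect_area <- function(a, b) {
  x0 <- max(a$x0, b$x0); y0 <- max(a$y0, b$y0)
  x1 <- min(a$x0 + ncol(a$m), b$x0 + ncol(b$m))
  y1 <- min(a$y0 + nrow(a$m), b$y0 + nrow(b$m))
  if (x1 <= x0 || y1 <= y0) return(0L)
  am <- a$m[(y0 - a$y0 + 1):(y1 - a$y0), (x0 - a$x0 + 1):(x1 - a$x0), drop = FALSE]
  bm <- b$m[(y0 - b$y0 + 1):(y1 - b$y0), (x0 - b$x0 + 1):(x1 - b$x0), drop = FALSE]
  sum(am & bm)
}

# Union of two pixmasks (window = union of windows).
pm_union <- function(a, b) {
  x0 <- min(a$x0, b$x0); y0 <- min(a$y0, b$y0)
  x1 <- max(a$x0 + ncol(a$m), b$x0 + ncol(b$m))
  y1 <- max(a$y0 + nrow(a$m), b$y0 + nrow(b$m))
  m <- matrix(FALSE, y1 - y0, x1 - x0)
  m[(a$y0 - y0 + 1):(a$y0 - y0 + nrow(a$m)),
    (a$x0 - x0 + 1):(a$x0 - x0 + ncol(a$m))] <- a$m
  win <- m[(b$y0 - y0 + 1):(b$y0 - y0 + nrow(b$m)),
           (b$x0 - x0 + 1):(b$x0 - x0 + ncol(b$m)), drop = FALSE]
  m[(b$y0 - y0 + 1):(b$y0 - y0 + nrow(b$m)),
    (b$x0 - x0 + 1):(b$x0 - x0 + ncol(b$m))] <- win | b$m
  pixmask(x0, y0, m)
}

# Does the mask contain pixel (x, y)? Vectorized over x, y.
pm_contains <- function(mask, x, y) {
  x <- floor(x); y <- floor(y)
  inside <- x >= mask$x0 & x < mask$x0 + ncol(mask$m) &
    y >= mask$y0 & y < mask$y0 + nrow(mask$m)
  out <- logical(length(x))
  if (any(inside))
    out[inside] <- mask$m[cbind(y[inside] - mask$y0 + 1,
                                x[inside] - mask$x0 + 1)]
  out
}

# Translate a pixmask by (dx, dy).
pm_shift <- function(mask, dx, dy) pixmask(mask$x0 + dx, mask$y0 + dy, mask$m)

# Clip a pixmask to the half-open window (x0, y0, x1, y1); NULL when empty.
pm_clip <- function(mask, x0, y0, x1, y1) {
  cx0 <- max(mask$x0, x0); cy0 <- max(mask$y0, y0)
  cx1 <- min(mask$x0 + ncol(mask$m), x1)
  cy1 <- min(mask$y0 + nrow(mask$m), y1)
  if (cx1 <= cx0 || cy1 <= cy0) return(NULL)
  m <- mask$m[(cy0 - mask$y0 + 1):(cy1 - mask$y0),
              (cx0 - mask$x0 + 1):(cx1 - mask$x0), drop = FALSE]
  if (!any(m)) return(NULL)
  pixmask(cx0, cy0, m)
}

#' Intersection-over-union of two pixel masks
#'
#' @param a,b Non-empty [pixmask()] objects.
#' @return Jaccard index of the two pixel sets, in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  stopifnot(inherits(a, "pixmask"), inherits(b, "pixmask"))
  aa <- pm_area(a); ab <- pm_area(b)
  if (aa == 0L || ab == 0L) stop("mask_iou requires non-empty masks")
  inter <- pm_intersect_area(a, b)
  inter / (aa + ab - inter)
}

#' Axis-aligned ellipse inscribed in a box, rasterized
#'
#' Returns the set of pixels whose centres `(x + 0.5, y + 0.5)` satisfy the
#' inscribed-ellipse inequality with `<=` (boundary pixels included). Used
#' as the cell region ("oval") for immunofluorescence positivity scoring.
#'
#' @param box Numeric `(x0, y0, x1, y1)`.
#' @return A [pixmask()]; always a subset of the box.
#' @export
inscribed_ellipse_mask <- function(box) {
  check_box(box)
  x0 <- floor(box[1]); y0 <- floor(box[2])
  x1 <- ceiling(box[3]); y1 <- ceiling(box[4])
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  a <- (box[3] - box[1]) / 2; b <- (box[4] - box[2]) / 2
  xs <- seq.int(x0, x1 - 1L) + 0.5
  ys <- seq.int(y0, y1 - 1L) + 0.5
  m <- outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, `+`) <= 1
  pixmask(x0, y0, m)
}

# Rasterize a (possibly rotated) ellipse: centre (cx, cy), semi-axes a >= b,
# orientation theta (radians, x-axis of the ellipse). Returns a pixmask.
ellipse_mask <- function(cx, cy, a, b, theta = 0) {
  # conservative bounding half-extents of the rotated ellipse
  hx <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  hy <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  x0 <- floor(cx - hx); x1 <- ceiling(cx + hx)
  y0 <- floor(cy - hy); y1 <- ceiling(cy + hy)
  xs <- seq.int(x0, x1 - 1L) + 0.5
  ys <- seq.int(y0, y1 - 1L) + 0.5
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  pixmask(x0, y0, (u / a)^2 + (v / b)^2 <= 1)
}

# Bounding box (half-open) of a rotated ellipse, as used for cell boxes.
ellipse_bbox <- function(cx, cy, a, b, theta = 0) {
  hx <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  hy <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  c(floor(cx - hx), floor(cy - hy), ceiling(cx + hx), ceiling(cy + hy))
}
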