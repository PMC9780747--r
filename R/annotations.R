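# Annotation IO. COCO-dialect JSON is the canonical format (cells as
# bounding-box annotations, tubule masks as uncompressed column-major RLE
# segmentations); the VGG Image Annotator (VIA) project dialect is
# supported for import. Image IO: single-channel PNG/TIFF, with documented
# luma conversion for color inputs.

# --- COCO uncompressed RLE (column-major, runs alternate 0s/1s, first run
# counts zeros) ---
rle_encode_mask <- function(mask, width, height) {
  full <- matrix(FALSE, height, width)
  bb <- pm_bbox(mask)
  full[(mask$y0 + 1):(bb[4]), (mask$x0 + 1):(bb[3])] <- mask$m
  v <- as.integer(full)  # column-major by R storage; COCO RLE expects
  # column-major too (pixels ordered down each column)
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  as.integer(counts)
}

rle_decode_mask <- function(counts, width, height) {
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  full <- matrix(as.logical(vals), nrow = height, ncol = width)
  pos <- which(full, arr.ind = TRUE)
  if (!nrow(pos)) stop("empty RLE mask")
  y0 <- min(pos[, 1]) - 1L; y1 <- max(pos[, 1])
  x0 <- min(pos[, 2]) - 1L; x1 <- max(pos[, 2])
  pixmask(x0, y0, full[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE])
}

#' Write an annotation set as COCO-dialect JSON
#'
#' Cells become box annotations (`bbox = [x, y, w, h]`) with cell-class
#' categories; tubule masks become uncompressed-RLE segmentations with
#' stage-class categories (ids offset by 100). The round trip
#' `read_coco_annotations(write_coco_annotations(x))` is lossless on the
#' data model.
#'
#' @param ann An `annotation_set` (fields `cells`, `tubules`, `dim`).
#' @param file Output path.
#' @param image_name Recorded file name of the underlying image.
#' @return `file`, invisibly.
#' @export
write_coco_annotations <- function(ann, file, image_name = "slide.png") {
  W <- ann$dim[1]; H <- ann$dim[2]
  cls <- union(cell_classes(), unique(ann$cells$class))
  categories <- c(
    lapply(seq_along(cls), function(i)
      list(id = i, name = cls[i], supercategory = "cell")),
    lapply(seq_along(stage_classes()), function(j)
      list(id = 100L + j, name = stage_classes()[j], supercategory = "stage")))
  anns <- list()
  for (i in seq_len(nrow(ann$cells))) {
    r <- ann$cells[i, ]
    anns[[length(anns) + 1L]] <- list(
      id = as.integer(r$id), image_id = 1L,
      category_id = match(r$class, cls),
      bbox = c(r$x0, r$y0, r$x1 - r$x0, r$y1 - r$y0),
      area = (r$x1 - r$x0) * (r$y1 - r$y0), iscrowd = 0L)
  }
  for (t in ann$tubules) {
    anns[[length(anns) + 1L]] <- list(
      id = 100000L + as.integer(t$id), image_id = 1L,
      category_id = 100L + match(t$stage, stage_classes()),
      segmentation = list(size = c(H, W),
                          counts = rle_encode_mask(t$mask, W, H)),
      area = pm_area(t$mask), iscrowd = 0L)
  }
  doc <- list(
    info = list(description = "seminiferous tubule annotations"),
    images = list(list(id = 1L, width = W, height = H,
                       file_name = image_name)),
    categories = categories,
    annotations = anns)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a COCO-dialect annotation JSON
#'
#' @param file Path to the JSON written by [write_coco_annotations()] or a
#'   compatible exporter (box annotations with cell categories,
#'   uncompressed-RLE segmentations with stage categories).
#' @return An `annotation_set`.
#' @export
read_coco_annotations <- function(file) {
  doc <- jsonlite::read_json(file)
  if (is.null(doc$images) || !length(doc$images))
    stop("malformed COCO file: no images entry")
  W <- doc$images[[1]]$width; H <- doc$images[[1]]$height
  cat_name <- setNames(
    vapply(doc$categories, function(c) c$name, ""),
    vapply(doc$categories, function(c) as.character(c$id), ""))
  cat_super <- setNames(
    vapply(doc$categories, function(c) c$supercategory %||% "cell", ""),
    names(cat_name))
  cells <- list(); tubules <- list()
  for (k in seq_along(doc$annotations)) {
    a <- doc$annotations[[k]]
    cid <- as.character(a$category_id)
    if (is.na(cat_name[cid]))
      stop(sprintf("malformed COCO file: annotation %d has unknown category %s",
                   k, cid))
    if (cat_super[cid] == "stage") {
      seg <- a$segmentation
      if (is.null(seg$counts))
        stop(sprintf("malformed COCO file: annotation %d lacks RLE counts", k))
      mask <- rle_decode_mask(unlist(seg$counts), W, H)
      tubules[[length(tubules) + 1L]] <-
        list(id = length(tubules) + 1L, mask = mask, stage = cat_name[[cid]])
    } else {
      bb <- unlist(a$bbox)
      if (length(bb) != 4)
        stop(sprintf("malformed COCO file: annotation %d has a bad bbox", k))
      cells[[length(cells) + 1L]] <-
        data.frame(id = a$id %||% k, x0 = bb[1], y0 = bb[2],
                   x1 = bb[1] + bb[3], y1 = bb[2] + bb[4],
                   class = cat_name[[cid]], tubule_id = NA_integer_,
                   stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(id = integer(0), x0 = numeric(0), y0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0), class = character(0),
               tubule_id = integer(0), stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  structure(list(cells = cells, tubules = tubules, dim = c(W, H)),
            class = "annotation_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Even-odd scanline fill of a polygon given 0-based vertex coordinates;
# a pixel is inside when its centre is inside the polygon.
rasterize_polygon <- function(xs, ys) {
  x0 <- floor(min(xs)); x1 <- ceiling(max(xs))
  y0 <- floor(min(ys)); y1 <- ceiling(max(ys))
  h <- y1 - y0; w <- x1 - x0
  m <- matrix(FALSE, h, w)
  n <- length(xs)
  for (row in seq_len(h)) {
    py <- y0 + row - 0.5
    crossings <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > py) != (ys[j] > py)) {
        crossings <- c(crossings,
                       xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i]))
      }
      j <- i
    }
    crossings <- sort(crossings)
    for (k in seq_len(length(crossings) %/% 2)) {
      a <- crossings[2 * k - 1]; b <- crossings[2 * k]
      cols <- which((x0 + seq_len(w) - 0.5) > a & (x0 + seq_len(w) - 0.5) < b)
      m[row, cols] <- TRUE
    }
  }
  pixmask(x0, y0, m)
}

#' Import a VGG Image Annotator (VIA) project JSON
#'
#' Rectangles with a `class` region attribute become cell annotations;
#' polygons and ellipses with a `stage` attribute become tubule masks.
#' Unknown class or stage values, and unsupported shapes, are rejected with
#' the offending record index.
#'
#' @param file Path to a VIA project or region-export JSON.
#' @param dim Optional `c(width, height)` of the annotated image; inferred
#'   from region extents when absent.
#' @return An `annotation_set`.
#' @export
read_via_annotations <- function(file, dim = NULL) {
  doc <- jsonlite::read_json(file)
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  cells <- list(); tubules <- list(); rec <- 0L
  for (img in doc) {
    if (is.null(img$regions)) next
    for (region in img$regions) {
      rec <- rec + 1L
      sa <- region$shape_attributes; ra <- region$region_attributes
      if (is.null(sa))
        stop(sprintf("VIA record %d: missing shape_attributes", rec))
      if (identical(sa$name, "rect")) {
        cl <- ra$class %||% ra$type
        if (is.null(cl) ||
            !cl %in% c(cell_classes(), pachytene_subclasses()))
          stop(sprintf("VIA record %d: unknown cell class '%s'", rec,
                       cl %||% "<missing>"))
        cells[[length(cells) + 1L]] <- data.frame(
          id = rec, x0 = sa$x, y0 = sa$y, x1 = sa$x + sa$width,
          y1 = sa$y + sa$height, class = cl, tubule_id = NA_integer_,
          stringsAsFactors = FALSE)
      } else if (identical(sa$name, "polygon") ||
                 identical(sa$name, "ellipse")) {
        st <- ra$stage %||% ra$class
        if (is.null(st) || !st %in% stage_classes())
          stop(sprintf("VIA record %d: unknown stage '%s'", rec,
                       st %||% "<missing>"))
        mask <- if (identical(sa$name, "polygon"))
          rasterize_polygon(unlist(sa$all_points_x), unlist(sa$all_points_y))
        else
          ellipse_mask(sa$cx, sa$cy, sa$rx, sa$ry,
                       (sa$theta %||% 0))
        tubules[[length(tubules) + 1L]] <-
          list(id = length(tubules) + 1L, mask = mask, stage = st)
      } else {
        stop(sprintf("VIA record %d: unsupported shape '%s'", rec,
                     sa$name %||% "<missing>"))
      }
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(id = integer(0), x0 = numeric(0), y0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0), class = character(0),
               tubule_id = integer(0), stringsAsFactors = FALSE)
  if (is.null(dim)) {
    xmax <- max(c(cells$x1, vapply(tubules, function(t) pm_bbox(t$mask)[3],
                                   0), 0))
    ymax <- max(c(cells$y1, vapply(tubules, function(t) pm_bbox(t$mask)[4],
                                   0), 0))
    dim <- c(ceiling(xmax), ceiling(ymax))
  }
  structure(list(cells = cells, tubules = tubules, dim = dim),
            class = "annotation_set")
}

#' Read a grayscale slide image from PNG or TIFF
#'
#' Multi-channel images are converted to grayscale with the Rec. 601 luma
#' weights (0.299 R + 0.587 G + 0.114 B). Intensities are rescaled to the
#' 0-255 range used throughout.
#'
#' @param file Path ending in .png, .tif or .tiff.
#' @param microns_per_px Physical scale recorded on the slide object.
#' @return A [slide_image()].
#' @export
read_slide_image <- function(file, microns_per_px = 0.161) {
  ext <- tolower(tools::file_ext(file))
  arr <- switch(ext,
                png = png::readPNG(file),
                tif = ,
                tiff = tiff::readTIFF(file),
                stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    arr <- if (ch >= 3)
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    else arr[, , 1]
  }
  slide_image(arr * 255, microns_per_px = microns_per_px)
}

#' Write a grayscale slide image to PNG or TIFF
#'
#' @param slide A [slide_image()] (0-255 intensities).
#' @param file Path ending in .png, .tif or .tiff.
#' @return `file`, invisibly.
#' @export
write_slide_image <- function(slide, file) {
  ext <- tolower(tools::file_ext(file))
  img <- pmin(pmax(slide$pixels / 255, 0), 1)
  switch(ext,
         png = png::writePNG(img, file),
         tif = ,
         tiff = tiff::writeTIFF(img, file),
         stop("unsupported image format: ", ext))
  invisible(file)
}
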