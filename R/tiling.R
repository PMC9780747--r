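# Slide tiling: a base lattice of size-by-size tiles plus a second lattice
# shifted by half a tile in both axes, so that interior objects cut by a
# base-tile border are seen whole by a shifted tile. Trailing partial tiles
# are dropped rather than padded; the shifted lattice recovers most of the
# border loss and padding would create artificial dark regions.

#' Slice a slide into overlapping tiles
#'
#' Produces the base lattice (step = `size`) plus the lattice shifted by
#' `shift` in both axes, keeping only tiles fully inside the slide. Tiles
#' whose foreground fraction (pixels with intensity above
#' `foreground_floor`) is below `min_foreground` are dropped; the default
#' keeps every tile.
#'
#' @param slide A [slide_image()].
#' @param size Tile side length (default 1024).
#' @param shift Lattice shift (default 512).
#' @param min_foreground Minimum foreground fraction in `[0, 1]`; 0 disables
#'   the filter.
#' @param foreground_floor Intensity above which a pixel counts as tissue
#'   (default 20 on the 0-255 scale).
#' @return A `tile_grid`: list with `tiles` (each a list `id`, `offset`,
#'   `size`, `image`), `size`, `shift` and `slide_dim`.
#' @export
slice_slide <- function(slide, size = 1024L, shift = 512L,
                        min_foreground = 0, foreground_floor = 20) {
  stopifnot(inherits(slide, "slide_image"))
  px <- slide$pixels
  H <- nrow(px); W <- ncol(px)
  if (W < size || H < size)
    stop("slide smaller than one tile")
  base_x <- seq.int(0L, W - size, by = size)
  base_y <- seq.int(0L, H - size, by = size)
  sh_x <- seq.int(shift, W, by = size); sh_x <- sh_x[sh_x + size <= W]
  sh_y <- seq.int(shift, H, by = size); sh_y <- sh_y[sh_y + size <= H]
  offs <- rbind(expand.grid(x = base_x, y = base_y),
                if (length(sh_x) && length(sh_y))
                  expand.grid(x = sh_x, y = sh_y))
  offs <- unique(offs)
  tiles <- list()
  for (i in seq_len(nrow(offs))) {
    ox <- offs$x[i]; oy <- offs$y[i]
    img <- px[(oy + 1):(oy + size), (ox + 1):(ox + size), drop = FALSE]
    if (min_foreground > 0 &&
        mean(img > foreground_floor) < min_foreground) next
    tiles[[length(tiles) + 1L]] <-
      list(id = length(tiles) + 1L, offset = c(x = ox, y = oy),
           size = as.integer(size), image = img)
  }
  structure(list(tiles = tiles, size = as.integer(size),
                 shift = as.integer(shift), slide_dim = c(W, H)),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d tiles of %d px (shift %d) on %d x %d slide\n",
              length(x$tiles), x$size, x$shift, x$slide_dim[1], x$slide_dim[2]))
  invisible(x)
}

#' Map tile-frame predictions to slide coordinates
#'
#' Translates cell detections or a tubule fragment from the frame of a tile
#' to slide coordinates by the tile offset. The inverse translation
#' round-trips exactly.
#'
#' @param obj A [cell_detections()] table or a [tubule_fragment()] in tile
#'   frame.
#' @param tile A tile from [slice_slide()].
#' @return The same type of object in slide coordinates.
#' @export
to_slide_coords <- function(obj, tile) UseMethod("to_slide_coords")

#' @export
to_slide_coords.cell_detections <- function(obj, tile) {
  if (nrow(obj) == 0L) return(obj)
  if (any(obj$x0 < 0 | obj$y0 < 0 | obj$x1 > tile$size | obj$y1 > tile$size))
    stop("detection exceeds tile bounds")
  obj$x0 <- obj$x0 + tile$offset["x"]; obj$x1 <- obj$x1 + tile$offset["x"]
  obj$y0 <- obj$y0 + tile$offset["y"]; obj$y1 <- obj$y1 + tile$offset["y"]
  rownames(obj) <- NULL
  obj
}

#' @export
to_slide_coords.tubule_fragment <- function(obj, tile) {
  bb <- pm_bbox(obj$mask)
  if (bb[1] < 0 || bb[2] < 0 || bb[3] > tile$size || bb[4] > tile$size)
    stop("fragment exceeds tile bounds")
  obj$mask <- pm_shift(obj$mask, tile$offset["x"], tile$offset["y"])
  obj
}

#' Closed-form tile count for an unfiltered square slide
#'
#' For an `n x n` slide, the grid holds `floor(n/size)^2` base tiles plus
#' `floor((n - shift)/size)^2` shifted tiles.
#'
#' @param n Slide side length.
#' @param size,shift Tiling parameters.
#' @return Integer tile count.
#' @export
tile_count <- function(n, size = 1024L, shift = 512L) {
  as.integer(floor(n / size)^2 + floor((n - shift) / size)^2)
}
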