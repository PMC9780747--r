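# End-to-end pipeline driver and report generation.

#' Run the full staging pipeline on a slide
#'
#' Slices the slide into overlapping tiles; detects cells on each tile at
#' all four quarter-turn rotations and merges the rotation ensemble
#' (IOU > 0.5 suppression); stitches detections into slide coordinates and
#' merges duplicates across tiles by weighted majority vote (IOU >= 0.4);
#' fuses the pachytene annotation subclasses; segments tubule fragments per
#' tile, assembles them many-to-one into tubules and votes each tubule's
#' stage by the area-weighted product rule; assigns cells to tubules and
#' applies the stage-XII consistency rules; finally drops tubules on the
#' exclusion list (the curation mechanism for unsuitable cross-sections).
#'
#' @param slide A [slide_image()].
#' @param backend A detector backend ([oracle_backend()],
#'   [baseline_backend()], or any object implementing the contract).
#' @param tile_size,shift,min_foreground Tiling parameters
#'   (see [slice_slide()]).
#' @param exclude_tubules Integer ids of tubules to drop from all reports.
#' @return A `pipeline_result`: list with `cells`, `tubules`, `assignment`,
#'   `crosstab`, and `log` (a data frame of per-step object counts).
#' @export
run_pipeline <- function(slide, backend, tile_size = 1024L, shift = 512L,
                         min_foreground = 0, exclude_tubules = NULL) {
  log <- list()
  note <- function(step, count) log[[length(log) + 1L]] <<-
    data.frame(step = step, count = count)

  grid <- slice_slide(slide, size = tile_size, shift = shift,
                      min_foreground = min_foreground)
  note("tiles", length(grid$tiles))

  cells_per_tile <- list()
  fragments <- list()
  n_raw <- 0L
  for (tile in grid$tiles) {
    per_rot <- lapply(0:3, function(k) {
      d <- detect_cells(backend, tile, rotation = k)
      if (nrow(d) && k > 0) {
        bx <- t(apply(det_boxes(d), 1, rotate_box, k = (4L - k) %% 4L,
                      size = tile$size))
        d[, c("x0", "y0", "x1", "y1")] <- bx
      }
      d
    })
    n_raw <- n_raw + sum(vapply(per_rot, nrow, 0L))
    merged <- merge_rotation_ensemble(per_rot)
    merged <- contract_filter_cells(merged)
    cells_per_tile[[length(cells_per_tile) + 1L]] <-
      to_slide_coords(merged, tile)
    frags <- contract_filter_fragments(segment_tubules(backend, tile))
    fragments <- c(fragments, lapply(frags, to_slide_coords, tile = tile))
  }
  note("raw cell detections", n_raw)
  cells <- rbind_detections(cells_per_tile)
  note("after rotation merge", nrow(cells))
  cells <- merge_cross_tile(cells)
  note("after cross-tile merge", nrow(cells))
  cells <- fuse_pachytene(cells)
  note("tubule fragments", length(fragments))

  tubules <- group_fragments_to_tubules(fragments)
  note("tubules", length(tubules))
  assignment <- assign_cells_to_tubules(cells, tubules)
  res <- apply_stage12_rules(tubules, cells, assignment)
  tubules <- res$tubules; cells <- res$cells; assignment <- res$assignment
  note("cells after stage-XII rules", nrow(cells))

  if (!is.null(exclude_tubules)) {
    keep <- !vapply(tubules, function(t) t$id %in% exclude_tubules, TRUE)
    dropped_ids <- vapply(tubules[!keep], function(t) t$id, 0L)
    tubules <- tubules[keep]
    drop_cells <- assignment %in% dropped_ids
    cells <- cells[!drop_cells, , drop = FALSE]
    rownames(cells) <- NULL
    assignment <- assignment[!drop_cells]
    note("tubules after exclusion", length(tubules))
  }

  structure(list(cells = cells, tubules = tubules, assignment = assignment,
                 crosstab = crosstab_report(cells, tubules, assignment),
                 log = do.call(rbind, log)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d tubules, %d cells (%d interstitial)\n",
              length(x$tubules), nrow(x$cells), sum(is.na(x$assignment))))
  stages <- vapply(x$tubules, function(t) t$stage, "")
  print(table(factor(stages, levels = stage_classes())))
  invisible(x)
}

#' Cell-class by stage crosstab report
#'
#' The summary table of pipeline output: counts of assigned
#' (non-interstitial) cells per cell class (rows, canonical order) and the
#' stage of their tubule (columns I-V through XII).
#'
#' @param cells,tubules,assignment Pipeline output components.
#' @return A `crosstab`: list with `counts` (9 x 5 integer matrix),
#'   `row_totals`, `col_totals`, `n_interstitial`.
#' @export
crosstab_report <- function(cells, tubules, assignment) {
  counts <- matrix(0L, length(cell_classes()), length(stage_classes()),
                   dimnames = list(cell_classes(), stage_classes()))
  stage_of <- setNames(vapply(tubules, function(t) t$stage, ""),
                       vapply(tubules, function(t) t$id, 0L))
  for (i in seq_len(nrow(cells))) {
    if (is.na(assignment[i])) next
    st <- stage_of[[as.character(assignment[i])]]
    counts[cells$class[i], st] <- counts[cells$class[i], st] + 1L
  }
  structure(list(counts = counts, row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 n_interstitial = sum(is.na(assignment))),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, sum(x$row_totals)))
  print(m)
  cat(sprintf("(%d interstitial cells not shown)\n", x$n_interstitial))
  invisible(x)
}

# Deterministic palettes (RGB in 0-1).
stage_palette <- function() {
  setNames(c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e"),
           stage_classes())
}
class_palette <- function() {
  setNames(c("#4477AA", "#66CCEE", "#228833", "#CCBB44", "#EE6677",
             "#AA3377", "#BBBBBB", "#EE8866", "#99DDFF"), cell_classes())
}

hex_to_rgb <- function(h) as.numeric(grDevices::col2rgb(h)) / 255

# Outline of a pixmask: set pixels with at least one unset 4-neighbour.
mask_outline <- function(mask) {
  m <- mask$m
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  pixmask(mask$x0, mask$y0, m & !interior)
}

#' Render a color overlay of pipeline results
#'
#' The grayscale slide with tubule contours colored by stage and cell box
#' outlines colored by class, plus an embedded legend of the palettes in
#' use. The palette is deterministic.
#'
#' @param slide A [slide_image()].
#' @param result A `pipeline_result` (or `NULL` components for an empty
#'   overlay).
#' @param file Output PNG path.
#' @return `file`, invisibly.
#' @export
render_overlay <- function(slide, result, file) {
  base <- pmin(pmax(slide$pixels / 255, 0), 1)
  H <- nrow(base); W <- ncol(base)
  # three channel matrices modified in place (never passed to helpers, so
  # no whole-image copies are triggered)
  rch <- base; gch <- base; bch <- base
  spal <- stage_palette(); cpal <- class_palette()
  present_stages <- character(0); present_classes <- character(0)
  for (t in result$tubules) {
    ol <- mask_outline(t$union_mask)
    pos <- which(ol$m, arr.ind = TRUE)
    if (!nrow(pos)) next
    col <- hex_to_rgb(spal[[t$stage]])
    present_stages <- union(present_stages, t$stage)
    ys0 <- pos[, 1] + ol$y0; xs0 <- pos[, 2] + ol$x0
    ys <- pmin(pmax(c(ys0 - 1, ys0, ys0 + 1, ys0, ys0), 1), H)
    xs <- pmin(pmax(c(xs0, xs0, xs0, xs0 - 1, xs0 + 1), 1), W)
    idx <- cbind(ys, xs)
    rch[idx] <- col[1]; gch[idx] <- col[2]; bch[idx] <- col[3]
  }
  cells <- result$cells
  for (i in seq_len(NROW(cells))) {
    col <- hex_to_rgb(cpal[[cells$class[i]]])
    present_classes <- union(present_classes, cells$class[i])
    xs <- pmin(pmax((floor(cells$x0[i]):floor(cells$x1[i])) + 1, 1), W)
    ys <- pmin(pmax((floor(cells$y0[i]):floor(cells$y1[i])) + 1, 1), H)
    idx <- rbind(cbind(rep(min(ys), length(xs)), xs),
                 cbind(rep(max(ys), length(xs)), xs),
                 cbind(ys, rep(min(xs), length(ys))),
                 cbind(ys, rep(max(xs), length(ys))))
    rch[idx] <- col[1]; gch[idx] <- col[2]; bch[idx] <- col[3]
  }
  # embedded legend: one filled swatch row per palette entry in use
  leg <- c(setNames(spal[present_stages], present_stages),
           setNames(cpal[present_classes], present_classes))
  y <- 6
  for (li in seq_along(leg)) {
    col <- hex_to_rgb(leg[li])
    ys <- pmin(y:(y + 8), H); xs <- pmin(6:40, W)
    rch[ys, xs] <- col[1]; gch[ys, xs] <- col[2]; bch[ys, xs] <- col[3]
    y <- y + 12
    if (y + 9 > H) break
  }
  arr <- array(c(rch, gch, bch), c(H, W, 3))
  png::writePNG(arr, file)
  invisible(file)
}

#' Analyze a slide end to end and write a report directory
#'
#' Runs [run_pipeline()] and writes: `tubules.json` (id, stage, log score
#' vector, fragment count, area), `cells.csv` (box, class, second class,
#' tubule id), `crosstab.csv`, `overlay.png` and `log.csv`. Reruns with the
#' same inputs and configuration are byte-identical.
#'
#' @param slide A [slide_image()] or a path readable by
#'   [read_slide_image()].
#' @param backend A detector backend.
#' @param out_dir Report directory (created if missing).
#' @param ... Passed to [run_pipeline()] (`tile_size`, `shift`,
#'   `min_foreground`, `exclude_tubules`).
#' @return The `pipeline_result`, invisibly.
#' @export
analyze <- function(slide, backend, out_dir, ...) {
  if (is.character(slide)) slide <- read_slide_image(slide)
  res <- run_pipeline(slide, backend, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tub <- lapply(res$tubules, function(t)
    list(id = t$id, stage = t$stage,
         log_score = as.list(round(t$stage_score, 6)),
         n_fragments = length(t$fragments), area_px = t$area_px))
  jsonlite::write_json(tub, file.path(out_dir, "tubules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cells_df <- as.data.frame(res$cells[, c("x0", "y0", "x1", "y1", "class",
                                          "second_class", "top_conf",
                                          "n_merged")])
  cells_df$tubule_id <- res$assignment
  write.csv(cells_df, file.path(out_dir, "cells.csv"), row.names = FALSE)
  ct <- res$crosstab
  write.csv(cbind(as.data.frame(ct$counts), Total = ct$row_totals),
            file.path(out_dir, "crosstab.csv"))
  write.csv(res$log, file.path(out_dir, "log.csv"), row.names = FALSE)
  render_overlay(slide, res, file.path(out_dir, "overlay.png"))
  invisible(res)
}
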