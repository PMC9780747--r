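# Prediction merging and tubule assembly: rotation-ensemble suppression,
# cross-tile weighted majority voting, many-to-one fragment grouping, the
# area-weighted product stage vote, and the stage-XII consistency rules.

rbind_detections <- function(lst) {
  lst <- Filter(function(d) nrow(d) > 0, lst)
  if (!length(lst)) return(empty_cell_detections())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  class(out) <- c("cell_detections", "data.frame")
  out
}

#' Merge the four rotation-ensemble detection sets
#'
#' Detections from the four quarter-turn passes (already mapped back to the
#' unrotated tile frame) are pooled, sorted by descending confidence (ties
#' broken by rotation order of arrival), and greedily kept: a detection
#' survives iff its IOU with every already-kept detection is at most 0.5
#' (overlaps strictly above 0.5 are discarded).
#'
#' @param per_rotation List of [cell_detections()] tables in tile frame.
#' @param iou_max Suppression threshold (strict `>`), default 0.5.
#' @return A single [cell_detections()] table, deterministically ordered.
#' @export
merge_rotation_ensemble <- function(per_rotation, iou_max = 0.5) {
  all <- rbind_detections(per_rotation)
  n <- nrow(all)
  if (n <= 1L) return(all)
  ord <- order(-all$top_conf, seq_len(n))
  all <- all[ord, , drop = FALSE]
  boxes <- det_boxes(all)
  keep <- integer(0)
  for (i in seq_len(n)) {
    if (length(keep)) {
      ious <- box_iou_matrix(boxes[i, , drop = FALSE],
                             boxes[keep, , drop = FALSE])
      if (any(ious > iou_max)) next
    }
    keep <- c(keep, i)
  }
  out <- all[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Single-linkage clusters of boxes with IOU >= iou_min, using a spatial grid
# on box centres so only nearby pairs are compared.
cluster_boxes <- function(boxes, iou_min) {
  n <- nrow(boxes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cx <- (boxes[, 1] + boxes[, 3]) / 2
  cy <- (boxes[, 2] + boxes[, 4]) / 2
  bin <- max(max(boxes[, 3] - boxes[, 1]), max(boxes[, 4] - boxes[, 2]), 1)
  key <- paste(floor(cx / bin), floor(cy / bin))
  grid <- split(seq_len(n), key)
  keys <- strsplit(names(grid), " ")
  kx <- vapply(keys, function(k) as.integer(k[1]), 0L)
  ky <- vapply(keys, function(k) as.integer(k[2]), 0L)
  keymap <- new.env(hash = TRUE)
  for (g in seq_along(grid)) assign(names(grid)[g], g, envir = keymap)
  for (g in seq_along(grid)) {
    idx <- grid[[g]]
    # neighbours: same cell and the 4 forward-adjacent cells (each unordered
    # pair of cells is visited once)
    nb <- idx
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      k2 <- paste(kx[g] + d[1], ky[g] + d[2])
      g2 <- mget(k2, envir = keymap, ifnotfound = list(NULL))[[1]]
      if (!is.null(g2)) nb <- c(nb, grid[[g2]])
    }
    if (length(nb) < 2) next
    ious <- box_iou_matrix(boxes[idx, , drop = FALSE],
                           boxes[nb, , drop = FALSE])
    hits <- which(ious >= iou_min, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      a <- idx[hits[h, 1]]; b <- nb[hits[h, 2]]
      if (a == b) next
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Merge duplicated cell predictions across overlapping tiles
#'
#' Detections of the same cell seen from several half-overlapping tiles
#' (IOU at least `iou_min`, single linkage) are merged by weighted majority
#' vote: per-class scores are the sums of member confidence vectors, the
#' top class is the argmax and the runner-up class is retained as the
#' second-best prediction (absent when no other class received any vote).
#' The merged box is the confidence-weighted mean of member boxes, and the
#' merged confidence vector is the normalized vote vector. Merging is
#' idempotent: running it on its own output changes nothing.
#'
#' @param cells A [cell_detections()] table in slide coordinates.
#' @param iou_min Clustering threshold (inclusive), default 0.4.
#' @return A merged [cell_detections()] table.
#' @export
merge_cross_tile <- function(cells, iou_min = 0.4) {
  n <- nrow(cells)
  if (n <= 1L) return(cells)
  boxes <- det_boxes(cells)
  comp <- cluster_boxes(boxes, iou_min)
  conf <- cells$conf
  classes <- colnames(conf)
  groups <- split(seq_len(n), comp)
  out_boxes <- matrix(0, length(groups), 4)
  out_conf <- matrix(0, length(groups), length(classes),
                     dimnames = list(NULL, classes))
  second <- character(length(groups))
  n_merged <- integer(length(groups))
  src <- character(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    votes <- if (length(idx) == 1L) conf[idx, ] else colSums(conf[idx, , drop = FALSE])
    w <- cells$top_conf[idx]
    out_boxes[g, ] <- colSums(boxes[idx, , drop = FALSE] * w) / sum(w)
    out_conf[g, ] <- votes / sum(votes)
    ord <- order(-votes, seq_along(votes))
    second[g] <- if (length(ord) > 1 && votes[ord[2]] > 0)
      classes[ord[2]] else NA_character_
    n_merged[g] <- length(idx)
    src[g] <- cells$source[idx[1]]
  }
  cell_detections(out_boxes, out_conf, source = src, n_merged = n_merged,
                  second_class = second)
}

#' Assemble tubule fragments into tubules (many-to-one mapping)
#'
#' Fragments form a graph with an edge whenever their pairwise mask
#' intersection is at least `overlap_min` times the smaller fragment's
#' area; connected components become tubules. Tubule ids follow scanline
#' order (y, then x) of the union-mask centroids, so output is
#' deterministic.
#'
#' @param fragments List of [tubule_fragment()] objects in slide
#'   coordinates.
#' @param overlap_min Edge threshold as a fraction of the smaller
#'   fragment's area, default 0.1.
#' @return List of `tubule` objects: `id`, `union_mask`, `fragments`,
#'   `stage`, `stage_score`, `area_px` (stage filled by
#'   [vote_tubule_stage()]).
#' @export
group_fragments_to_tubules <- function(fragments, overlap_min = 0.1) {
  n <- length(fragments)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  bbs <- t(vapply(fragments, function(f) pm_bbox(f$mask), numeric(4)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bbs[i, 3] <= bbs[j, 1] || bbs[j, 3] <= bbs[i, 1] ||
        bbs[i, 4] <= bbs[j, 2] || bbs[j, 4] <= bbs[i, 2]) next
    inter <- pm_intersect_area(fragments[[i]]$mask, fragments[[j]]$mask)
    if (inter >= overlap_min * min(fragments[[i]]$area_px,
                                   fragments[[j]]$area_px)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), comp)
  tubules <- lapply(groups, function(idx) {
    um <- fragments[[idx[1]]]$mask
    for (k in idx[-1]) um <- pm_union(um, fragments[[k]]$mask)
    pos <- which(um$m, arr.ind = TRUE)
    centroid <- c(um$x0 + mean(pos[, 2]) - 1, um$y0 + mean(pos[, 1]) - 1)
    list(union_mask = um, fragments = fragments[idx],
         area_px = pm_area(um), centroid = centroid)
  })
  ord <- order(vapply(tubules, function(t) t$centroid[2], 0),
               vapply(tubules, function(t) t$centroid[1], 0))
  tubules <- tubules[ord]
  for (i in seq_along(tubules)) tubules[[i]]$id <- i
  lapply(tubules, function(t) {
    v <- vote_tubule_stage(t)
    t$stage <- v$stage
    t$stage_score <- v$score
    structure(t, class = "tubule")
  })
}

#' Vote the stage of an assembled tubule
#'
#' For fragment i and stage c the weighted confidence is
#' `w_i(c) = stage_conf_i(c) * area_i / union_area`; larger masks thus
#' carry more weight. The tubule score is the product of the `w_i(c)` over
#' fragments, computed in log space with a floor of 1e-6 on each factor so
#' a single zero-confidence fragment cannot veto a stage. The stage is the
#' argmax; ties break by stage-class order.
#'
#' @param tubule A tubule (list with `fragments` and `area_px`) from
#'   [group_fragments_to_tubules()].
#' @return List with `stage` and `score` (named log-score vector).
#' @export
vote_tubule_stage <- function(tubule) {
  frags <- tubule$fragments
  if (!length(frags)) stop("cannot vote the stage of an empty tubule")
  union_area <- tubule$area_px
  logS <- setNames(numeric(length(stage_classes())), stage_classes())
  for (f in frags) {
    w <- f$stage_conf * (f$area_px / union_area)
    logS <- logS + log(pmax(w, 1e-6))
  }
  stage <- stage_classes()[which.max(logS)]
  list(stage = stage, score = logS)
}

#' Assign cells to tubules by box centre
#'
#' A cell belongs to the tubule whose union mask contains its box centre;
#' when two tubule masks share the pixel, the lower tubule id wins. Cells
#' inside no tubule are interstitial (`NA`).
#'
#' @param cells A [cell_detections()] table in slide coordinates.
#' @param tubules List of tubules from [group_fragments_to_tubules()].
#' @return Integer vector of tubule ids (NA = interstitial), one per cell.
#' @export
assign_cells_to_tubules <- function(cells, tubules) {
  n <- nrow(cells)
  assign <- rep(NA_integer_, n)
  if (n == 0L || !length(tubules)) return(assign)
  cx <- (cells$x0 + cells$x1) / 2
  cy <- (cells$y0 + cells$y1) / 2
  for (t in tubules) {
    open <- is.na(assign)
    if (!any(open)) break
    hit <- open
    hit[open] <- pm_contains(t$union_mask, cx[open], cy[open])
    assign[hit] <- t$id
  }
  assign
}

#' Apply the stage-XII biological consistency rules
#'
#' Two rules, applied once, in order. Rule 1: a tubule staged XII that
#' contains no cell labeled `m2m` (metaphase plates) or `Spc-sec`
#' (secondary spermatocytes) is restaged I-V. Rule 2: any `m2m` or
#' `Spc-sec` cell sitting in a tubule not staged XII is relabeled to its
#' second-best class when one exists, otherwise deleted. Rule 2 does not
#' re-trigger Rule 1. Interstitial cells are untouched.
#'
#' @param tubules List of tubules with voted stages.
#' @param cells A [cell_detections()] table.
#' @param assignment Integer tubule-id vector from
#'   [assign_cells_to_tubules()].
#' @return List with updated `tubules`, `cells` and `assignment` (rows of
#'   deleted cells removed from both).
#' @export
apply_stage12_rules <- function(tubules, cells, assignment) {
  hallmark <- c("m2m", "Spc-sec")
  # Rule 1: XII without meiotic hallmark cells -> I-V
  for (i in seq_along(tubules)) {
    if (tubules[[i]]$stage != "XII") next
    member <- which(assignment == tubules[[i]]$id)
    if (!any(cells$class[member] %in% hallmark))
      tubules[[i]]$stage <- "I-V"
  }
  # Rule 2: hallmark cells outside XII tubules
  stage_of <- setNames(vapply(tubules, function(t) t$stage, ""),
                       vapply(tubules, function(t) t$id, 0L))
  in_tubule <- !is.na(assignment)
  bad <- in_tubule & cells$class %in% hallmark &
    stage_of[as.character(assignment)] != "XII"
  bad[is.na(bad)] <- FALSE
  has_second <- bad & !is.na(cells$second_class)
  if (any(has_second)) {
    idx <- which(has_second)
    cells$class[idx] <- cells$second_class[idx]
    cells$top_conf[idx] <- cells$conf[cbind(idx, match(cells$class[idx],
                                                       colnames(cells$conf)))]
    cells$second_class[idx] <- NA_character_
  }
  drop <- bad & !has_second
  if (any(drop)) {
    cells <- cells[!drop, , drop = FALSE]
    rownames(cells) <- NULL
    assignment <- assignment[!drop]
  }
  list(tubules = tubules, cells = cells, assignment = assignment)
}
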