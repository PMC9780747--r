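# Pluggable detection backends. A backend is any object with S3 methods
# detect_cells(backend, tile, rotation) and segment_tubules(backend, tile)
# returning tile-frame predictions. Score thresholds (0.5 for cells, 0.3
# for tubule fragments) live in the contract, not in the backends, so all
# backends are comparable: the pipeline suppresses sub-threshold output
# from every backend alike.

#' Detect cells on a tile (detection contract)
#'
#' @param backend A detector backend (e.g. [oracle_backend()] or
#'   [baseline_backend()]).
#' @param tile A tile from [slice_slide()].
#' @param rotation Quarter turns applied to the tile before detection;
#'   returned coordinates are in the rotated frame.
#' @return A [cell_detections()] table in the (rotated) tile frame.
#' @export
detect_cells <- function(backend, tile, rotation = 0L) UseMethod("detect_cells")

#' Segment tubule fragments on a tile (detection contract)
#'
#' @inheritParams detect_cells
#' @return List of [tubule_fragment()] objects in tile frame.
#' @export
segment_tubules <- function(backend, tile) UseMethod("segment_tubules")

# Contract-level score suppression.
contract_filter_cells <- function(cells) {
  cells[cells$top_conf >= CELL_SCORE_MIN, , drop = FALSE]
}
contract_filter_fragments <- function(frags) {
  Filter(function(f) max(f$stage_conf) >= TUBULE_SCORE_MIN, frags)
}

#' Noise model for the ground-truth oracle backend
#'
#' With all parameters zero the oracle reproduces ground truth exactly with
#' confidence 1. Noise is realized once per ground-truth object (not per
#' tile or rotation), so repeated views of the same cell in overlapping
#' tiles agree and a drop probability `d` translates directly into detector
#' sensitivity `1 - d`. Label flips apply both to cell class labels and to
#' fragment stage labels; fragment flips are realized independently per
#' (tubule, tile) pair.
#'
#' @param label_flip_prob Probability a label is replaced by a uniformly
#'   random other class.
#' @param box_jitter_px Uniform integer jitter (+-px) applied to each box.
#' @param drop_prob Probability a ground-truth object is not emitted.
#' @param conf_on_label Confidence mass placed on the emitted label; the
#'   remainder is spread uniformly over the other classes.
#' @param seed Integer seed making the noise realization deterministic.
#' @return A list of class `oracle_noise`.
#' @export
oracle_noise <- function(label_flip_prob = 0, box_jitter_px = 0,
                         drop_prob = 0, conf_on_label = 1, seed = 1L) {
  stopifnot(label_flip_prob >= 0, label_flip_prob <= 1,
            drop_prob >= 0, drop_prob <= 1, box_jitter_px >= 0,
            conf_on_label > 0, conf_on_label <= 1)
  structure(list(label_flip_prob = label_flip_prob,
                 box_jitter_px = box_jitter_px, drop_prob = drop_prob,
                 conf_on_label = conf_on_label, seed = as.integer(seed)),
            class = "oracle_noise")
}

# Spread (1 - conf_on_label) uniformly over the non-emitted classes.
conf_vector <- function(label, classes, conf_on_label) {
  v <- rep((1 - conf_on_label) / (length(classes) - 1), length(classes))
  names(v) <- classes
  v[label] <- conf_on_label
  v
}

#' Ground-truth oracle backend with injectable noise
#'
#' Emits the generator's ground-truth annotations, optionally corrupted by
#' an [oracle_noise()] model, enabling end-to-end pipeline tests without
#' trained weights. Cell noise (drops, label flips, box jitter) is realized
#' once over the whole annotation set at construction time; fragment stage
#' flips are drawn per (tubule, tile) with a seed derived from the noise
#' seed, so all output is deterministic.
#'
#' @param truth An `annotation_set` (from [generate_slide()] or
#'   [read_coco_annotations()]).
#' @param noise An [oracle_noise()].
#' @return A detector backend of class `oracle_backend`.
#' @export
oracle_backend <- function(truth, noise = oracle_noise()) {
  cells <- truth$cells
  withr::with_seed(noise$seed, {
    keep <- runif(nrow(cells)) >= noise$drop_prob
    cells <- cells[keep, , drop = FALSE]
    n <- nrow(cells)
    if (n) {
      flip <- runif(n) < noise$label_flip_prob
      # flips confuse among the classes that actually occur in the truth
      pool <- unique(truth$cells$class)
      if (any(flip) && length(pool) > 1) {
        cells$class[flip] <- vapply(cells$class[flip], function(cl)
          sample(setdiff(pool, cl), 1), "")
      }
      if (noise$box_jitter_px > 0) {
        j <- noise$box_jitter_px
        dx <- sample(-j:j, n, replace = TRUE)
        dy <- sample(-j:j, n, replace = TRUE)
        cells$x0 <- cells$x0 + dx; cells$x1 <- cells$x1 + dx
        cells$y0 <- cells$y0 + dy; cells$y1 <- cells$y1 + dy
      }
    }
  })
  structure(list(cells = cells, tubules = truth$tubules,
                 dim = truth$dim, noise = noise),
            class = c("oracle_backend", "detector_backend"))
}

#' @export
detect_cells.oracle_backend <- function(backend, tile, rotation = 0L) {
  cells <- backend$cells
  ox <- tile$offset["x"]; oy <- tile$offset["y"]; s <- tile$size
  cx <- (cells$x0 + cells$x1) / 2; cy <- (cells$y0 + cells$y1) / 2
  sel <- cx >= ox & cx < ox + s & cy >= oy & cy < oy + s
  cells <- cells[sel, , drop = FALSE]
  if (!nrow(cells))
    return(empty_cell_detections(union(cell_classes(),
                                       unique(backend$cells$class))))
  boxes <- cbind(pmax(cells$x0 - ox, 0), pmax(cells$y0 - oy, 0),
                 pmin(cells$x1 - ox, s), pmin(cells$y1 - oy, s))
  if (rotation %% 4L != 0L)
    boxes <- t(apply(boxes, 1, rotate_box, k = rotation, size = s))
  classes <- union(cell_classes(), unique(cells$class))
  conf <- t(vapply(cells$class, conf_vector, numeric(length(classes)),
                   classes = classes,
                   conf_on_label = backend$noise$conf_on_label))
  colnames(conf) <- classes
  cell_detections(boxes, conf,
                  source = sprintf("tile%d_r%d", tile$id, rotation))
}

#' @export
segment_tubules.oracle_backend <- function(backend, tile) {
  ox <- tile$offset["x"]; oy <- tile$offset["y"]; s <- tile$size
  noise <- backend$noise
  frags <- list()
  for (t in backend$tubules) {
    clip <- pm_clip(t$mask, ox, oy, ox + s, oy + s)
    if (is.null(clip)) next
    stage <- t$stage
    if (noise$label_flip_prob > 0) {
      local_seed <- (noise$seed * 48271 + t$id * 7919 + tile$id * 104729) %%
        2147483647L
      withr::with_seed(as.integer(local_seed), {
        if (runif(1) < noise$label_flip_prob)
          stage <- sample(setdiff(stage_classes(), stage), 1)
      })
    }
    clip <- pm_shift(clip, -ox, -oy)  # tile frame
    frags[[length(frags) + 1L]] <- tubule_fragment(
      clip, conf_vector(stage, stage_classes(), noise$conf_on_label))
  }
  frags
}

#' Parameters of the classical blob-detector baseline
#'
#' @param intensity_floor Threshold above which pixels are considered
#'   nuclear signal (0-255 scale).
#' @param min_area_px Minimum connected-component area kept.
#' @param centroids Per-class (area, intensity, eccentricity) centroids;
#'   defaults to the values implied by [render_params()] via
#'   [render_feature_centroids()].
#' @param feature_scale Divisors normalizing the three features before
#'   nearest-centroid distances are computed.
#' @return A list of class `baseline_params`.
#' @export
baseline_params <- function(intensity_floor = 75, min_area_px = 12L,
                            centroids = render_feature_centroids(),
                            feature_scale = c(area = 60, intensity = 25,
                                              ecc = 0.25)) {
  structure(list(intensity_floor = intensity_floor,
                 min_area_px = as.integer(min_area_px),
                 centroids = centroids, feature_scale = feature_scale),
            class = "baseline_params")
}

#' Classical baseline detector backend
#'
#' A weights-free demonstration backend: nuclei are found by intensity
#' thresholding plus connected-component labeling, filtered by area, and
#' classified by the nearest per-class centroid in (area, mean intensity,
#' eccentricity) feature space; confidence is the normalized inverse
#' centroid distance. Tubule fragments are tissue blobs found at a low
#' intensity floor, staged by a composition heuristic over the cell classes
#' detected inside them.
#'
#' @param params A [baseline_params()].
#' @return A detector backend of class `baseline_backend`.
#' @export
baseline_backend <- function(params = baseline_params()) {
  structure(list(params = params),
            class = c("baseline_backend", "detector_backend"))
}

# Blob features from a label matrix: area, mean intensity, eccentricity
# (from second central moments), bounding box. Single pass over the set
# pixels so tiles with hundreds of nuclei stay fast.
blob_features <- function(lab, img) {
  v <- as.integer(lab)
  pos <- which(v > 0L)
  if (!length(pos)) return(list())
  h <- nrow(lab)
  ys <- (pos - 1L) %% h + 1L
  xs <- (pos - 1L) %/% h + 1L
  f <- factor(v[pos])
  sp_y <- split(ys, f); sp_x <- split(xs, f); sp_i <- split(img[pos], f)
  lapply(seq_along(sp_y), function(k) {
    ys <- sp_y[[k]]; xs <- sp_x[[k]]
    mu_y <- mean(ys); mu_x <- mean(xs)
    cyy <- mean((ys - mu_y)^2); cxx <- mean((xs - mu_x)^2)
    cxy <- mean((xs - mu_x) * (ys - mu_y))
    tr <- cxx + cyy
    disc <- sqrt(max(tr^2 / 4 - (cxx * cyy - cxy^2), 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    list(area = length(ys), intensity = mean(sp_i[[k]]),
         ecc = if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0,
         box = c(min(xs) - 1, min(ys) - 1, max(xs), max(ys)))
  })
}

#' Detect nuclei on a single tile image with the baseline detector
#'
#' @param tile_img Numeric matrix (grayscale tile, 0-255).
#' @param params A [baseline_params()].
#' @return A [cell_detections()] table in tile frame.
#' @export
baseline_detect_cells <- function(tile_img, params = baseline_params()) {
  bw <- tile_img > params$intensity_floor
  if (!any(bw)) return(empty_cell_detections())
  lab <- EBImage::bwlabel(bw)
  feats <- blob_features(lab, tile_img)
  feats <- Filter(function(f) f$area >= params$min_area_px, feats)
  if (!length(feats)) return(empty_cell_detections())
  cen <- params$centroids
  sc <- params$feature_scale
  boxes <- t(vapply(feats, function(f) f$box, numeric(4)))
  conf <- t(vapply(feats, function(f) {
    d <- sqrt(((cen[, "area"] - f$area) / sc["area"])^2 +
                ((cen[, "intensity"] - f$intensity) / sc["intensity"])^2 +
                ((cen[, "ecc"] - f$ecc) / sc["ecc"])^2)
    w <- 1 / (d + 1e-6)
    w / sum(w)
  }, numeric(nrow(cen))))
  colnames(conf) <- rownames(cen)
  cell_detections(boxes, conf, source = "baseline")
}

#' @export
detect_cells.baseline_backend <- function(backend, tile, rotation = 0L) {
  img <- rotate_image(tile$image, rotation)
  d <- baseline_detect_cells(img, backend$params)
  if (nrow(d)) d$source <- sprintf("tile%d_r%d", tile$id, rotation)
  d
}

#' @export
segment_tubules.baseline_backend <- function(backend, tile) {
  # tissue = anything clearly above glass background, smoothed
  img <- EBImage::gblur(tile$image, sigma = 6)
  bw <- img > 22
  if (!any(bw)) return(list())
  lab <- EBImage::bwlabel(bw)
  cells <- baseline_detect_cells(tile$image, backend$params)
  rules <- stage_composition_rules()
  frags <- list()
  for (id in seq_len(max(lab))) {
    sel <- lab == id
    if (sum(sel) < 5000) next
    mask <- pixmask(0L, 0L, sel)
    inside <- pm_contains(mask, (cells$x0 + cells$x1) / 2,
                          (cells$y0 + cells$y1) / 2)
    present <- unique(cells$class[inside])
    score <- vapply(rules, function(r) {
      s <- mean(r$required %in% present)
      if (length(r$required_any))
        s <- s * (0.5 + 0.5 * any(r$required_any %in% present))
      if (any(r$forbidden %in% present)) s <- s * 0.3
      s
    }, 0)
    if (all(score == 0)) score[] <- 1
    conf <- 0.8 * score / sum(score) + 0.04
    names(conf) <- stage_classes()
    frags[[length(frags) + 1L]] <- tubule_fragment(mask, conf)
  }
  frags
}

#' Fuse pachytene annotation subclasses
#'
#' Relabels the annotation-dialect subclasses `Spc-Pach-early` and
#' `Spc-Pach-late` to `Spc-Pach`, summing their confidence entries into the
#' fused column; the fused set has exactly the nine canonical classes.
#'
#' @param cells A [cell_detections()] table (confidence columns may include
#'   the dialect subclasses).
#' @return The table with fused labels and a 9-column confidence matrix.
#' @export
fuse_pachytene <- function(cells) {
  subs <- pachytene_subclasses()
  conf <- cells$conf
  present <- intersect(subs, colnames(conf))
  if (length(present)) {
    fused <- conf[, "Spc-Pach", drop = TRUE]
    if (nrow(conf) == 0) fused <- numeric(0)
    for (s in present) fused <- fused + conf[, s]
    conf <- conf[, setdiff(colnames(conf), present), drop = FALSE]
    conf[, "Spc-Pach"] <- fused
    cells$conf <- conf
  }
  relab <- cells$class %in% subs
  if (any(relab)) {
    cells$class[relab] <- "Spc-Pach"
    cells$top_conf[relab] <- cells$conf[relab, "Spc-Pach"]
  }
  relab2 <- !is.na(cells$second_class) & cells$second_class %in% subs
  if (any(relab2)) cells$second_class[relab2] <- "Spc-Pach"
  cells
}
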