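# Shared fixtures. Synthetic slides are cached per (seed, size) within a
# test run so several test files can reuse the same generated material.

.fixture_cache <- new.env(parent = emptyenv())

cached_slide <- function(seed, n_tubules = 8L, dim = 2048L, markers = NULL) {
  key <- paste0("s", seed, "_n", n_tubules, "_d", dim, "_m",
                is.null(markers))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_slide(n_tubules = n_tubules,
                                            seed = seed, dim = dim,
                                            markers = markers)
  .fixture_cache[[key]]
}

# Stage accuracy of a pipeline result against generator truth: the
# predicted stage at each true tubule centroid.
stage_accuracy <- function(result, truth) {
  pmc <- semistage:::pm_contains
  pred <- vapply(truth$tubules, function(tt) {
    for (t in result$tubules)
      if (pmc(t$union_mask, tt$cx, tt$cy)) return(t$stage)
    NA_character_
  }, "")
  mean(pred == vapply(truth$tubules, function(t) t$stage, ""))
}

# A filled-rectangle pixmask covering the half-open box.
box_mask <- function(box) {
  pixmask(box[1], box[2],
          matrix(TRUE, box[4] - box[2], box[3] - box[1]))
}

# Detections with full confidence mass on one class per row.
make_cells <- function(boxes, labels, confs,
                       classes = cell_classes()) {
  boxes <- matrix(boxes, ncol = 4, byrow = TRUE)
  conf <- matrix(0, nrow(boxes), length(classes),
                 dimnames = list(NULL, classes))
  conf[cbind(seq_len(nrow(boxes)), match(labels, classes))] <- confs
  cell_detections(boxes, conf)
}

# Minimal annotation set.
make_truth <- function(cells, tubules = list(), dim = c(1024L, 1024L)) {
  structure(list(cells = cells, tubules = tubules, dim = dim),
            class = "annotation_set")
}

# One-tile stand-in (the oracle backend only reads offset/size/id).
make_tile <- function(offset = c(x = 0L, y = 0L), size = 1024L, id = 1L) {
  list(id = id, offset = offset, size = size,
       image = matrix(0, 8, 8))
}

# Brute-force pixel-set IOU of two boxes by lattice enumeration.
enum_box_iou <- function(a, b) {
  pa <- expand.grid(x = seq.int(a[1], a[3] - 1), y = seq.int(a[2], a[4] - 1))
  pb <- expand.grid(x = seq.int(b[1], b[3] - 1), y = seq.int(b[2], b[4] - 1))
  ka <- paste(pa$x, pa$y); kb <- paste(pb$x, pb$y)
  length(intersect(ka, kb)) / length(union(ka, kb))
}
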