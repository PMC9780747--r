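# Synthetic DAPI-like slides with exact ground truth. The generator does not
# imitate real chromatin texture; it guarantees that the nine cell classes
# are separable in (area, mean intensity, eccentricity) feature space so the
# classical baseline detector and all downstream pipeline logic are testable
# without trained neural weights.

#' Stage composition rules
#'
#' Encodes which cell classes are required, allowed, and forbidden in each
#' of the five epithelial stage classes, their radial layering (1 = basal,
#' 4 = luminal) and nominal per-class count ranges for a reference tubule of
#' 160 px radius (counts are scaled by tubule area at generation time).
#'
#' The rules follow the classical staging criteria: stages I-V and VI-VIII
#' carry round spermatids and late elongating spermatids (bundled in I-V),
#' stages IX and X-XI lack round spermatids while spermatids elongate, and
#' stage XII is defined by the presence of meiotic metaphase plates and/or
#' secondary spermatocytes. Sertoli cells are present at every stage.
#'
#' @return Named list over [stage_classes()]; each element has `required`,
#'   `required_any`, `allowed`, `forbidden`, `layer` (named integer) and
#'   `count` (named list of `c(lo, hi)` ranges).
#' @export
stage_composition_rules <- function() {
  L <- function(...) c(...)
  list(
    "I-V" = list(
      required = c("Sert", "Spg", "Spc-Pach", "RS", "elSpt-late"),
      required_any = character(0),
      allowed = "Spc-prePach",
      forbidden = c("elSpt-early", "m2m", "Spc-sec"),
      layer = L(Sert = 1L, Spg = 1L, "Spc-prePach" = 1L, "Spc-Pach" = 2L,
                RS = 3L, "elSpt-late" = 4L),
      count = list(Sert = c(8, 12), Spg = c(6, 10), "Spc-prePach" = c(0, 5),
                   "Spc-Pach" = c(12, 18), RS = c(22, 32),
                   "elSpt-late" = c(22, 32)),
      bundled = "elSpt-late"),
    "VI-VIII" = list(
      required = c("Sert", "Spc-prePach", "Spc-Pach", "RS", "elSpt-late"),
      required_any = character(0),
      allowed = "Spg",
      forbidden = c("elSpt-early", "m2m", "Spc-sec"),
      layer = L(Sert = 1L, Spg = 1L, "Spc-prePach" = 1L, "Spc-Pach" = 2L,
                RS = 3L, "elSpt-late" = 4L),
      count = list(Sert = c(8, 12), Spg = c(0, 5), "Spc-prePach" = c(6, 12),
                   "Spc-Pach" = c(12, 18), RS = c(22, 32),
                   "elSpt-late" = c(18, 28)),
      bundled = character(0)),
    "IX" = list(
      required = c("Sert", "Spc-prePach", "Spc-Pach", "elSpt-early"),
      required_any = character(0),
      allowed = "Spg",
      forbidden = c("RS", "elSpt-late", "m2m", "Spc-sec"),
      layer = L(Sert = 1L, Spg = 1L, "Spc-prePach" = 1L, "Spc-Pach" = 2L,
                "elSpt-early" = 4L),
      count = list(Sert = c(8, 12), Spg = c(0, 4), "Spc-prePach" = c(8, 14),
                   "Spc-Pach" = c(12, 18), "elSpt-early" = c(20, 30)),
      bundled = character(0)),
    "X-XI" = list(
      required = c("Sert", "Spc-prePach", "Spc-Pach", "elSpt-early"),
      required_any = character(0),
      allowed = c("Spg", "elSpt-late"),
      forbidden = c("RS", "m2m", "Spc-sec"),
      layer = L(Sert = 1L, Spg = 1L, "Spc-prePach" = 1L, "Spc-Pach" = 2L,
                "elSpt-early" = 4L, "elSpt-late" = 4L),
      count = list(Sert = c(8, 12), Spg = c(0, 4), "Spc-prePach" = c(8, 14),
                   "Spc-Pach" = c(12, 18), "elSpt-early" = c(20, 30),
                   "elSpt-late" = c(0, 5)),
      bundled = character(0)),
    "XII" = list(
      required = c("Sert", "Spc-Pach", "elSpt-late"),
      required_any = c("m2m", "Spc-sec"),
      allowed = c("Spg", "Spc-prePach"),
      forbidden = c("RS", "elSpt-early"),
      layer = L(Sert = 1L, Spg = 1L, "Spc-prePach" = 1L, "Spc-Pach" = 2L,
                "m2m" = 3L, "Spc-sec" = 3L, "elSpt-late" = 4L),
      count = list(Sert = c(8, 12), Spg = c(0, 4), "Spc-prePach" = c(0, 5),
                   "Spc-Pach" = c(10, 16), "m2m" = c(2, 6),
                   "Spc-sec" = c(2, 7), "elSpt-late" = c(18, 28)),
      bundled = character(0))
  )
}

#' Rendering parameters for the synthetic slide generator
#'
#' Per-class nuclear semi-axis range (px), mean intensity (0-255), axis
#' ratio (minor/major, eccentric classes such as metaphase plates and
#' elongating spermatids are elongated) and texture amplitude; plus tubule
#' geometry, background levels and noise. Nuclear statistics of real
#' material are not published, so these values are synthetic, chosen so the
#' per-class (area, intensity, eccentricity) centroids are separated by a
#' comfortable margin.
#'
#' @param ... Named overrides for the defaults.
#' @return A list of class `render_params`.
#' @export
render_params <- function(...) {
  p <- list(
    background = 12, tubule_interior = 30, tubule_wall = 60, wall_px = 5,
    noise_sd = 2.5,
    tubule_radius = c(130, 190), tubule_axis_ratio = c(0.78, 1),
    margin_px = 25, attempt_budget = 4000L,
    marker_background = 6, marker_noise_sd = 2, marker_contrast = 180,
    cell = data.frame(
      class = cell_classes(),
      r_lo = c(7.5, 6.0, 4.5, 9.0, 6.5, 5.0, 4.0, 4.0, 2.8),
      r_hi = c(8.5, 7.0, 5.5, 10.5, 7.5, 6.0, 5.0, 5.0, 3.5),
      intensity = c(100, 140, 165, 190, 215, 245, 125, 220, 250),
      axis_ratio = c(0.95, 0.90, 0.95, 0.90, 0.95, 0.50, 1.00, 0.60, 0.45),
      texture_amp = c(6, 6, 6, 8, 6, 4, 5, 4, 3),
      stringsAsFactors = FALSE))
  rownames(p$cell) <- p$cell$class
  modifyList(p, list(...))
}

#' Per-class feature centroids implied by the render parameters
#'
#' The (area, mean intensity, eccentricity) centroid of each class as
#' rendered, used by the classical baseline detector for nearest-centroid
#' classification.
#'
#' @param params A [render_params()] list.
#' @return Matrix 9 x 3 with columns `area`, `intensity`, `ecc`.
#' @export
render_feature_centroids <- function(params = render_params()) {
  cc <- params$cell
  r <- (cc$r_lo + cc$r_hi) / 2
  cbind(area = pi * r^2 * cc$axis_ratio,
        intensity = cc$intensity,
        ecc = sqrt(1 - cc$axis_ratio^2)) -> m
  rownames(m) <- cc$class
  m
}

#' Default marker rules for synthetic immunofluorescence channels
#'
#' Each marker names the cell classes and stage classes in which it is
#' expressed, emulating classical patterns: a pan-Sertoli marker (SOX9-like),
#' a stage-dependent Sertoli marker expressed only at early-to-mid stages
#' (AR-like), and a pan-spermatogonial marker (SALL4-like).
#'
#' @param contrast Rendered nuclear intensity of positive cells.
#' @return Named list of marker rules.
#' @export
default_marker_rules <- function(contrast = 180) {
  list(
    SOX9 = list(classes = "Sert", stages = stage_classes(), contrast = contrast),
    AR = list(classes = "Sert", stages = c("I-V", "VI-VIII"), contrast = contrast),
    SALL4 = list(classes = "Spg", stages = stage_classes(), contrast = contrast)
  )
}

# Draw integer count for a class, scaled by tubule area relative to the
# 160-px reference radius; required classes get at least 1.
draw_count <- function(range, scale, required) {
  n <- round(runif(1, range[1], range[2]) * scale)
  if (required) max(1L, n) else max(0L, as.integer(n))
}

# Radial band (fractions of tubule radius) per layer, basal -> luminal.
LAYER_BANDS <- rbind(c(0.80, 0.95), c(0.56, 0.78), c(0.32, 0.55), c(0.10, 0.31))

# Place cells of one tubule. Returns data.frame cx, cy, a, b, theta, class.
place_tubule_cells <- function(stage, rule, params, cx0, cy0, R, ratio, phi) {
  scale <- (R / 160)^2
  placed <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                       b = numeric(0), theta = numeric(0),
                       class = character(0), stringsAsFactors = FALSE)
  bundles <- NULL
  for (cls in names(rule$layer)) {
    cnt <- draw_count(rule$count[[cls]], scale, cls %in% rule$required)
    if (cnt == 0L) next
    layer <- rule$layer[[cls]]
    band <- LAYER_BANDS[layer, ]
    cp <- params$cell[cls, ]
    if (cls %in% rule$bundled && is.null(bundles)) {
      nb <- sample(4:6, 1)
      bth <- runif(nb, 0, 2 * pi)
      brf <- runif(nb, mean(band) - 0.05, mean(band) + 0.05)
      bundles <- cbind(bth, brf)
    }
    for (i in seq_len(cnt)) {
      a <- runif(1, cp$r_lo, cp$r_hi)
      b <- a * cp$axis_ratio
      ok <- FALSE
      for (try in 1:60) {
        if (cls %in% rule$bundled) {
          j <- sample(nrow(bundles), 1)
          th <- bundles[j, 1] + rnorm(1, 0, 0.12)
          rf <- bundles[j, 2] + rnorm(1, 0, 0.03)
        } else {
          th <- runif(1, 0, 2 * pi)
          rf <- sqrt(runif(1, band[1]^2, band[2]^2))
        }
        # position on the (unrotated) tubule ellipse, then rotate by phi
        ex <- rf * R * cos(th); ey <- rf * R * ratio * sin(th)
        px <- cx0 + ex * cos(phi) - ey * sin(phi)
        py <- cy0 + ex * sin(phi) + ey * cos(phi)
        if (nrow(placed)) {
          d2 <- (placed$cx - px)^2 + (placed$cy - py)^2
          if (any(d2 < (placed$a + a + 2)^2)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) next  # crowded layer: drop this cell
      theta <- if (cls %in% rule$bundled) atan2(py - cy0, px - cx0) else
        runif(1, 0, pi)
      placed <- rbind(placed, data.frame(cx = px, cy = py, a = a, b = b,
                                         theta = theta, class = cls,
                                         stringsAsFactors = FALSE))
    }
  }
  # guarantee the rule's required and required-any classes survived placement
  for (cls in rule$required)
    if (!cls %in% placed$class)
      stop("packing infeasible: required class ", cls, " could not be placed")
  if (length(rule$required_any) && !any(rule$required_any %in% placed$class))
    stop("packing infeasible: no ", paste(rule$required_any, collapse = "/"),
         " placed in a stage XII tubule")
  placed
}

# Paint an elliptical nucleus into the slide matrix (in place via return).
paint_ellipse <- function(px, mask, level, amp = 0) {
  h <- nrow(mask$m); w <- ncol(mask$m)
  ys <- (mask$y0 + 1):(mask$y0 + h); xs <- (mask$x0 + 1):(mask$x0 + w)
  win <- px[ys, xs, drop = FALSE]
  val <- level
  if (amp > 0) {
    tex <- amp * outer(sin(ys / 2.1), cos(xs / 2.3))
    val <- level + tex
  }
  win[mask$m] <- if (is.matrix(val)) val[mask$m] else val
  px[ys, xs] <- win
  px
}

#' Generate a synthetic DAPI-like testis cross-section slide
#'
#' Places non-overlapping elliptical tubules by dart throwing, draws each
#' tubule's stage from `stage_mix`, populates it with cells in radial layers
#' according to [stage_composition_rules()], and renders nuclei with
#' class-specific size/intensity/eccentricity plus Gaussian noise. Marker
#' channels are rendered per `markers` rules (positive nuclei bright).
#' Fully deterministic given `seed`.
#'
#' @param n_tubules Number of tubules to place.
#' @param stage_mix Named probability vector over [stage_classes()];
#'   must sum to 1.
#' @param params A [render_params()] list.
#' @param seed Integer seed.
#' @param dim Slide side length in px (multiple of 1024 recommended);
#'   `NULL` chooses automatically from `n_tubules`.
#' @param markers Named list of marker rules as in
#'   [default_marker_rules()], or `NULL` for no marker channels.
#' @param rules Composition rules (override for knockout emulation).
#' @param transitional_prob Probability that a tubule is transitional
#'   (composition mixed with the next stage; truth label stays the drawn
#'   stage). Default 0 so core tests have unambiguous truth.
#' @return List with `slide` ([slide_image()]), `truth` (an
#'   `annotation_set`: `cells` data frame, `tubules` list, `dim`),
#'   and `markers` (named list of channel matrices).
#' @export
generate_slide <- function(n_tubules = 30L,
                           stage_mix = c("I-V" = 0.35, "VI-VIII" = 0.25,
                                         "IX" = 0.10, "X-XI" = 0.15,
                                         "XII" = 0.15),
                           params = render_params(), seed = 1L, dim = NULL,
                           markers = default_marker_rules(),
                           rules = stage_composition_rules(),
                           transitional_prob = 0) {
  stopifnot(abs(sum(stage_mix) - 1) < 1e-8,
            all(names(stage_mix) %in% stage_classes()))
  if (is.null(dim))
    dim <- 1024L * max(2L, ceiling(sqrt(n_tubules * pi * 170^2 / 0.24) / 1024))
  dim <- as.integer(dim)
  withr::with_seed(as.integer(seed), {
    px <- matrix(params$background, dim, dim)
    # --- tubule placement by dart throwing ---
    centers <- matrix(numeric(0), 0, 2)
    tub <- list()
    tries <- 0L
    while (length(tub) < n_tubules) {
      tries <- tries + 1L
      if (tries > params$attempt_budget)
        stop("packing infeasible: attempt budget exhausted placing tubules")
      a <- runif(1, params$tubule_radius[1], params$tubule_radius[2])
      ratio <- runif(1, params$tubule_axis_ratio[1], params$tubule_axis_ratio[2])
      phi <- runif(1, 0, pi)
      cx <- runif(1, a + params$margin_px, dim - a - params$margin_px)
      cy <- runif(1, a + params$margin_px, dim - a - params$margin_px)
      if (!tile_cover_ok(c(floor(cx - a), floor(cy - a),
                           ceiling(cx + a), ceiling(cy + a)), dim)) next
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(d < sapply(tub, function(t) t$a) + a + params$margin_px)) next
      }
      stage <- sample(names(stage_mix), 1, prob = stage_mix)
      tub[[length(tub) + 1L]] <- list(id = length(tub) + 1L, cx = cx, cy = cy,
                                      a = a, b = a * ratio, ratio = ratio,
                                      phi = phi, stage = stage)
      centers <- rbind(centers, c(cx, cy))
    }
    # --- place cells, render per-tubule windows (avoids whole-slide copies) ---
    all_cells <- list()
    tubules <- list()
    marker_ch <- lapply(markers, function(.)
      matrix(params$marker_background, dim, dim))
    boxes_by_tub <- list()
    for (t in tub) {
      outer_m <- ellipse_mask(t$cx, t$cy, t$a, t$b, t$phi)
      inner_m <- ellipse_mask(t$cx, t$cy, t$a - params$wall_px,
                              t$b - params$wall_px, t$phi)
      rule <- rules[[t$stage]]
      if (transitional_prob > 0 && runif(1) < transitional_prob) {
        nxt <- stage_classes()[match(t$stage, stage_classes()) %% 5 + 1]
        rule <- mix_rules(rule, rules[[nxt]])
      }
      cells <- place_tubule_cells(t$stage, rule, params, t$cx, t$cy,
                                  t$a, t$ratio, t$phi)
      cells$tubule_id <- t$id
      all_cells[[t$id]] <- cells
      tubules[[t$id]] <- list(id = t$id, mask = outer_m, stage = t$stage,
                              cx = t$cx, cy = t$cy, a = t$a, b = t$b,
                              phi = t$phi)
      # window covering the tubule plus any nucleus poking past its rim
      pad <- 16L
      bb <- pm_bbox(outer_m)
      wx0 <- max(bb[1] - pad, 0L); wy0 <- max(bb[2] - pad, 0L)
      wx1 <- min(bb[3] + pad, dim); wy1 <- min(bb[4] + pad, dim)
      local <- px[(wy0 + 1):wy1, (wx0 + 1):wx1, drop = FALSE]
      local <- paint_ellipse(local, pm_shift(outer_m, -wx0, -wy0),
                             params$tubule_wall)
      local <- paint_ellipse(local, pm_shift(inner_m, -wx0, -wy0),
                             params$tubule_interior)
      boxes <- matrix(0, nrow(cells), 4)
      for (i in seq_len(nrow(cells))) {
        cp <- params$cell[cells$class[i], ]
        m <- ellipse_mask(cells$cx[i] - wx0, cells$cy[i] - wy0,
                          cells$a[i], cells$b[i], cells$theta[i])
        local <- paint_ellipse(local, m, cp$intensity, cp$texture_amp)
        boxes[i, ] <- ellipse_bbox(cells$cx[i], cells$cy[i], cells$a[i],
                                   cells$b[i], cells$theta[i])
      }
      px[(wy0 + 1):wy1, (wx0 + 1):wx1] <- local
      boxes_by_tub[[t$id]] <- boxes
      for (mk in names(markers)) {
        mrule <- markers[[mk]]
        if (!t$stage %in% mrule$stages) next
        sel <- which(cells$class %in% mrule$classes)
        if (!length(sel)) next
        loc <- marker_ch[[mk]][(wy0 + 1):wy1, (wx0 + 1):wx1, drop = FALSE]
        for (i in sel) {
          m <- ellipse_mask(cells$cx[i] - wx0, cells$cy[i] - wy0,
                            cells$a[i], cells$b[i], cells$theta[i])
          loc <- paint_ellipse(loc, m, mrule$contrast)
        }
        marker_ch[[mk]][(wy0 + 1):wy1, (wx0 + 1):wx1] <- loc
      }
    }
    cells <- do.call(rbind, all_cells)
    boxes <- do.call(rbind, boxes_by_tub)
    px <- px + matrix(rnorm(length(px), 0, params$noise_sd), nrow(px))
    px <- pmin(pmax(px, 0), 255)
    for (mk in names(marker_ch)) {
      ch <- marker_ch[[mk]] +
        matrix(rnorm(length(px), 0, params$marker_noise_sd), nrow(px))
      marker_ch[[mk]] <- pmin(pmax(ch, 0), 255)
    }
    truth_cells <- data.frame(id = seq_len(nrow(cells)),
                              x0 = boxes[, 1], y0 = boxes[, 2],
                              x1 = boxes[, 3], y1 = boxes[, 4],
                              class = cells$class,
                              tubule_id = cells$tubule_id,
                              stringsAsFactors = FALSE)
    truth <- structure(list(cells = truth_cells, tubules = tubules,
                            dim = c(dim, dim)),
                       class = "annotation_set")
    list(slide = slide_image(px), truth = truth, markers = marker_ch)
  })
}

# Is a bounding box either fully inside one tile of the default tiling, or
# fully inside the region covered by the shifted lattice? Either condition
# guarantees that the fragments of a tubule cut by tile borders overlap
# pairwise, so many-to-one grouping reassembles it. The generator places
# tubules only in such positions, mirroring real whole-testis scans where
# the tissue sits in the slide interior and border tubules are curated away.
tile_cover_ok <- function(bb, dim, size = 1024L, shift = 512L) {
  base_off <- seq.int(0L, dim - size, by = size)
  sh_off <- seq.int(shift, dim, by = size)
  sh_off <- sh_off[sh_off + size <= dim]
  fits <- function(offs) {
    any(vapply(offs, function(o) o <= bb[1] && bb[3] <= o + size, TRUE)) &&
      any(vapply(offs, function(o) o <= bb[2] && bb[4] <= o + size, TRUE))
  }
  one_tile <- (any(vapply(base_off, function(ox)
    ox <= bb[1] && bb[3] <= ox + size, TRUE)) &&
      any(vapply(base_off, function(oy)
        oy <= bb[2] && bb[4] <= oy + size, TRUE))) ||
    (length(sh_off) > 0 &&
       any(vapply(sh_off, function(ox)
         ox <= bb[1] && bb[3] <= ox + size, TRUE)) &&
       any(vapply(sh_off, function(oy)
         oy <= bb[2] && bb[4] <= oy + size, TRUE)))
  in_shifted_region <- length(sh_off) > 0 &&
    bb[1] >= shift && bb[2] >= shift &&
    bb[3] <= max(sh_off) + size && bb[4] <= max(sh_off) + size
  one_tile || in_shifted_region
}

# Blend two stage rules for a transitional tubule: union of layers, averaged
# count ranges, required = classes required by either stage that are not
# forbidden by the other.
mix_rules <- function(r1, r2) {
  classes <- union(names(r1$layer), names(r2$layer))
  layer <- sapply(classes, function(c)
    if (!is.null(r1$layer[[c]])) r1$layer[[c]] else r2$layer[[c]])
  count <- lapply(classes, function(c) {
    c1 <- r1$count[[c]]; c2 <- r2$count[[c]]
    if (is.null(c1)) c2 / 2 else if (is.null(c2)) c1 / 2 else (c1 + c2) / 2
  })
  names(count) <- classes
  list(required = setdiff(union(r1$required, r2$required),
                          union(r1$forbidden, r2$forbidden)),
       required_any = character(0),
       allowed = classes, forbidden = character(0),
       layer = layer, count = count, bundled = r1$bundled)
}

#' Generate a knockout-model synthetic slide
#'
#' `miwi` mode emulates spermatogenic arrest at the round-spermatid stage:
#' no early or late elongating spermatids are generated at any stage (their
#' counts are zeroed and they are dropped from the required sets). `spef2`
#' mode emulates abnormal spermatid head morphology: elongating spermatids
#' are rendered wider and less eccentric, but ground-truth labels are
#' identical to wild type.
#'
#' @param mode `"miwi"` or `"spef2"`.
#' @inheritParams generate_slide
#' @param ... Passed to [generate_slide()].
#' @return As [generate_slide()].
#' @export
generate_ko_slide <- function(mode = c("miwi", "spef2"), n_tubules = 30L,
                              params = render_params(), ...) {
  mode <- match.arg(mode)
  rules <- stage_composition_rules()
  if (mode == "miwi") {
    el <- c("elSpt-early", "elSpt-late")
    rules <- lapply(rules, function(r) {
      r$required <- setdiff(r$required, el)
      r$layer <- r$layer[setdiff(names(r$layer), el)]
      r$count <- r$count[setdiff(names(r$count), el)]
      r$bundled <- character(0)
      r
    })
  } else {
    cc <- params$cell
    el <- c("elSpt-early", "elSpt-late")
    cc[el, "axis_ratio"] <- pmin(1, cc[el, "axis_ratio"] * 1.6)
    cc[el, c("r_lo", "r_hi")] <- cc[el, c("r_lo", "r_hi")] * 1.25
    params$cell <- cc
  }
  generate_slide(n_tubules = n_tubules, params = params, rules = rules, ...)
}

#' Ground-truth cell-class by stage composition table
#'
#' Tallies the generator's ground-truth cells by class and by the stage of
#' their tubule; the reference the pipeline crosstab is compared against.
#'
#' @param truth An `annotation_set` from [generate_slide()].
#' @return Integer matrix 9 x 5 (classes x stages).
#' @export
truth_composition <- function(truth) {
  stages <- vapply(truth$tubules, function(t) t$stage, "")
  tab <- matrix(0L, length(cell_classes()), length(stage_classes()),
                dimnames = list(cell_classes(), stage_classes()))
  st <- stages[truth$cells$tubule_id]
  for (i in seq_len(nrow(truth$cells)))
    tab[truth$cells$class[i], st[i]] <- tab[truth$cells$class[i], st[i]] + 1L
  tab
}

#' Remove small tubule annotation masks
#'
#' Drops tubule masks strictly smaller than `min_area` pixels (the
#' training-data cleaning step; ~1% of a 1024 x 1024 tile). Cell
#' annotations are untouched.
#'
#' @param ann An `annotation_set`.
#' @param min_area Area floor in pixels (default 12000).
#' @return The filtered `annotation_set`.
#' @export
filter_small_masks <- function(ann, min_area = 12000L) {
  keep <- vapply(ann$tubules, function(t) pm_area(t$mask) >= min_area, TRUE)
  ann$tubules <- ann$tubules[keep]
  ann
}
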