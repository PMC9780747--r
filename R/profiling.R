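# Immunofluorescence positivity: overlay a co-registered marker channel on
# the cell predictions and profile expression per cell class and stage.

#' Positivity rule for a fluorescent marker
#'
#' Luminosity thresholds are fixed per marker (empirically, by the user on
#' raw channel intensities); a cell is positive when its region mean
#' exceeds the threshold AND at least `half_fraction_min` of its region
#' pixels exceed half the threshold.
#'
#' @param threshold Intensity threshold T (> 0, raw channel units).
#' @param half_fraction_min Minimum fraction of region pixels above T/2,
#'   default 0.65.
#' @return A list of class `positivity_rule`.
#' @export
positivity_rule <- function(threshold, half_fraction_min = 0.65) {
  stopifnot(threshold > 0, half_fraction_min > 0, half_fraction_min <= 1)
  structure(list(threshold = threshold,
                 half_fraction_min = half_fraction_min),
            class = "positivity_rule")
}

#' Is a cell positive for a marker?
#'
#' The cell region is the oval (inscribed ellipse) of its box. "Above the
#' threshold" is read as strict `>`; the pixel fraction is compared with
#' `>=`.
#'
#' @param box Cell box `(x0, y0, x1, y1)`.
#' @param channel Marker channel matrix, co-registered with the analysis
#'   image.
#' @param rule A [positivity_rule()].
#' @return Logical.
#' @export
antigen_positive <- function(box, channel, rule) {
  region <- inscribed_ellipse_mask(box)
  bb <- pm_bbox(region)
  if (bb[1] < 0 || bb[2] < 0 || bb[3] > ncol(channel) || bb[4] > nrow(channel))
    stop("cell region lies outside the marker channel")
  win <- channel[(region$y0 + 1):(region$y0 + nrow(region$m)),
                 (region$x0 + 1):(region$x0 + ncol(region$m)), drop = FALSE]
  vals <- win[region$m]
  mean(vals) > rule$threshold &&
    mean(vals > rule$threshold / 2) >= rule$half_fraction_min
}

#' Cell-class by stage expression profile
#'
#' For each (cell class, stage) pair, the number of marker-positive cells
#' and the total cell count among cells assigned to a staged tubule.
#' Fractions for unpopulated pairs are `NA` (flagged undefined), never
#' silently 0.
#'
#' @param cells A [cell_detections()] table (pipeline output).
#' @param tubules Staged tubules.
#' @param assignment Tubule assignment from [assign_cells_to_tubules()].
#' @param channel Marker channel matrix.
#' @param rule A [positivity_rule()].
#' @return An `expression_profile`: list of 9 x 5 matrices `fraction`,
#'   `positive`, `total`.
#' @export
expression_profile <- function(cells, tubules, assignment, channel, rule) {
  classes <- cell_classes(); stages <- stage_classes()
  pos <- tot <- matrix(0L, length(classes), length(stages),
                       dimnames = list(classes, stages))
  stage_of <- setNames(vapply(tubules, function(t) t$stage, ""),
                       vapply(tubules, function(t) t$id, 0L))
  for (i in seq_len(nrow(cells))) {
    if (is.na(assignment[i])) next
    st <- stage_of[[as.character(assignment[i])]]
    cl <- cells$class[i]
    if (!cl %in% classes) next
    tot[cl, st] <- tot[cl, st] + 1L
    if (antigen_positive(c(cells$x0[i], cells$y0[i], cells$x1[i],
                           cells$y1[i]), channel, rule))
      pos[cl, st] <- pos[cl, st] + 1L
  }
  frac <- ifelse(tot > 0, pos / tot, NA_real_)
  structure(list(fraction = frac, positive = pos, total = tot),
            class = "expression_profile")
}

#' Per-class mean-intensity report to assist threshold selection
#'
#' No automatic thresholding is claimed; this helper reports, per predicted
#' cell class, summary statistics of region mean intensity on the marker
#' channel so the user can fix T per marker.
#'
#' @param cells A [cell_detections()] table.
#' @param channel Marker channel matrix.
#' @return Data frame: class, n, mean/median/quartiles of region means.
#' @export
marker_intensity_report <- function(cells, channel) {
  means <- vapply(seq_len(nrow(cells)), function(i) {
    region <- inscribed_ellipse_mask(c(cells$x0[i], cells$y0[i],
                                       cells$x1[i], cells$y1[i]))
    win <- channel[(region$y0 + 1):(region$y0 + nrow(region$m)),
                   (region$x0 + 1):(region$x0 + ncol(region$m)), drop = FALSE]
    mean(win[region$m])
  }, 0)
  res <- lapply(split(means, cells$class), function(v)
    c(n = length(v), mean = mean(v), q25 = unname(stats::quantile(v, 0.25)),
      median = stats::median(v), q75 = unname(stats::quantile(v, 0.75))))
  df <- as.data.frame(do.call(rbind, res))
  df$class <- rownames(df)
  rownames(df) <- NULL
  df[, c("class", "n", "mean", "q25", "median", "q75")]
}

#' Plot an expression profile as grouped bars
#'
#' Bar height is the fraction of positive cells per class, grouped by cell
#' class and colored by stage.
#'
#' @param profile An [expression_profile()].
#' @param file Optional PNG path; when `NULL`, draws on the active device.
#' @param main Plot title.
#' @return Invisibly, the fraction matrix.
#' @export
plot_expression_profile <- function(profile, file = NULL, main = "") {
  frac <- profile$fraction
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 500)
    on.exit(dev.off())
  }
  op <- par(mar = c(7, 4, 3, 8), xpd = TRUE)
  on.exit(par(op), add = TRUE)
  cols <- stage_palette()
  barplot(t(ifelse(is.na(frac), 0, frac)) * 100, beside = TRUE,
          col = cols, las = 2, ylab = "% positive", main = main,
          ylim = c(0, 100))
  legend("topright", inset = c(-0.08, 0), legend = stage_classes(),
         fill = cols, title = "Stage", bty = "n")
  invisible(frac)
}
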