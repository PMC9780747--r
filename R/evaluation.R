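# Detection and segmentation metrics: greedy IOU matching, per-class
# PPV/sensitivity/F1, confusion matrices, COCO-style average precision,
# the four pixel-level segmentation metrics, and staging agreement.

#' Match predicted and ground-truth detections by IOU
#'
#' Greedy matching at a fixed IOU threshold: predictions, in descending
#' confidence order, each claim the still-unclaimed truth of highest IOU at
#' least `iou_min`. By default matching is class-agnostic and class
#' agreement is scored afterwards (enabling the confusion matrix); set
#' `class_aware = TRUE` to only match within the same class.
#'
#' @param pred A [cell_detections()] table (or data frame with box columns,
#'   `class` and `top_conf`).
#' @param truth Data frame with box columns and `class`.
#' @param iou_min Matching threshold, default 0.5.
#' @param class_aware Restrict matches to equal labels.
#' @return A `match_result`: list with `pairs` (data frame `pred`, `truth`,
#'   `iou`), `fp` (unmatched prediction rows), `fn` (unmatched truth rows).
#' @export
match_detections <- function(pred, truth, iou_min = 0.5,
                             class_aware = FALSE) {
  np <- nrow(pred); nt <- nrow(truth)
  pairs <- data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  if (np && nt) {
    ious <- box_iou_matrix(det_boxes(pred),
                           as.matrix(truth[, c("x0", "y0", "x1", "y1")]))
    if (class_aware)
      ious[outer(pred$class, truth$class, `!=`)] <- 0
    claimed <- logical(nt)
    ord <- order(-pred$top_conf, seq_len(np))
    for (i in ord) {
      cand <- ious[i, ]
      cand[claimed] <- 0
      j <- which.max(cand)
      if (cand[j] >= iou_min) {
        claimed[j] <- TRUE
        pairs <- rbind(pairs, data.frame(pred = i, truth = j, iou = cand[j]))
      }
    }
  } else {
    claimed <- logical(nt)
  }
  structure(list(pairs = pairs,
                 fp = setdiff(seq_len(np), pairs$pred),
                 fn = which(!claimed),
                 pred_class = pred$class, truth_class = truth$class),
            class = "match_result")
}

#' Per-class positive predictive value, sensitivity and F1
#'
#' For class c: TP = matched pairs where both labels are c; PPV =
#' TP / predictions labeled c; sensitivity = TP / truths labeled c; F1 is
#' their harmonic mean. Ratios with zero denominator are `NA` (undefined),
#' never silently 0.
#'
#' @param match A `match_result` from [match_detections()].
#' @param classes Class universe for the report rows.
#' @return Data frame with rows per class: `ppv`, `sensitivity`, `f1`.
#' @export
detection_prf <- function(match, classes = cell_classes()) {
  out <- data.frame(class = classes, ppv = NA_real_,
                    sensitivity = NA_real_, f1 = NA_real_)
  pc <- match$pred_class; tc <- match$truth_class
  for (k in seq_along(classes)) {
    c <- classes[k]
    tp <- sum(pc[match$pairs$pred] == c & tc[match$pairs$truth] == c)
    npred <- sum(pc == c); ntruth <- sum(tc == c)
    ppv <- if (npred > 0) tp / npred else NA_real_
    sens <- if (ntruth > 0) tp / ntruth else NA_real_
    out$ppv[k] <- ppv; out$sensitivity[k] <- sens
    out$f1[k] <- f1_score(ppv, sens)
  }
  out
}

#' F1 score from positive predictive value and sensitivity
#'
#' @param ppv,sensitivity Ratios in `[0, 1]` (vectorized).
#' @return `2 * ppv * sensitivity / (ppv + sensitivity)`; `NA` when either
#'   input is `NA` or both are zero.
#' @export
#' @examples
#' f1_score(0.9934, 0.9700)  # 0.9815...
f1_score <- function(ppv, sensitivity) {
  ifelse(is.na(ppv) | is.na(sensitivity) | (ppv + sensitivity) == 0,
         NA_real_, 2 * ppv * sensitivity / (ppv + sensitivity))
}

#' Unweighted macro average over defined per-class values
#'
#' @param values Numeric vector of per-class ratios, `NA` = undefined.
#' @return Arithmetic mean over the defined values.
#' @export
macro_average <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("macro_average: all values undefined")
  mean(v)
}

#' Confusion matrix over matched detection pairs
#'
#' @param match A `match_result`.
#' @param classes Class universe ordering rows (truth) and columns
#'   (prediction).
#' @return Integer matrix of counts, rows = true class, cols = predicted.
#' @export
confusion_matrix <- function(match, classes = cell_classes()) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(truth = classes, pred = classes))
  for (i in seq_len(nrow(match$pairs))) {
    tc <- match$truth_class[match$pairs$truth[i]]
    pc <- match$pred_class[match$pairs$pred[i]]
    m[tc, pc] <- m[tc, pc] + 1L
  }
  m
}

#' COCO-style average precision
#'
#' Per class, predictions are ranked by confidence and greedily matched
#' (within the class) to unclaimed truths at IOU at least `iou_min`; the
#' precision-recall curve is interpolated at 101 recall points
#' (0, 0.01, ..., 1) taking the maximum precision at recall >= r, and AP is
#' its mean. The reported value is the average over classes that have
#' ground truth, scaled to `[0, 100]` (AP50 uses `iou_min = 0.5`, AP75
#' `0.75`).
#'
#' @param pred A [cell_detections()] table with confidences.
#' @param truth Data frame with boxes and `class`.
#' @param iou_min Matching IOU threshold.
#' @return List with `ap` (mean over classes, on the 0-100 scale) and
#'   `per_class` (named vector, 0-100).
#' @export
average_precision <- function(pred, truth, iou_min = 0.5) {
  classes <- sort(unique(truth$class))
  if (!length(classes)) stop("average_precision: no ground truth")
  per <- setNames(numeric(length(classes)), classes)
  recall_pts <- seq(0, 1, by = 0.01)
  for (c in classes) {
    tsel <- which(truth$class == c)
    psel <- which(pred$class == c)
    nt <- length(tsel)
    if (!length(psel)) { per[c] <- 0; next }
    p <- pred[psel, , drop = FALSE]
    ord <- order(-p$top_conf, seq_len(nrow(p)))
    ious <- box_iou_matrix(det_boxes(p),
                           as.matrix(truth[tsel, c("x0", "y0", "x1", "y1")]))
    claimed <- logical(nt)
    tp <- numeric(length(ord))
    for (r in seq_along(ord)) {
      i <- ord[r]
      cand <- ious[i, ]
      cand[claimed] <- 0
      j <- which.max(cand)
      if (length(cand) && cand[j] >= iou_min) {
        claimed[j] <- TRUE
        tp[r] <- 1
      }
    }
    cum_tp <- cumsum(tp)
    precision <- cum_tp / seq_along(tp)
    recall <- cum_tp / nt
    interp <- vapply(recall_pts, function(r) {
      ok <- recall >= r
      if (any(ok)) max(precision[ok]) else 0
    }, 0)
    per[c] <- mean(interp) * 100
  }
  list(ap = mean(per), per_class = per)
}

#' Pixel-level segmentation metrics
#'
#' The four standard semantic-segmentation metrics over same-shaped label
#' images. With `n_ij` the number of pixels of true class i predicted as
#' class j, and `t_i = sum_j n_ij`:
#' pixel accuracy = `sum_i n_ii / sum_i t_i`;
#' mean accuracy = `mean_i (n_ii / t_i)`;
#' mean IU = `mean_i (n_ii / (t_i + sum_j n_ji - n_ii))`;
#' frequency-weighted IU = `sum_i t_i IU_i / sum_k t_k`.
#' Means run over classes present in the truth.
#'
#' @param pred_seg,truth_seg Same-shaped matrices of class labels
#'   (integers, characters or factors; include a background label).
#' @return Named list: `pixel_accuracy`, `mean_accuracy`, `mean_iu`,
#'   `freq_weighted_iu`.
#' @export
pixel_metrics <- function(pred_seg, truth_seg) {
  if (!identical(dim(pred_seg), dim(truth_seg)))
    stop("label images must have identical shape")
  classes <- sort(unique(c(as.vector(truth_seg), as.vector(pred_seg))))
  tt <- factor(as.vector(truth_seg), levels = classes)
  pp <- factor(as.vector(pred_seg), levels = classes)
  n <- table(tt, pp)
  t_i <- rowSums(n)
  present <- t_i > 0
  n_ii <- diag(n)
  iu_den <- t_i + colSums(n) - n_ii
  iu <- ifelse(iu_den > 0, n_ii / iu_den, NA_real_)
  list(pixel_accuracy = sum(n_ii) / sum(t_i),
       mean_accuracy = mean(n_ii[present] / t_i[present]),
       mean_iu = mean(iu[present]),
       freq_weighted_iu = sum(t_i[present] * iu[present]) / sum(t_i))
}

#' Human-versus-model staging agreement
#'
#' Counts exact stage-class matches over a shared tubule id set. An
#' optional set of reconciled tubule ids (adjudicated borderline cases,
#' e.g. tubules lying on a stage V/VI boundary) is counted as agreement
#' before the percentage is computed.
#'
#' @param human,model Named (by tubule id) or plain aligned character
#'   vectors of stage classes.
#' @param reconciled Optional vector of tubule ids (or indices) whose
#'   disagreement is adjudicated as agreement.
#' @return List with `n`, `n_agree`, `percent` (rounded to 1 decimal).
#' @export
#' @examples
#' staging_agreement(rep("I-V", 4), c(rep("I-V", 3), "XII"))
staging_agreement <- function(human, model, reconciled = NULL) {
  if (length(human) != length(model))
    stop("human and model stage lists differ in length")
  if (!is.null(names(human)) && !is.null(names(model))) {
    if (!setequal(names(human), names(model)))
      stop("tubule id sets differ between human and model")
    model <- model[names(human)]
  }
  agree <- human == model
  if (!is.null(reconciled)) {
    ids <- if (!is.null(names(human))) match(as.character(reconciled),
                                             names(human)) else
                                               as.integer(reconciled)
    if (anyNA(ids)) stop("reconciled ids not present in the tubule set")
    agree[ids] <- TRUE
  }
  n <- length(agree); n_agree <- sum(agree)
  list(n = n, n_agree = n_agree,
       percent = round(100 * n_agree / n, 1))
}
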