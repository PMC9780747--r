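# Printed per-class detection statistics of the published cell model
# (PPV, sensitivity), used as inputs to the metric arithmetic.
published_prf <- data.frame(
  class = c("Sert", "Spg", "Spc-prePach", "Spc-Pach", "Spc-sec", "m2m",
            "RS", "elSpt-early", "elSpt-late"),
  ppv = c(0.9934, 0.9152, 0.9390, 0.9782, 0.9906, 0.9500, 0.9947,
          0.9243, 0.9611),
  sensitivity = c(0.9700, 0.7593, 0.8964, 0.9352, 0.8203, 0.8261,
                  0.9033, 0.7680, 0.6829))

test_that("F1 and macro averages reproduce the published arithmetic", {
  f1 <- f1_score(published_prf$ppv, published_prf$sensitivity)
  # agreement to 4 decimals (the published F1s were computed from unrounded
  # inputs, so recomputation from the printed ones can differ in the last
  # printed digit's half-ulp)
  expect_lt(abs(f1[published_prf$class == "Sert"] - 0.9815), 1e-4)
  expect_lt(abs(f1[published_prf$class == "Spg"] - 0.8300), 1e-4)
  expect_lt(abs(f1[published_prf$class == "RS"] - 0.9468), 1e-4)
  expect_lt(abs(f1[published_prf$class == "elSpt-late"] - 0.7985), 1e-4)
  expect_equal(round(macro_average(published_prf$ppv), 4), 0.9607)
  expect_equal(round(macro_average(published_prf$sensitivity), 4), 0.8402)
  expect_true(is.na(f1_score(NA, 0.5)))
  expect_error(macro_average(c(NA_real_, NA_real_)), "undefined")
})

test_that("greedy IOU matching behaves on the boundary cases", {
  truth <- data.frame(x0 = c(0, 100), y0 = c(0, 0),
                      x1 = c(20, 120), y1 = c(20, 20),
                      class = c("RS", "Sert"))
  pred <- make_cells(c(0, 0, 20, 20, 100, 0, 120, 20),
                     c("RS", "Sert"), c(0.9, 0.8))
  m <- match_detections(pred, truth)
  expect_equal(nrow(m$pairs), 2)
  expect_length(m$fp, 0)
  expect_length(m$fn, 0)

  m2 <- match_detections(pred[0, ], truth)
  expect_equal(m2$fn, c(1, 2))

  # two predictions over one truth: the more confident one wins
  pred3 <- make_cells(c(0, 0, 20, 20, 1, 1, 21, 21), c("RS", "RS"),
                      c(0.7, 0.95))
  m3 <- match_detections(pred3, data.frame(x0 = 0, y0 = 0, x1 = 20, y1 = 20,
                                           class = "RS"))
  expect_equal(m3$pairs$pred, 2)
  expect_equal(m3$fp, 1)
})

test_that("matching conserves prediction and truth counts", {
  set.seed(17)
  for (i in 1:20) {
    nt <- sample(3:10, 1); np <- sample(3:10, 1)
    tx <- runif(nt, 0, 200); ty <- runif(nt, 0, 200)
    truth <- data.frame(x0 = tx, y0 = ty, x1 = tx + 15, y1 = ty + 15,
                        class = sample(cell_classes(), nt, replace = TRUE))
    px <- runif(np, 0, 200); py <- runif(np, 0, 200)
    pred <- make_cells(as.vector(t(cbind(px, py, px + 15, py + 15))),
                       sample(cell_classes(), np, replace = TRUE),
                       runif(np, 0.5, 1))
    m <- match_detections(pred, truth)
    expect_equal(nrow(m$pairs) + length(m$fp), np)
    expect_equal(nrow(m$pairs) + length(m$fn), nt)
    # confusion-matrix trace equals the summed per-class true positives
    cm <- confusion_matrix(m)
    prf <- detection_prf(m)
    tp_from_prf <- sum(prf$ppv * vapply(cell_classes(), function(c)
      sum(pred$class == c), 0), na.rm = TRUE)
    expect_equal(sum(diag(cm)), tp_from_prf)
  }
})

test_that("perfect detections give perfect per-class statistics", {
  set.seed(8)
  n <- 30
  xs <- seq(0, by = 40, length.out = n)
  cls <- sample(cell_classes(), n, replace = TRUE)
  truth <- data.frame(x0 = xs, y0 = 0, x1 = xs + 20, y1 = 20, class = cls)
  pred <- make_cells(as.vector(t(cbind(xs, 0, xs + 20, 20))), cls,
                     runif(n, 0.6, 1))
  prf <- detection_prf(match_detections(pred, truth))
  populated <- prf$class %in% cls
  expect_true(all(prf$f1[populated] == 1))
  expect_true(all(is.na(prf$f1[!populated])))
  cm <- confusion_matrix(match_detections(pred, truth))
  expect_true(all(cm[upper.tri(cm)] == 0) && all(cm[lower.tri(cm)] == 0))
})

test_that("average precision matches the hand-enumerated PR curve", {
  # every truth found by one confident correct prediction -> 100
  truth <- data.frame(x0 = c(0, 50), y0 = 0, x1 = c(20, 70), y1 = 20,
                      class = "RS")
  perfect <- make_cells(c(0, 0, 20, 20, 50, 0, 70, 20), c("RS", "RS"),
                        c(0.9, 0.85))
  expect_equal(average_precision(perfect, truth)$ap, 100)

  # zero predictions -> 0
  expect_equal(average_precision(perfect[0, ], truth)$ap, 0)
  expect_error(average_precision(perfect, truth[0, ]), "no ground truth")

  # 3 predictions, 2 truths, ranked TP, FP, TP:
  # precision after each rank: 1, 1/2, 2/3; recall: 1/2, 1/2, 1
  # interpolated precision: 1 for r <= 0.5 (51 pts), 2/3 above (50 pts)
  pred <- make_cells(c(0, 0, 20, 20,
                       200, 200, 220, 220,
                       50, 0, 70, 20),
                     c("RS", "RS", "RS"), c(0.9, 0.8, 0.7))
  expected <- (51 * 1 + 50 * 2 / 3) / 101 * 100
  expect_equal(average_precision(pred, truth)$ap, expected, tolerance = 1e-9)
})

test_that("AP at IOU 0.5 dominates AP at IOU 0.75", {
  set.seed(23)
  for (i in 1:10) {
    n <- 15
    xs <- runif(n, 0, 400); ys <- runif(n, 0, 400)
    truth <- data.frame(x0 = xs, y0 = ys, x1 = xs + 20, y1 = ys + 20,
                        class = sample(c("RS", "Sert"), n, replace = TRUE))
    jx <- xs + sample(-6:6, n, replace = TRUE)
    jy <- ys + sample(-6:6, n, replace = TRUE)
    pred <- make_cells(as.vector(t(cbind(jx, jy, jx + 20, jy + 20))),
                       sample(c("RS", "Sert"), n, replace = TRUE),
                       runif(n, 0.5, 1))
    ap50 <- average_precision(pred, truth, 0.5)$ap
    ap75 <- average_precision(pred, truth, 0.75)$ap
    expect_gte(ap50, ap75)
  }
})

test_that("pixel metrics follow the four formulas", {
  lab <- matrix(sample(0:2, 400, replace = TRUE), 20)
  pm <- pixel_metrics(lab, lab)
  expect_equal(unlist(pm), c(pixel_accuracy = 1, mean_accuracy = 1,
                             mean_iu = 1, freq_weighted_iu = 1))

  # prediction all-background vs truth half-foreground (2 classes)
  truth <- matrix(0L, 10, 10)
  truth[, 1:5] <- 1L
  pred <- matrix(0L, 10, 10)
  pm2 <- pixel_metrics(pred, truth)
  expect_equal(pm2$pixel_accuracy, 0.5)
  expect_equal(pm2$mean_accuracy, 0.5)
  expect_equal(pm2$mean_iu, 0.25)        # IU: 0.5 (bg), 0 (fg)
  expect_equal(pm2$freq_weighted_iu, 0.25)

  expect_error(pixel_metrics(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("pixel metrics are invariant under class relabeling", {
  set.seed(31)
  for (i in 1:10) {
    truth <- matrix(sample(0:3, 900, replace = TRUE), 30)
    pred <- truth
    flip <- sample(900, 200)
    pred[flip] <- sample(0:3, 200, replace = TRUE)
    base <- pixel_metrics(pred, truth)
    perm <- sample(0:3)
    names(perm) <- as.character(0:3)
    pm <- pixel_metrics(matrix(perm[as.character(pred)], 30),
                        matrix(perm[as.character(truth)], 30))
    expect_equal(pm, base, tolerance = 1e-12)
  }
})

test_that("staging agreement reproduces the published contingency", {
  expect_equal(staging_agreement(rep("IX", 10), rep("IX", 10))$percent, 100)

  human <- c(rep("I-V", 60), rep("VI-VIII", 30), rep("IX", 10),
             rep("X-XI", 6), rep("XII", 6))
  model <- human
  model[1:4] <- "VI-VIII"  # four I-V/VI-VIII borderline disagreements
  model[61] <- "I-V"       # one genuine conflict
  ag <- staging_agreement(human, model)
  expect_equal(ag$n, 112)
  expect_equal(ag$n_agree, 107)
  # 107/112 = 95.536%; the complementary count (5/112 = 4.5%) confirms the
  # arithmetic, so the rounded report is 95.5
  expect_equal(ag$percent, 95.5)

  # adjudicating the four borderline tubules yields the reconciled figure
  ag2 <- staging_agreement(human, model, reconciled = 1:4)
  expect_equal(ag2$n_agree, 111)
  expect_equal(ag2$percent, 99.1)

  expect_error(staging_agreement(setNames(rep("IX", 2), c("a", "b")),
                                 setNames(rep("IX", 2), c("a", "c"))),
               "id sets")
})
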