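test_that("rotation-ensemble merge keeps the best box and is strict at 0.5", {
  one <- make_cells(c(5, 5, 20, 20), "RS", 0.9)
  empty <- one[0, ]
  m <- merge_rotation_ensemble(list(one, empty, empty, empty))
  expect_equal(nrow(m), 1)
  expect_equal(m$top_conf, 0.9)

  # identical box from two rotations: single detection at the higher conf
  a <- make_cells(c(5, 5, 20, 20), "RS", 0.9)
  b <- make_cells(c(5, 5, 20, 20), "RS", 0.8)
  m2 <- merge_rotation_ensemble(list(a, b))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$top_conf, 0.9)

  # IOU 0.45 < 0.5: both kept
  p <- make_cells(c(0, 0, 10, 20), "RS", 0.9)
  q <- make_cells(c(0, 7, 10, 27), "RS", 0.8)  # IOU = 130/270 = 0.481
  expect_lt(box_iou(c(0, 0, 10, 20), c(0, 7, 10, 27)), 0.5)
  expect_equal(nrow(merge_rotation_ensemble(list(p, q))), 2)

  # IOU exactly 0.5 is kept: suppression requires strictly > 0.5
  r <- make_cells(c(0, 0, 10, 3), "RS", 0.9)
  s <- make_cells(c(0, 1, 10, 4), "RS", 0.8)
  expect_equal(box_iou(c(0, 0, 10, 3), c(0, 1, 10, 4)), 0.5)
  expect_equal(nrow(merge_rotation_ensemble(list(r, s))), 2)

  # just above 0.5 is suppressed
  u <- make_cells(c(0, 0, 10, 10), "RS", 0.9)
  v <- make_cells(c(0, 2, 10, 12), "RS", 0.8)  # IOU = 80/120 = 0.667
  expect_equal(nrow(merge_rotation_ensemble(list(u, v))), 1)
})

test_that("cross-tile merge votes by summed confidence with second best", {
  single <- make_cells(c(0, 0, 10, 10), "RS", 0.9)
  m <- merge_cross_tile(single)
  expect_equal(nrow(m), 1)
  expect_true(is.na(m$second_class))

  # (RS, 0.9) + (Spc-Pach, 0.6) -> RS with second Spc-Pach
  two <- make_cells(c(0, 0, 10, 10, 0, 0, 10, 10),
                    c("RS", "Spc-Pach"), c(0.9, 0.6))
  m2 <- merge_cross_tile(two)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$class, "RS")
  expect_equal(m2$second_class, "Spc-Pach")
  expect_equal(m2$n_merged, 2L)

  # (RS, 0.5) + (Spc-Pach, 0.4) + (Spc-Pach, 0.3) -> Spc-Pach, second RS
  three <- make_cells(rep(c(0, 0, 10, 10), 3),
                      c("RS", "Spc-Pach", "Spc-Pach"), c(0.5, 0.4, 0.3))
  m3 <- merge_cross_tile(three)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$class, "Spc-Pach")
  expect_equal(m3$second_class, "RS")
})

test_that("cross-tile merge is idempotent", {
  set.seed(99)
  n <- 60
  xs <- runif(n, 0, 800); ys <- runif(n, 0, 800)
  boxes <- as.vector(t(cbind(xs, ys, xs + runif(n, 8, 20),
                             ys + runif(n, 8, 20))))
  cells <- make_cells(boxes, sample(cell_classes(), n, replace = TRUE),
                      runif(n, 0.5, 1))
  m1 <- merge_cross_tile(cells)
  m2 <- merge_cross_tile(m1)
  expect_equal(nrow(m1), nrow(m2))
  expect_equal(m1$class, m2$class)
  expect_equal(det_boxes(m1), det_boxes(m2))
})

test_that("fragments group into tubules by chained overlaps", {
  u <- rep(0.3, 5)
  names(u) <- stage_classes()
  fA <- tubule_fragment(box_mask(c(0, 0, 100, 100)), u)
  fB <- tubule_fragment(box_mask(c(80, 0, 180, 100)), u)
  fC <- tubule_fragment(box_mask(c(160, 0, 260, 100)), u)
  # A-B and B-C overlap by 20%, A-C are disjoint: one tubule of 3
  t1 <- group_fragments_to_tubules(list(fA, fB, fC))
  expect_length(t1, 1)
  expect_length(t1[[1]]$fragments, 3)
  expect_equal(t1[[1]]$area_px, 260 * 100)

  fD <- tubule_fragment(box_mask(c(500, 500, 600, 600)), u)
  t2 <- group_fragments_to_tubules(list(fA, fD))
  expect_length(t2, 2)

  t3 <- group_fragments_to_tubules(list(fA))
  expect_length(t3, 1)
  expect_equal(t3[[1]]$area_px, pm_area(fA$mask))
})

test_that("stage vote multiplies area-weighted confidences", {
  conf <- function(iv, vi) {
    v <- c(iv, vi, 0, 0, 0)
    names(v) <- stage_classes()
    v
  }
  fA <- tubule_fragment(box_mask(c(0, 0, 75, 1)), conf(0.8, 0.2))   # 75 px
  fB <- tubule_fragment(box_mask(c(75, 0, 100, 1)), conf(0.3, 0.7)) # 25 px
  tub <- list(fragments = list(fA, fB), area_px = 100)
  v <- vote_tubule_stage(tub)
  tub$stage <- v$stage
  tub$stage_score <- v$score
  # S(I-V) = (0.8*0.75) * (0.3*0.25) = 0.045
  # S(VI-VIII) = (0.2*0.75) * (0.7*0.25) = 0.02625
  expect_equal(tub$stage, "I-V")
  expect_equal(exp(tub$stage_score[["I-V"]]), 0.045, tolerance = 1e-9)
  expect_equal(exp(tub$stage_score[["VI-VIII"]]), 0.02625, tolerance = 1e-9)

  # single fragment spanning the union keeps its top stage
  f1 <- tubule_fragment(box_mask(c(0, 0, 10, 10)),
                        setNames(c(0.9, 0.1, 0, 0, 0), stage_classes()))
  v <- vote_tubule_stage(list(fragments = list(f1), area_px = 100))
  expect_equal(v$stage, "I-V")

  # unanimity wins regardless of fragment areas
  fu1 <- tubule_fragment(box_mask(c(0, 0, 90, 1)),
                         setNames(c(0.1, 0.1, 0.7, 0.05, 0.05),
                                  stage_classes()))
  fu2 <- tubule_fragment(box_mask(c(80, 0, 100, 1)),
                         setNames(c(0.2, 0.1, 0.6, 0.05, 0.05),
                                  stage_classes()))
  tub2 <- group_fragments_to_tubules(list(fu1, fu2))[[1]]
  expect_equal(tub2$stage, "IX")

  expect_error(vote_tubule_stage(list(fragments = list(), area_px = 0)),
               "empty")
})

test_that("log-space product vote equals the direct product", {
  set.seed(55)
  for (i in 1:40) {
    k <- sample(2:6, 1)
    frags <- lapply(seq_len(k), function(j) {
      w <- runif(5); w <- w / sum(w) * runif(1, 0.5, 1)
      names(w) <- stage_classes()
      tubule_fragment(box_mask(c(20 * j, 0, 20 * j + sample(5:20, 1), 7)), w)
    })
    area <- sum(vapply(frags, function(f) f$area_px, 0))
    v <- vote_tubule_stage(list(fragments = frags, area_px = area))
    direct <- rep(1, 5)
    for (f in frags)
      direct <- direct * pmax(f$stage_conf * f$area_px / area, 1e-6)
    expect_equal(exp(unname(v$score)), unname(direct), tolerance = 1e-9)
    expect_equal(v$stage, stage_classes()[which.max(direct)])
  }
})

test_that("cells map to the tubule containing their box centre", {
  u <- setNames(rep(0.3, 5), stage_classes())
  tubs <- group_fragments_to_tubules(list(
    tubule_fragment(box_mask(c(0, 0, 100, 100)), u),
    tubule_fragment(box_mask(c(300, 0, 400, 100)), u)))
  cells <- make_cells(c(40, 40, 60, 60,       # inside tubule 1
                        340, 40, 360, 60,     # inside tubule 2
                        800, 800, 820, 820),  # interstitial
                      c("RS", "RS", "Sert"), c(1, 1, 1))
  a <- assign_cells_to_tubules(cells, tubs)
  expect_equal(a, c(1L, 2L, NA))

  # a centre pixel shared by two tubule masks goes to the lower id
  tubs2 <- group_fragments_to_tubules(list(
    tubule_fragment(box_mask(c(0, 0, 60, 100)), u),
    tubule_fragment(box_mask(c(0, 200, 60, 300)), u)))
  overlap_tub <- tubs2
  overlap_tub[[2]]$union_mask <- box_mask(c(0, 0, 60, 100))
  cell <- make_cells(c(20, 20, 40, 40), "RS", 1)
  expect_equal(assign_cells_to_tubules(cell, overlap_tub), 1L)
})

test_that("stage-XII rules follow the two quoted corrections in order", {
  u <- setNames(rep(0.3, 5), stage_classes())
  mk_tub <- function(box, stage, id) {
    t <- group_fragments_to_tubules(list(tubule_fragment(box_mask(box), u)))[[1]]
    t$stage <- stage
    t$id <- id
    t
  }
  # Case 1: XII tubule containing one m2m is unchanged
  tub <- list(mk_tub(c(0, 0, 100, 100), "XII", 1L))
  cells <- make_cells(c(40, 40, 50, 50), "m2m", 1)
  a <- assign_cells_to_tubules(cells, tub)
  r <- apply_stage12_rules(tub, cells, a)
  expect_equal(r$tubules[[1]]$stage, "XII")
  expect_equal(nrow(r$cells), 1)

  # Case 2: XII tubule without m2m/Spc-sec is restaged I-V
  cells2 <- make_cells(c(40, 40, 50, 50), "RS", 1)
  r2 <- apply_stage12_rules(tub, cells2, assign_cells_to_tubules(cells2, tub))
  expect_equal(r2$tubules[[1]]$stage, "I-V")

  # Case 3a: Spc-sec in a non-XII tubule with second class RS -> relabeled
  tub3 <- list(mk_tub(c(0, 0, 100, 100), "I-V", 1L))
  boxes <- matrix(c(40, 40, 50, 50), 1)
  conf <- matrix(0, 1, 9, dimnames = list(NULL, cell_classes()))
  conf[1, "Spc-sec"] <- 0.6; conf[1, "RS"] <- 0.3
  cells3 <- cell_detections(boxes, conf, second_class = "RS")
  r3 <- apply_stage12_rules(tub3, cells3,
                            assign_cells_to_tubules(cells3, tub3))
  expect_equal(r3$cells$class, "RS")
  expect_equal(nrow(r3$cells), 1)

  # Case 3b: same cell with no second class -> deleted
  cells4 <- make_cells(c(40, 40, 50, 50), "Spc-sec", 0.9)
  expect_true(is.na(cells4$second_class))
  r4 <- apply_stage12_rules(tub3, cells4,
                            assign_cells_to_tubules(cells4, tub3))
  expect_equal(nrow(r4$cells), 0)

  # global postcondition on a mixed fixture
  tub5 <- list(mk_tub(c(0, 0, 100, 100), "XII", 1L),
               mk_tub(c(300, 0, 400, 100), "I-V", 2L))
  cells5 <- make_cells(c(40, 40, 50, 50,
                         340, 40, 350, 50,
                         360, 60, 370, 70),
                       c("m2m", "Spc-sec", "RS"), c(1, 0.9, 1))
  r5 <- apply_stage12_rules(tub5, cells5,
                            assign_cells_to_tubules(cells5, tub5))
  st <- setNames(vapply(r5$tubules, function(t) t$stage, ""),
                 vapply(r5$tubules, function(t) t$id, 0L))
  bad <- r5$cells$class %in% c("m2m", "Spc-sec") &
    st[as.character(r5$assignment)] != "XII"
  expect_false(any(bad, na.rm = TRUE))
  for (t in r5$tubules) {
    if (t$stage != "XII") next
    member <- which(r5$assignment == t$id)
    expect_true(any(r5$cells$class[member] %in% c("m2m", "Spc-sec")))
  }
})
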