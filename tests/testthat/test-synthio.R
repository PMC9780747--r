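test_that("generated tubules respect the stage composition rules", {
  for (seed in c(2, 9)) {
    g <- cached_slide(seed)
    comp <- truth_composition(g$truth)
    stages <- vapply(g$truth$tubules, function(t) t$stage, "")
    for (t in g$truth$tubules) {
      classes <- g$truth$cells$class[g$truth$cells$tubule_id == t$id]
      if (t$stage == "XII")
        expect_true(any(classes %in% c("m2m", "Spc-sec")))
      if (t$stage %in% c("IX", "X-XI"))
        expect_equal(sum(classes == "RS"), 0)
    }
    # aggregate zero pattern of the output crosstab
    expect_equal(comp["elSpt-early", "I-V"], 0)
    expect_equal(comp["elSpt-early", "VI-VIII"], 0)
    expect_equal(comp["RS", "X-XI"], 0)
    expect_equal(sum(comp[c("m2m", "Spc-sec"),
                          setdiff(stage_classes(), "XII")]), 0)
    # Sertoli cells populate every stage that occurs on the slide
    expect_true(all(comp["Sert", unique(stages)] > 0))
  }
})

test_that("the generator is bit-identical under a repeated seed", {
  a <- generate_slide(n_tubules = 4, seed = 123, dim = 2048)
  b <- generate_slide(n_tubules = 4, seed = 123, dim = 2048)
  expect_identical(a$slide$pixels, b$slide$pixels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$markers, b$markers)
})

test_that("knockout modes alter composition or rendering as labeled", {
  miwi <- generate_ko_slide("miwi", n_tubules = 6, seed = 4, dim = 2048,
                            markers = NULL)
  expect_equal(sum(miwi$truth$cells$class %in%
                     c("elSpt-early", "elSpt-late")), 0)
  # stages persist despite the arrest
  expect_gt(length(unique(vapply(miwi$truth$tubules,
                                 function(t) t$stage, ""))), 1)

  spef2 <- generate_ko_slide("spef2", n_tubules = 6, seed = 4, dim = 2048,
                             markers = NULL)
  wt <- cached_slide(4, n_tubules = 6)
  # only rendering differs: the label vocabulary matches wild type
  expect_setequal(unique(spef2$truth$cells$class),
                  unique(wt$truth$cells$class))
  expect_gt(sum(spef2$truth$cells$class == "elSpt-late"), 0)
})

test_that("small-mask filtering is strict at the 12000-pixel floor", {
  u <- setNames(rep(0.3, 5), stage_classes())
  just_under <- pixmask(0, 0, matrix(c(rep(TRUE, 11999), FALSE), 120, 100))
  at_floor <- pixmask(0, 0, matrix(TRUE, 120, 100))
  expect_equal(pm_area(just_under), 11999)
  expect_equal(pm_area(at_floor), 12000)
  ann <- make_truth(data.frame(), tubules = list(
    list(id = 1L, mask = just_under, stage = "IX"),
    list(id = 2L, mask = at_floor, stage = "IX")))
  kept <- filter_small_masks(ann)
  expect_length(kept$tubules, 1)
  expect_equal(kept$tubules[[1]]$id, 2L)
  expect_equal(formals(filter_small_masks)$min_area, 12000L)
  empty <- filter_small_masks(make_truth(data.frame(), list()))
  expect_length(empty$tubules, 0)
})

test_that("augmentation scales counts exactly and transforms labels", {
  set.seed(6)
  mk_sample <- function() {
    img <- matrix(runif(64 * 64, 0, 255), 64)
    cells <- data.frame(x0 = c(4, 40), y0 = c(10, 20), x1 = c(14, 52),
                        y1 = c(22, 30), class = c("RS", "Sert"))
    u <- setNames(rep(0.3, 5), stage_classes())
    list(image = img, cells = cells,
         tubules = list(list(mask = box_mask(c(8, 8, 40, 40)),
                             stage = "IX")))
  }
  samples <- list(mk_sample(), mk_sample(), mk_sample())
  aug <- augment_dataset(samples, augment_variants_cells())
  expect_length(aug, 3 * 12)
  # geometric transforms conserve per-image label counts
  expect_true(all(vapply(aug, function(s) nrow(s$cells), 0) == 2))
  expect_true(all(vapply(aug, function(s) length(s$tubules), 0) == 1))
  # a horizontal flip twice is the identity on labels and pixels
  s <- samples[[1]]
  ff <- augment_dataset(list(s), list(list("flip-h"), list("flip-h")))
  back <- augment_dataset(list(ff[[1]]), list(list("flip-h")))[[1]]
  expect_equal(back$image, s$image)
  expect_equal(back$cells[, 1:4], s$cells[, 1:4])
  # mask area is conserved under every geometric op
  areas <- vapply(aug, function(s) pm_area(s$tubules[[1]]$mask), 0)
  expect_true(all(areas == 32 * 32))

  expect_error(augment_dataset(list(s), list(list("shear"))), "unknown")
})

test_that("the shipped presets reproduce the published dataset bookkeeping", {
  expect_length(augment_variants_cells(), 12)
  expect_length(augment_variants_tubules(), 9)
  bk <- augmentation_bookkeeping(424, 52807, augment_variants_cells())
  expect_equal(unname(bk["images"]), 5088)
  expect_equal(unname(bk["labels"]), 633684)
  bk2 <- augmentation_bookkeeping(3097, 0, augment_variants_tubules())
  expect_equal(unname(bk2["images"]), 27873)
})

test_that("COCO annotation round trip is lossless", {
  g <- cached_slide(2)
  f <- tempfile(fileext = ".json")
  write_coco_annotations(g$truth, f)
  back <- read_coco_annotations(f)
  expect_equal(back$dim, g$truth$dim)
  expect_equal(nrow(back$cells), nrow(g$truth$cells))
  expect_equal(back$cells$class, g$truth$cells$class)
  expect_equal(as.matrix(back$cells[, c("x0", "y0", "x1", "y1")]),
               as.matrix(g$truth$cells[, c("x0", "y0", "x1", "y1")]))
  expect_length(back$tubules, length(g$truth$tubules))
  for (i in seq_along(back$tubules)) {
    expect_equal(back$tubules[[i]]$stage, g$truth$tubules[[i]]$stage)
    expect_equal(mask_iou(back$tubules[[i]]$mask,
                          g$truth$tubules[[i]]$mask), 1)
  }
  unlink(f)

  # empty annotation set survives the round trip
  f2 <- tempfile(fileext = ".json")
  write_coco_annotations(make_truth(
    data.frame(id = integer(0), x0 = numeric(0), y0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0), class = character(0),
               tubule_id = integer(0))), f2)
  e <- read_coco_annotations(f2)
  expect_equal(nrow(e$cells), 0)
  expect_length(e$tubules, 0)
  unlink(f2)
})

test_that("VIA import maps regions and rejects unknown attributes", {
  via <- list(
    "img1.png-1" = list(
      filename = "img1.png", size = 1,
      regions = list(
        list(shape_attributes = list(name = "rect", x = 10, y = 20,
                                     width = 30, height = 15),
             region_attributes = list(class = "RS")),
        list(shape_attributes = list(name = "polygon",
                                     all_points_x = c(50, 90, 90, 50),
                                     all_points_y = c(50, 50, 90, 90)),
             region_attributes = list(stage = "IX")))))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(via, f, auto_unbox = TRUE)
  ann <- read_via_annotations(f)
  expect_equal(nrow(ann$cells), 1)
  expect_equal(ann$cells$class, "RS")
  expect_equal(unlist(ann$cells[1, c("x0", "y0", "x1", "y1")],
                      use.names = FALSE), c(10, 20, 40, 35))
  expect_length(ann$tubules, 1)
  expect_equal(ann$tubules[[1]]$stage, "IX")
  # the 40x40 square polygon rasterizes to its pixel area
  expect_equal(pm_area(ann$tubules[[1]]$mask), 40 * 40)
  unlink(f)

  bad <- via
  bad[["img1.png-1"]]$regions[[1]]$region_attributes$class <- "Spermatocyte"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE)
  expect_error(read_via_annotations(f2), "record 1")
  unlink(f2)
})

test_that("slide image files round trip through PNG and TIFF", {
  px <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64)
  s <- slide_image(px)
  for (ext in c(".png", ".tif")) {
    f <- tempfile(fileext = ext)
    write_slide_image(s, f)
    back <- read_slide_image(f)
    expect_equal(back$pixels, px, tolerance = 1 / 255)
    unlink(f)
  }
})
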