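test_that("the ripeness rule maps red fractions to classes at the 40% threshold", {
  expect_equal(ripeness_from_red_fraction(c(0.5, 0.3, 0, 0.41, 0.40)),
               c(0L, 1L, 2L, 0L, 1L))
})

test_that("scenes render one annotation per placed fruit with pixel-true classes", {
  p <- scene_params(n_fruits = 5, occlusion_level = "none", seed = 11)
  sc <- generate_scene(p)
  nd <- attr(sc$truth_meta, "n_dropped")
  expect_equal(nrow(sc$annotations), 5 - nd)
  expect_equal(nrow(sc$truth_meta), nrow(sc$annotations))
  expect_equal(dim(sc$image), c(160, 160, 3))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  # the rendered red cap reproduces the sampled fraction and hence the class
  m <- sc$truth_meta
  expect_true(all(abs(m$red_fraction - m$red_fraction_target) < 0.06))
  expect_equal(m$class_id, ripeness_from_red_fraction(m$red_fraction_target))
  # class is consistent with the pixel-counted fraction away from the
  # threshold boundary
  clear <- abs(m$red_fraction_target - 0.40) > 0.06 &
    (m$red_fraction_target == 0 | m$red_fraction_target > 0.03)
  expect_equal(m$class_id[clear],
               ripeness_from_red_fraction(m$red_fraction[clear]))
  # boxes cover the fruit masks
  for (i in seq_len(nrow(m))) {
    px <- which(sc$fruit_mask == i, arr.ind = TRUE)
    expect_gte(min(px[, 2]) - 1, floor(sc$annotations$x1[i]) - 1)
    expect_lte(max(px[, 2]), ceiling(sc$annotations$x2[i]) + 1)
  }
})

test_that("occlusion metadata matches a pixel recount and scenes are deterministic", {
  p <- scene_params(n_fruits = 4, occlusion_level = "heavy", seed = 12)
  sc <- generate_scene(p)
  m <- sc$truth_meta
  for (i in seq_len(nrow(m))) {
    recount <- sum(sc$leaf_mask & sc$fruit_mask == i) /
      max(sum(sc$fruit_mask == i), 1)
    expect_lt(abs(recount - m$occluded_fraction[i]), 0.02)
    expect_lte(m$occluded_fraction[i], 0.6 + 1e-9)
  }
  sc2 <- generate_scene(p)
  expect_identical(sc$image, sc2$image)
  expect_identical(sc$annotations, sc2$annotations)
  # blur and jitter keep the image valid
  pb <- scene_params(n_fruits = 3, blur_kernel_len = 5, seed = 13)
  scb <- generate_scene(pb)
  expect_true(all(is.finite(scb$image)))
  expect_false(is.na(attr(scb$truth_meta, "blur_angle")))
  # empty scene degenerates gracefully
  se <- generate_scene(scene_params(n_fruits = 0, seed = 14))
  expect_equal(nrow(se$annotations), 0)
})

test_that("generated datasets round-trip through their own files", {
  dir <- file.path(tempdir(), "synthds")
  unlink(dir, recursive = TRUE)
  p <- scene_params(n_fruits = 4, image_size = 96L,
                    fruit_radius_range = c(9, 16), seed = 20)
  gd <- generate_dataset(20, p, dir, seed = 2)
  expect_setequal(names(gd$split), c("train", "val", "test"))
  expect_equal(length(gd$split$train), 14)  # 7:2:1 floors, remainder to train
  expect_equal(length(gd$split$val), 4)
  expect_equal(length(gd$split$test), 2)
  # XML re-parse reproduces the written annotations (integer rounding)
  id <- gd$split$train[1]
  ann <- parse_voc_xml(paste(readLines(file.path(dir, "voc",
                                                 paste0(id, ".xml"))),
                             collapse = "\n"))
  yl <- read_yolo_labels(file.path(dir, "labels", paste0(id, ".txt")))
  expect_equal(nrow(ann), nrow(yl))
  if (nrow(ann)) {
    back <- voc_to_yolo(ann, 96, 96)
    expect_equal(back$cx, yl$cx, tolerance = 0.02)
    expect_equal(back$w, yl$w, tolerance = 0.03)
  }
  # determinism of the files
  dir2 <- file.path(tempdir(), "synthds2")
  unlink(dir2, recursive = TRUE)
  generate_dataset(20, p, dir2, seed = 2)
  f1 <- file.path(dir, "images", paste0(id, ".png"))
  f2 <- file.path(dir2, "images", paste0(id, ".png"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # loads back into memory with consistent boxes
  tr <- load_split(dir, "train")
  expect_equal(length(tr), 14)
  expect_equal(dim(tr[[1]]$image), c(96, 96, 3))
})

test_that("class balance tracks the sampler and oracle detections score a perfect mAP", {
  p <- scene_params(n_fruits = 5, image_size = 96L,
                    fruit_radius_range = c(9, 16), seed = 30)
  metas <- lapply(1:40, function(i) {
    pi <- p; pi$seed <- p$seed + i
    generate_scene(pi)$truth_meta
  })
  cls <- unlist(lapply(metas, `[[`, "class_id"))
  frac <- tabulate(cls + 1L, 3) / length(cls)
  expect_true(all(abs(frac - c(0.39, 0.26, 0.35)) < 0.10))
  # ground truth replayed as detections: mAP@0.5 = 1
  scenes <- lapply(1:8, function(i) {
    pi <- p; pi$seed <- 500 + i
    generate_scene(pi)
  })
  names(scenes) <- sprintf("s%d", 1:8)
  gts <- lapply(scenes, `[[`, "annotations")
  dets <- lapply(gts, function(a)
    cbind(a[, "class_id", drop = FALSE], confidence = 0.99,
          a[, c("x1", "y1", "x2", "y2")]))
  ev <- evaluate_map50(dets, gts, classes = 0:2)
  expect_equal(ev$map50, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})
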