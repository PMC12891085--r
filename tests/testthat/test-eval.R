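mkdet <- function(conf, boxes, class_id = 0L) {
  data.frame(class_id = rep(class_id, length.out = nrow(boxes)),
             confidence = conf, x1 = boxes[, 1], y1 = boxes[, 2],
             x2 = boxes[, 3], y2 = boxes[, 4])
}
mkgt <- function(boxes, class_id = 0L) {
  data.frame(class_id = rep(class_id, length.out = nrow(boxes)),
             x1 = boxes[, 1], y1 = boxes[, 2],
             x2 = boxes[, 3], y2 = boxes[, 4])
}

test_that("greedy matching takes the best unmatched ground truth once", {
  gt <- mkgt(matrix(c(0, 0, 10, 10), 1))
  # two detections overlapping the single gt: the more confident wins
  dets <- mkdet(c(0.9, 0.8), rbind(c(0, 0, 10, 6.1), c(0, 0, 10, 5.6)))
  fl <- match_detections(dets, gt, 0.5)
  expect_equal(as.logical(fl), c(TRUE, FALSE))
  expect_equal(as.logical(match_detections(dets, gt[0, ], 0.5)),
               c(FALSE, FALSE))
  expect_length(match_detections(dets[0, ], gt, 0.5), 0)
})

test_that("all-point AP reproduces hand-enumerated PR areas", {
  # flags (TP, FP, TP) with 2 gts: recall steps 0.5, 1; envelope 1 then 2/3
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2), 5 / 6)
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1)
  expect_equal(average_precision(c(FALSE, FALSE, FALSE), 3), 0)
  expect_equal(average_precision(logical(0), 2), 0)
  expect_error(average_precision(c(TRUE), 0), "zero ground truths")
  set.seed(60)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    fl <- runif(n) > 0.5
    ngt <- sum(fl) + sample(0:3, 1)
    if (ngt == 0) next
    expect_equal(average_precision(fl, ngt), oracle_ap(fl, ngt))
  }
})

test_that("AP is invariant to monotone confidence rescaling and duplicates never help", {
  set.seed(61)
  gts <- mkgt(rbind(c(0, 0, 8, 8), c(12, 12, 20, 20)))
  dets <- mkdet(c(0.9, 0.6, 0.3),
                rbind(c(0, 0, 8, 7), c(12, 12, 20, 19), c(3, 3, 9, 9)))
  ev1 <- evaluate_map50(list(a = dets), list(a = gts), classes = 0L)
  dets2 <- dets
  dets2$confidence <- plogis(5 * dets$confidence - 2)  # strictly monotone
  ev2 <- evaluate_map50(list(a = dets2), list(a = gts), classes = 0L)
  expect_equal(ev1$map50, ev2$map50)
  # duplicating an already matched detection at lower confidence
  dup <- rbind(dets, transform(dets[1, ], confidence = 0.05))
  ev3 <- evaluate_map50(list(a = dup), list(a = gts), classes = 0L)
  expect_lte(ev3$map50, ev1$map50)
})

test_that("mAP@0.5 pools per class and averages over classes present", {
  gts <- rbind(mkgt(matrix(c(0, 0, 10, 10), 1), 0L),
               mkgt(matrix(c(20, 20, 30, 30), 1), 1L))
  dets <- rbind(mkdet(0.9, matrix(c(0, 0, 10, 10), 1), 0L),
                mkdet(0.8, matrix(c(20, 20, 30, 30), 1), 1L))
  ev <- evaluate_map50(list(a = dets), list(a = gts), classes = 0:2)
  expect_equal(unname(ev$ap_per_class[1:2]), c(1, 1))
  expect_true(is.na(ev$ap_per_class[3]))  # class 2 absent -> excluded
  expect_equal(ev$map50, 1)
  expect_equal(ev$precision, 1); expect_equal(ev$recall, 1)
  # no detections at all
  ev0 <- evaluate_map50(list(a = trdnet:::empty_detections()),
                        list(a = gts), classes = 0:2)
  expect_equal(ev0$map50, 0)
})

test_that("pooled AP agrees with the exhaustive small-instance oracle", {
  set.seed(62)
  for (rep in 1:40) {
    scenes <- lapply(1:3, function(i) {
      ng <- sample(0:3, 1); nd <- sample(0:5, 1)
      gts <- if (ng) mkgt(t(replicate(ng, rand_box()))) else
        mkgt(matrix(numeric(0), 0, 4))
      dets <- if (nd) mkdet(runif(nd), t(replicate(nd, rand_box()))) else
        trdnet:::empty_detections()
      list(dets = dets, gts = gts)
    })
    n_gt <- sum(vapply(scenes, function(s) nrow(s$gts), numeric(1)))
    if (n_gt == 0) next
    ours <- evaluate_map50(
      setNames(lapply(scenes, `[[`, "dets"), paste0("im", 1:3)),
      setNames(lapply(scenes, `[[`, "gts"), paste0("im", 1:3)),
      classes = 0L)$map50
    expect_equal(ours, oracle_scene_ap(scenes), tolerance = 1e-12)
  }
})

test_that("NMS suppresses same-class overlaps only and detection files round-trip", {
  dets <- rbind(mkdet(c(0.9, 0.8), rbind(c(0, 0, 10, 10), c(1, 1, 10, 10)), 0L),
                mkdet(0.7, matrix(c(1, 1, 10, 10), 1), 1L))
  kept <- nms(dets, iou_thr = 0.5)
  expect_equal(nrow(kept), 2)   # overlap of different classes survives
  expect_setequal(kept$class_id, c(0L, 1L))
  f <- tempfile(fileext = ".txt")
  write_detections(dets, f)
  back <- read_detections(f)
  expect_equal(back$class_id, dets$class_id)
  expect_equal(back$x1, dets$x1, tolerance = 1e-3)
  expect_equal(nrow(read_detections({writeLines("", f); f})), 0)
})
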