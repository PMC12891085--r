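test_that("IoU matches hand geometry and the rasterization oracle", {
  expect_equal(iou(c(0, 0, 4, 4), c(0, 0, 4, 4)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 4, 4), c(2, 2, 6, 6)), 4 / 28)
  expect_error(iou(c(0, 0, 0, 4), c(0, 0, 1, 1)), "degenerate")
  set.seed(50)
  err <- vapply(1:200, function(i) {
    a <- rand_box(); b <- rand_box()
    abs(iou(a, b) - raster_iou(a, b))
  }, numeric(1))
  expect_lt(max(err), 1e-3)
})

test_that("MPDIoU reproduces the worked examples and its bounds", {
  ext <- c(10, 10)
  expect_equal(mpdiou(c(0, 0, 2, 2), c(0, 0, 2, 2), ext), 1)
  expect_equal(mpdiou(c(0, 0, 2, 2), c(4, 4, 6, 6), ext),
               -32 / 200 - 32 / 200, tolerance = 1e-12)
  expect_equal(mpdiou(c(0, 0, 4, 4), c(2, 2, 6, 6), ext),
               1 / 7 - 8 / 200 - 8 / 200, tolerance = 1e-12)
  expect_equal(mpdiou_loss(c(0, 0, 2, 2), c(4, 4, 6, 6), ext), 1.32,
               tolerance = 1e-12)
  expect_equal(mpdiou_loss(c(1, 1, 3, 3), c(1, 1, 3, 3), ext), 0)
  expect_error(mpdiou(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 10)), "positive")
  set.seed(51)
  for (i in 1:500) {
    a <- rand_box(); b <- rand_box()
    m <- mpdiou(a, b, c(16, 16))
    expect_lte(m, iou(a, b) + 1e-12)
    l <- mpdiou_loss(a, b, c(16, 16))
    expect_gte(l, 0); expect_lt(l, 3)
    # translation covariance
    sh <- runif(2, -3, 3)
    expect_equal(mpdiou(a + sh[c(1, 2, 1, 2)], b + sh[c(1, 2, 1, 2)],
                        c(16, 16)), m, tolerance = 1e-12)
  }
})

test_that("the MPDIoU loss decreases monotonically as the prediction slides onto the target", {
  gt <- c(6, 6, 10, 10)
  ts <- seq(0, 1, by = 0.02)
  losses <- vapply(ts, function(t) {
    pred <- c(0, 0, 4, 4) + t * 6  # translate towards gt along the diagonal
    mpdiou_loss(gt, pred, c(16, 16))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("analytic box-loss gradients match finite differences", {
  set.seed(52)
  fd <- function(f, pred) {
    g <- numeric(4)
    for (k in 1:4) {
      e <- 1e-6; p1 <- pred; p2 <- pred
      p1[k] <- p1[k] + e; p2[k] <- p2[k] - e
      g[k] <- (f(p1) - f(p2)) / (2 * e)
    }
    g
  }
  for (i in 1:25) {
    gt <- rand_box(); pred <- rand_box()
    gm <- trdnet:::mpdiou_grad_pred(gt, pred, c(16, 16))
    gn <- fd(function(p) mpdiou(gt, p, c(16, 16)), pred)
    expect_equal(as.vector(gm), gn, tolerance = 1e-4)
    gc <- trdnet:::ciou_grad_pred(gt, pred)
    gcn <- fd(function(p) ciou(gt, p), pred)
    expect_equal(as.vector(gc), gcn, tolerance = 1e-3)
  }
})

test_that("detection loss terms behave at the identity and scale linearly", {
  set.seed(53)
  g <- build_trdnet(nc = 3, width_mult = 0.0625, input_size = 64)
  net <- trdnet:::instantiate_network(g, seed = 5)
  x <- array(runif(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  targets <- list(data.frame(class_id = 0L, x1 = 8, y1 = 8,
                             x2 = 40, y2 = 40))
  fwd <- network_forward(net, x, train = FALSE)
  # zero weights: zero total regardless of predictions
  l0 <- detection_loss(fwd$head, targets,
                       weights = list(box = 0, cls = 0, dfl = 0),
                       extent = c(64, 64), nc = 3)
  expect_equal(l0$total, 0)
  # doubling the box weight doubles exactly the box contribution
  l1 <- detection_loss(fwd$head, targets, extent = c(64, 64), nc = 3)
  l2 <- detection_loss(fwd$head, targets,
                       weights = list(box = 15, cls = 0.5, dfl = 1.5),
                       extent = c(64, 64), nc = 3)
  expect_equal(l2$total - l1$total, 7.5 * l1$box, tolerance = 1e-9)
  expect_equal(l1$box, l2$box)
  # hand-built perfect predictions: box and dfl terms vanish
  hd <- lapply(fwd$head, function(h) array(0, dim(h)))
  # gt box (8,8)-(40,40) on stride 8: anchor (2,2) center (20,20),
  # distances l=t=12px=1.5 bins, r=b=20px=2.5 bins -- representable by
  # two-bin mass; use huge logits for an exact expectation
  BIG <- 200
  R <- g$reg_bins
  for (s in 1:4) {
    dgt <- if (s <= 2) 1.5 else 2.5
    fl <- floor(dgt)
    hd[[1]][1, (s - 1) * R + fl + 1, 3, 3] <- BIG + log(1 - (dgt - fl))
    hd[[1]][1, (s - 1) * R + fl + 2, 3, 3] <- BIG + log(dgt - fl)
  }
  hd[[1]][1, 4 * R + 1, 3, 3] <- 40  # confident correct class
  hd[[1]][1, 4 * R + 1:3, , ][hd[[1]][1, 4 * R + 1:3, , ] == 0] <- -40
  hd[[2]][1, 4 * R + 1:3, , ] <- -40
  hd[[3]][1, 4 * R + 1:3, , ] <- -40
  lp <- detection_loss(hd, targets, extent = c(64, 64), nc = 3)
  expect_lt(lp$box, 1e-6)
  expect_lt(lp$cls, 1e-6)
  # dfl cannot vanish for fractional bin targets: its floor is the two-hot
  # entropy of the 0.5/1.5-bin splits
  expect_equal(lp$dfl, -log(0.5), tolerance = 1e-3)
  # no ground truths: box and dfl are zero, cls covers the negatives
  le <- detection_loss(fwd$head, list(trdnet:::empty_annotations()),
                       extent = c(64, 64), nc = 3)
  expect_equal(le$box, 0)
  expect_equal(le$dfl, 0)
  expect_gt(le$cls, 0)
})
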