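# Gradient correctness of the hand-written backward passes, and the
# training loop contracts.

fd_param_check <- function(net, x, prim, nm, n_try = 2, eps = 1e-5,
                           tol = 1e-4) {
  fwd <- network_forward(net, x, train = TRUE)
  seed_w <- lapply(fwd$head, function(h) {
    set.seed(prod(dim(h)) %% 1000L + 7L)
    array(rnorm(length(h)), dim(h))
  })
  lossv <- function(head) sum(mapply(function(h, w) sum(h * w), head,
                                     seed_w))
  trdnet:::zero_grads(net)
  trdnet:::network_backward(net, seed_w)
  ok <- TRUE
  for (i in sample(length(prim$par[[nm]]), n_try)) {
    orig <- prim$par[[nm]][i]
    prim$par[[nm]][i] <- orig + eps
    L1 <- lossv(network_forward(net, x, train = TRUE)$head)
    prim$par[[nm]][i] <- orig - eps
    L2 <- lossv(network_forward(net, x, train = TRUE)$head)
    prim$par[[nm]][i] <- orig
    num <- (L1 - L2) / (2 * eps)
    ana <- prim$grad[[nm]][i]
    rel <- abs(num - ana) / max(abs(num), abs(ana), 1e-6)
    ok <- ok && rel < tol
  }
  ok
}

test_that("backpropagated parameter gradients match finite differences", {
  set.seed(80)
  g <- build_yolov8s(nc = 3, width_mult = 0.0625, input_size = 64)
  net <- trdnet:::instantiate_network(g, seed = 81)
  x <- array(runif(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  kinds <- vapply(net$prims, `[[`, "", "kind")
  cb <- which(kinds == "conv_bn")
  # convolution weights and batch-norm affines across the depth of the net
  expect_true(fd_param_check(net, x, net$prims[[cb[2]]], "w"))
  expect_true(fd_param_check(net, x, net$prims[[cb[length(cb) %/% 2]]],
                             "gamma"))
  expect_true(fd_param_check(net, x, net$prims[[cb[length(cb)]]], "beta"))
  raw <- which(kinds == "conv_raw")
  expect_true(fd_param_check(net, x, net$prims[[raw[1]]], "w"))
  expect_true(fd_param_check(net, x, net$prims[[raw[length(raw)]]], "b"))
})

test_that("SCRConv and SimAM modules backpropagate exact gradients", {
  set.seed(82)
  # isolated SCRConv module (gate masks fixed during the check)
  m <- trdnet:::mod_scrconv(8)
  x <- array(rnorm(1 * 8 * 6 * 6), c(1, 8, 6, 6))
  y <- m$fw(list(x), train = TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  trdnet:::zero_grads(m$gwc)
  dx <- m$bw(dy)[[1]]
  w <- m$gwc$par$w
  for (i in sample(length(w), 3)) {
    eps <- 1e-6
    m$gwc$par$w[i] <- w[i] + eps
    L1 <- sum(m$fw(list(x), train = TRUE) * dy)
    m$gwc$par$w[i] <- w[i] - eps
    L2 <- sum(m$fw(list(x), train = TRUE) * dy)
    m$gwc$par$w[i] <- w[i]
    expect_equal(m$gwc$grad$w[i], (L1 - L2) / (2 * eps), tolerance = 1e-4)
  }
  # SimAM input gradient (fully differentiable closed form)
  sm <- trdnet:::mod_simam(1e-4)
  xs <- array(rnorm(1 * 2 * 4 * 4), c(1, 2, 4, 4))
  ys <- sm$fw(list(xs), train = TRUE)
  dys <- array(rnorm(length(ys)), dim(ys))
  dxs <- sm$bw(dys)[[1]]
  for (i in sample(length(xs), 4)) {
    eps <- 1e-6
    x1 <- xs; x1[i] <- x1[i] + eps
    x2 <- xs; x2[i] <- x2[i] - eps
    num <- (sum(sm$fw(list(x1)) * dys) - sum(sm$fw(list(x2)) * dys)) /
      (2 * eps)
    expect_equal(dxs[i], num, tolerance = 1e-5)
  }
})

test_that("a few optimizer steps reduce the detection loss on a fixed batch", {
  set.seed(83)
  sc <- generate_scene(scene_params(n_fruits = 3, image_size = 96L,
                                    fruit_radius_range = c(9, 16),
                                    seed = 84))
  data <- list(list(image = sc$image, annotations = sc$annotations))
  g <- build_trdnet(nc = 3, width_mult = 0.0625, input_size = 96)
  fit <- trdnet_fit(g, data, epochs = 6, batch_size = 1, lr = 2e-3,
                    seed = 85)
  expect_lt(tail(fit$history$total, 1), fit$history$total[1])
  expect_true(all(is.finite(fit$history$total)))
  # deterministic restart: identical first-epoch loss
  fit2 <- trdnet_fit(g, data, epochs = 1, batch_size = 1, lr = 2e-3,
                     seed = 85)
  expect_equal(fit2$history$total[1], fit$history$total[1],
               tolerance = 1e-12)
  # prediction pipeline contract on the (undertrained) model
  dets <- predict(fit, sc$image, conf_thr = 0)
  expect_true(is.data.frame(dets))
  if (nrow(dets)) {
    expect_true(all(dets$confidence >= 0 & dets$confidence <= 1))
    expect_true(all(dets$class_id %in% 0:2))
  }
  ev <- evaluate_model(fit, data)
  expect_gte(ev$map50, 0)
  out <- capture.output(print(fit))
  expect_true(any(grepl("trdnet", out)))
})
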