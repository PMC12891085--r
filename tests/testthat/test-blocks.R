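test_that("group normalization forces per-group statistics and applies the affine", {
  # two values {1,3} in one group -> {-1, 1} as epsilon vanishes
  x <- array(c(1, 3), c(1, 1, 1, 2))
  cfg <- srcu_config(1, epsilon = 1e-12)
  expect_equal(as.vector(group_normalize(x, cfg)), c(-1, 1),
               tolerance = 1e-5)
  # constant input: zero-variance case returns beta per channel
  xc <- array(5, c(2, 4, 3, 3))
  cfg2 <- srcu_config(4, gamma = rep(2, 4), beta = c(1, 2, 3, 4))
  out <- group_normalize(xc, cfg2)
  for (ch in 1:4) expect_equal(as.vector(out[, ch, , ]), rep(ch, 2 * 9))
  # random input: recomputed group statistics are ~ (0, 1) pre-affine
  set.seed(41)
  xr <- rand_fmap(1, 8, 4, 4)
  cfg3 <- srcu_config(8, gn_groups = 4)
  g <- group_normalize(xr, cfg3)
  for (gi in 1:4) {
    sl <- g[1, (gi - 1) * 2 + 1:2, , ]
    expect_lt(abs(mean(sl)), 1e-5)
    expect_equal(mean((sl - mean(sl))^2), 1, tolerance = 1e-3)
  }
  expect_error(srcu_config(8, gn_groups = 3), "divide")
})

test_that("SRCU gate weights are complementary and respect the gamma normalization", {
  set.seed(42)
  x <- rand_fmap(2, 6, 5, 5)
  cfg <- srcu_config(6)
  g <- srcu_gate_weights(x, cfg)
  expect_equal(g$w_gamma, rep(1 / 6, 6))
  expect_true(all(g$W1 + g$W2 == 1))
  expect_true(all(g$W1 %in% c(0, 1)))
  # threshold below every sigmoid weight marks everything informative
  cfg_lo <- srcu_config(6, gate_threshold = 1e-9)
  g2 <- srcu_gate_weights(x, cfg_lo)
  expect_true(all(g2$W1 == 1) && all(g2$W2 == 0))
  expect_error(srcu_gate_weights(x, srcu_config(6, gamma = rep(0, 6))),
               "degenerate")
})

test_that("SRCU cross-reconstruction is additive and conserving", {
  set.seed(43)
  x <- rand_fmap(1, 4, 3, 3)
  zero <- x * 0
  expect_equal(srcu_reconstruct(x, zero), x)
  expect_equal(srcu_reconstruct(zero, zero), zero)
  y <- rand_fmap(1, 4, 3, 3)
  expect_equal(sum(srcu_reconstruct(x, y)), sum(x) + sum(y))
  expect_error(srcu_reconstruct(rand_fmap(1, 3, 2, 2),
                                rand_fmap(1, 3, 2, 2)), "even")
})

test_that("SRCU forward conserves activation mass and matches its composition", {
  set.seed(44)
  for (rep in 1:5) {
    x <- rand_fmap(2, 16, 8, 8)
    cfg <- srcu_config(16)
    out <- srcu_forward(x, cfg)
    expect_equal(sum(out), sum(x), tolerance = 1e-12)
    g <- srcu_gate_weights(x, cfg)
    expect_equal(out, srcu_reconstruct(g$W1 * x, g$W2 * x))
  }
  # identity when every position is informative
  x <- rand_fmap(1, 8, 4, 4)
  expect_equal(srcu_forward(x, srcu_config(8, gate_threshold = 1e-9)), x)
})

test_that("channel fusion weights are a pairwise softmax summing to one", {
  set.seed(45)
  y1 <- rand_fmap(2, 5, 4, 4)
  out <- channel_fuse(y1, y1)
  expect_equal(as.vector(attr(out, "beta1")), rep(0.5, 10))
  expect_equal(out, y1, ignore_attr = TRUE)
  # dominant pooled mean drives beta -> 1
  big <- y1 + 50
  out2 <- channel_fuse(big, y1)
  expect_true(all(attr(out2, "beta1") > 1 - 1e-9))
  y2 <- rand_fmap(2, 5, 4, 4)
  out3 <- channel_fuse(y1, y2)
  expect_equal(attr(out3, "beta1") + attr(out3, "beta2"),
               matrix(1, 2, 5))
})

test_that("CRCU channel bookkeeping reaches the input width", {
  cfg <- crcu_config(4, alpha = 0.5, squeeze_ratio = 2, seed = 1)
  expect_equal(cfg$up, 2L); expect_equal(cfg$up_s, 1L)
  x <- rand_fmap(1, 4, 6, 6)
  out <- crcu_forward(x, cfg)
  expect_equal(dim(out), dim(x))
  # zero weights leave a finite result (identity path of the lower branch)
  cfg0 <- crcu_config(8, init = "zero")
  out0 <- crcu_forward(rand_fmap(1, 8, 4, 4), cfg0)
  expect_true(all(is.finite(out0)))
  set.seed(46)
  x2 <- rand_fmap(2, 16, 5, 5)
  expect_equal(dim(crcu_forward(x2, crcu_config(16, seed = 2))), dim(x2))
})

test_that("SCRConv composes SRCU then CRCU and preserves shape", {
  set.seed(47)
  x <- rand_fmap(1, 32, 16, 16)
  s <- srcu_config(32)
  c <- crcu_config(32, seed = 3)
  out <- scrconv_forward(x, s, c)
  expect_equal(dim(out), dim(x))
  expect_equal(out, crcu_forward(srcu_forward(x, s), c), ignore_attr = TRUE)
})

test_that("SimAM closed-form energy matches hand values and weights stay in (0,1)", {
  # constant channel: e* = 2, weight sigmoid(0.5) everywhere
  x <- array(3, c(1, 1, 2, 2))
  e <- simam_energy(x, lam = 1e-4)
  expect_equal(as.vector(e), rep(2, 4), tolerance = 1e-3)
  out <- simam_forward(x, simam_config(1e-4))
  expect_equal(as.vector(attr(out, "weights")),
               rep(1 / (1 + exp(-0.5)), 4), tolerance = 1e-3)
  # channel {0, 2}: mu = 1, var = 1, e* = 4(1+lam)/(3+2lam)
  x2 <- array(c(0, 2), c(1, 1, 1, 2))
  lam <- 1e-4
  e2 <- simam_energy(x2, lam)
  expect_equal(as.vector(e2), rep(4 * (1 + lam) / (3 + 2 * lam), 2),
               tolerance = 1e-12)
  w2 <- attr(simam_forward(x2, simam_config(lam)), "weights")
  expect_equal(as.vector(w2), rep(plogis(1 / e2[1]), 2), tolerance = 1e-12)
  # weights strictly inside (0, 1), energies positive, shape preserved
  set.seed(48)
  xr <- rand_fmap(2, 3, 6, 6)
  o <- simam_forward(xr)
  w <- attr(o, "weights")
  expect_true(all(w > 0 & w < 1))
  expect_true(all(simam_energy(xr) > 0))
  expect_equal(dim(o), dim(xr))
  expect_error(simam_energy(array(1, c(1, 1, 1, 1))), "at least 2")
})

test_that("numeric energy minimization agrees with both closed-form conventions", {
  set.seed(49)
  # pooled convention is what the forward pass uses
  for (rep in 1:10) {
    M <- sample(4:20, 1)
    ch <- rnorm(M, sd = runif(1, 0.3, 2))
    ti <- sample(M, 1)
    lam <- 10^runif(1, -4, -1)
    num <- simam_oracle(ch, ti, lam, convention = "pooled")
    x <- array(ch, c(1, 1, 1, M))
    ana <- simam_energy(x, lam, stats = "pooled")[1, 1, 1, ti]
    expect_lt(abs(num - ana), 1e-6)
    nume <- simam_oracle(ch, ti, lam, convention = "exclusive")
    anae <- simam_energy(x, lam, stats = "exclusive")[1, 1, 1, ti]
    expect_lt(abs(nume - anae), 1e-6)
  }
  # worked two-neuron case, exclusive labels
  expect_equal(simam_oracle(c(0, 2), 2, 0.1, convention = "exclusive"),
               4 * 0.1 / (4 + 0.2), tolerance = 1e-6)
  # ridge-dominated limit: w -> 0, energy -> objective at w = 0 minimum
  big <- simam_oracle(c(0.3, -1, 2), 1, 1e6, convention = "exclusive")
  expect_gt(big, 0)
  expect_equal(big, 4 * (var(c(-1, 2)) * 1 / 2 + 1e6) /
                 ((0.3 - 0.5)^2 + 2 * var(c(-1, 2)) / 2 + 2e6),
               tolerance = 1e-3)
})

test_that("SimAM attention is exactly parameter-free in a network", {
  g0 <- build_yolov8s(nc = 3, width_mult = 0.0625, input_size = 64)
  g1 <- build_trdnet(nc = 3, width_mult = 0.0625, input_size = 64,
                     placement = character(0))  # SimAM only, no SCRConv
  expect_equal(count_parameters(g1), count_parameters(g0))
})
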