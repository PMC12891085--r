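tiny_graph <- function(layers, nc = 3L, input = 64L) {
  g <- structure(list(layers = layers, nc = nc, width_mult = 1,
                      depth_mult = 1, ratio = 2, reg_bins = 16L,
                      input_size = input, loss = "ciou", variant = "test"),
                 class = "model_graph")
  trdnet:::propagate_graph(g)
}

test_that("per-layer parameter accounting matches hand counts", {
  ls <- trdnet:::layer_spec
  # conv 3 -> 16, k3 + batch norm, no bias: 432 + 32
  g <- tiny_graph(list(
    ls("c", "Conv", "input", list(c2 = 16L, k = 3L, s = 2L)),
    ls("h", "DetectHead", c("c", "c", "c"),
       list(nc = 3L, reg_bins = 16L))))
  expect_equal(trdnet:::layer_parameters(g$layers[[1]], g), 464)
  # a SimAM layer contributes nothing anywhere
  g2 <- build_trdnet(nc = 3, width_mult = 0.0625, input_size = 64)
  att <- Filter(function(sp) sp$kind == "SimAM", g2$layers)
  expect_length(att, 4)
  expect_true(all(vapply(att, trdnet:::layer_parameters, numeric(1),
                         g = g2) == 0))
})

test_that("FLOP accounting follows the 2xMAC convention and scaling laws", {
  ls <- trdnet:::layer_spec
  # 1 -> 1 conv, k3, on a 4x4 map, stride 1: 2 * 9 * 16 = 288
  sp <- ls("c", "Conv", "input", list(c2 = 1L, k = 3L, s = 1L))
  sp$c_in <- 1L; sp$stride <- 1L
  g <- list(input_size = 4)
  expect_equal(trdnet:::layer_flops(sp, g, input_size = 4), 288)
  # halving the spatial input quarters the conv FLOPs
  b <- build_yolov8s(nc = 3)
  expect_equal(count_flops(b, 320) / count_flops(b, 640), 0.25)
})

test_that("s-scale totals reproduce the reference compression figures", {
  b <- build_yolov8s(nc = 3, width_mult = 0.5, depth_mult = 0.33)
  t <- build_trdnet(nc = 3, width_mult = 0.5, depth_mult = 0.33)
  expect_equal(count_parameters(b) / 1e6, 11.12, tolerance = 0.02)
  expect_equal(count_flops(b, 640) / 1e9, 28.6, tolerance = 0.02)
  expect_equal(count_parameters(t) / 1e6, 8.93, tolerance = 0.02)
  expect_equal(count_flops(t, 640) / 1e9, 22.3, tolerance = 0.02)
})

test_that("the variant is strictly lighter than the baseline at every scale", {
  for (w in c(0.5, 0.25, 0.125, 0.0625)) {
    b <- build_yolov8s(nc = 3, width_mult = w)
    t <- build_trdnet(nc = 3, width_mult = w)
    expect_lt(count_parameters(t), count_parameters(b))
    expect_lt(count_flops(t, 640), count_flops(b, 640))
  }
})

test_that("profiles are deterministic, additive, and report reductions", {
  b <- build_yolov8s(nc = 3)
  t <- build_trdnet(nc = 3)
  p1 <- profile_model(t, baseline = b)
  p2 <- profile_model(t, baseline = b)
  expect_identical(p1$parameters, p2$parameters)
  expect_identical(p1$flops, p2$flops)
  expect_equal(sum(p1$per_layer$params), p1$parameters)
  expect_equal(sum(p1$per_layer$flops), p1$flops)
  expect_gt(p1$param_reduction_pct, 0)
  expect_gt(p1$flop_reduction_pct, 0)
  out <- capture.output(print(p1))
  expect_true(any(grepl("reduction", out)))
  pr <- trd_profile(quiet = TRUE)
  expect_equal(pr$trdnet$parameters, p1$parameters)
})

test_that("the analytic count equals the instantiated weight scalars", {
  for (builder in list(build_yolov8s, build_trdnet)) {
    g <- builder(nc = 3, width_mult = 0.0625, input_size = 64)
    net <- trdnet:::instantiate_network(g, seed = 1)
    expect_equal(trdnet:::network_num_params(net), count_parameters(g))
  }
})

test_that("graphs serialize to a plain-text layer table and back", {
  t <- build_trdnet(nc = 3, width_mult = 0.125)
  f <- tempfile(fileext = ".tsv")
  write_model_table(t, f)
  back <- read_model_table(f)
  expect_equal(count_parameters(back), count_parameters(t))
  expect_equal(count_flops(back, 640), count_flops(t, 640))
  expect_equal(back$loss, "mpdiou")
  expect_equal(length(back$layers), length(t$layers))
})

test_that("head outputs appear at strides 8/16/32 with 4*bins + nc channels", {
  g <- build_trdnet(nc = 3, width_mult = 0.0625, input_size = 96)
  expect_equal(g$head_strides, c(8, 16, 32))
  net <- trdnet:::instantiate_network(g, seed = 2)
  x <- array(runif(1 * 3 * 96 * 96), c(1, 3, 96, 96))
  out <- network_forward(net, x)
  expect_length(out$head, 3)
  for (i in 1:3) {
    d <- dim(out$head[[i]])
    expect_equal(d[2], 4 * 16 + 3)
    expect_equal(d[3], 96 / c(8, 16, 32)[i])
  }
  # tiny baseline also builds and forward-passes a small input
  gb <- build_yolov8s(nc = 3, width_mult = 0.125, input_size = 160)
  nb <- trdnet:::instantiate_network(gb, seed = 3)
  xb <- array(runif(1 * 3 * 160 * 160), c(1, 3, 160, 160))
  ob <- network_forward(nb, xb)
  expect_equal(dim(ob$head[[1]])[3:4], c(20, 20))
})
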