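# Declarative model builders and exact parameter/FLOP accounting.
#
# A model graph is an ordered list of layer specs (kind, from, args) over
# which channel counts and feature-map strides are propagated, so parameter
# and FLOP totals are derived analytically, layer by layer, without
# instantiating weights. The same channel bookkeeping drives weight
# instantiation, so the analytic count equals the number of weight scalars
# of the instantiated network.
#
# Layer kinds: Conv (k x k conv + batch-norm + SiLU), C2f (split-bottleneck
# residual stage; optionally with its 3x3 bottleneck convolutions replaced
# by SCRConv), SPPF (spatial pyramid pooling fast), Upsample (nearest 2x),
# Concat, SimAM (parameter-free attention) and DetectHead (decoupled
# anchor-free head with distribution-focal box regression).

layer_spec <- function(name, kind, from, args = list()) {
  list(name = name, kind = kind, from = from, args = args)
}

# width scaling: multiples of 4 with a floor of 4, the divisibility the
# block bookkeeping needs (even channel splits, group convolutions)
scale_channels <- function(c_base, width_mult) {
  max(4L, as.integer(4L * round(c_base * width_mult / 4)))
}

scale_depth <- function(n_base, depth_mult) {
  max(1L, as.integer(round(n_base * depth_mult)))
}

#' Build the YOLOv8s-style baseline detection graph
#'
#' Backbone of Conv/C2f stages with an SPPF tail, a PAN feature-fusion neck,
#' and a decoupled anchor-free detection head at strides 8, 16 and 32 with
#' distribution-focal box regression (16 bins per side). At s-scale
#' (`width_mult = 0.5`, `depth_mult = 0.33`) with 3 classes the graph
#' carries about 11.1 M learnable parameters and 28.4 GFLOPs at 640 x 640.
#'
#' @param nc number of classes (>= 1).
#' @param width_mult channel width multiplier (0.50 = s-scale).
#' @param depth_mult stage depth multiplier (0.33 = s-scale).
#' @param ratio backbone deep-stage width ratio (2 at s-scale).
#' @param reg_bins distribution-focal regression bins per box side.
#' @param input_size nominal square input size in px.
#' @return an object of class `model_graph`.
#' @export
build_yolov8s <- function(nc = 3L, width_mult = 0.5, depth_mult = 0.33,
                          ratio = 2, reg_bins = 16L, input_size = 640L) {
  stopifnot(nc >= 1L, width_mult > 0, depth_mult > 0)
  ch <- function(x) scale_channels(x, width_mult)
  nd <- function(n) scale_depth(n, depth_mult)
  C1 <- ch(64); C2 <- ch(128); C3 <- ch(256); C4 <- ch(512)
  C5 <- ch(512 * ratio)
  L <- list(
    layer_spec("b1", "Conv", "input", list(c2 = C1, k = 3L, s = 2L)),
    layer_spec("b2", "Conv", "b1", list(c2 = C2, k = 3L, s = 2L)),
    layer_spec("b3", "C2f", "b2", list(c2 = C2, n = nd(3), shortcut = TRUE)),
    layer_spec("b4", "Conv", "b3", list(c2 = C3, k = 3L, s = 2L)),
    layer_spec("b5", "C2f", "b4", list(c2 = C3, n = nd(6), shortcut = TRUE)),
    layer_spec("b6", "Conv", "b5", list(c2 = C4, k = 3L, s = 2L)),
    layer_spec("b7", "C2f", "b6", list(c2 = C4, n = nd(6), shortcut = TRUE)),
    layer_spec("b8", "Conv", "b7", list(c2 = C5, k = 3L, s = 2L)),
    layer_spec("b9", "C2f", "b8", list(c2 = C5, n = nd(3), shortcut = TRUE)),
    layer_spec("sppf", "SPPF", "b9", list(c2 = C5, k = 5L)),
    layer_spec("up1", "Upsample", "sppf"),
    layer_spec("cat1", "Concat", c("up1", "b7")),
    layer_spec("n1", "C2f", "cat1", list(c2 = C4, n = nd(3),
                                         shortcut = FALSE)),
    layer_spec("up2", "Upsample", "n1"),
    layer_spec("cat2", "Concat", c("up2", "b5")),
    layer_spec("n2", "C2f", "cat2", list(c2 = C3, n = nd(3),
                                         shortcut = FALSE)),
    layer_spec("d1", "Conv", "n2", list(c2 = C3, k = 3L, s = 2L)),
    layer_spec("cat3", "Concat", c("d1", "n1")),
    layer_spec("n3", "C2f", "cat3", list(c2 = C4, n = nd(3),
                                         shortcut = FALSE)),
    layer_spec("d2", "Conv", "n3", list(c2 = C4, k = 3L, s = 2L)),
    layer_spec("cat4", "Concat", c("d2", "sppf")),
    layer_spec("n4", "C2f", "cat4", list(c2 = C5, n = nd(3),
                                         shortcut = FALSE)),
    layer_spec("head", "DetectHead", c("n2", "n3", "n4"),
               list(nc = as.integer(nc), reg_bins = as.integer(reg_bins)))
  )
  g <- structure(list(layers = L, nc = as.integer(nc),
                      width_mult = width_mult, depth_mult = depth_mult,
                      ratio = ratio, reg_bins = as.integer(reg_bins),
                      input_size = as.integer(input_size),
                      loss = "ciou", variant = "yolov8s"),
                 class = "model_graph")
  propagate_graph(g)
}

#' SCRConv placement table
#'
#' Names of the C2f stages whose 3x3 bottleneck convolutions are replaced by
#' SCRConv in the TRD-Net variant: the four neck fusion stages and the two
#' mid-backbone stages. The table is the single point of control for the
#' placement; the residual between the resulting parameter/FLOP totals and
#' the reference compression figures is reported by [profile_model()].
#'
#' @return character vector of layer names.
#' @export
trd_placement <- function() c("b5", "b7", "n1", "n2", "n3", "n4")

#' Build the TRD-Net detection graph
#'
#' The baseline graph of [build_yolov8s()] with (a) the 3x3 convolutions
#' inside the C2f bottlenecks of the stages named by `placement` replaced by
#' SCRConv, (b) parameter-free SimAM attention inserted after each neck C2f
#' output, and (c) the box-regression loss bound to MPDIoU. At equal scale
#' the variant always carries strictly fewer parameters and FLOPs than the
#' baseline.
#'
#' @inheritParams build_yolov8s
#' @param placement character vector of C2f stage names receiving SCRConv;
#'   default [trd_placement()].
#' @param simam_lam SimAM regularization lambda.
#' @return an object of class `model_graph`.
#' @export
build_trdnet <- function(nc = 3L, width_mult = 0.5, depth_mult = 0.33,
                         ratio = 2, reg_bins = 16L, input_size = 640L,
                         placement = trd_placement(), simam_lam = 1e-4) {
  g <- build_yolov8s(nc, width_mult, depth_mult, ratio, reg_bins, input_size)
  L <- g$layers
  for (i in seq_along(L)) {
    if (L[[i]]$kind == "C2f" && L[[i]]$name %in% placement)
      L[[i]]$args$scr <- TRUE
  }
  # insert SimAM after each neck C2f output, rebinding consumers
  out <- list()
  att_of <- character(0)
  neck_c2f <- c("n1", "n2", "n3", "n4")
  for (sp in L) {
    sp$from <- ifelse(sp$from %in% names(att_of),
                      unname(att_of[sp$from]), sp$from)
    out[[length(out) + 1L]] <- sp
    if (sp$kind == "C2f" && sp$name %in% neck_c2f) {
      att <- paste0("att_", sp$name)
      out[[length(out) + 1L]] <-
        layer_spec(att, "SimAM", sp$name, list(lam = simam_lam))
      att_of[sp$name] <- att
    }
  }
  g$layers <- out
  g$loss <- "mpdiou"
  g$variant <- "trdnet"
  propagate_graph(g)
}

# Channel bookkeeping shared by the profiler and the weight instantiation.
scrconv_plan <- function(C, alpha = 0.5, squeeze_ratio = 2L, gwc_groups = 2L,
                         kernel = 3L) {
  up <- as.integer(round(alpha * C)); lo <- C - up
  up_s <- max(1L, as.integer(round(up / squeeze_ratio)))
  lo_s <- max(1L, as.integer(round(lo / squeeze_ratio)))
  g <- largest_divisor_leq(gcd2(up_s, C), as.integer(gwc_groups))
  list(C = C, alpha = alpha, squeeze_ratio = squeeze_ratio, kernel = kernel,
       up = up, lo = lo, up_s = up_s, lo_s = lo_s, g = g,
       pwc2_out = C - lo_s)
}

scrconv_params <- function(C, ...) {
  p <- scrconv_plan(C, ...)
  k <- p$kernel
  # GN affine (2C) + squeeze convs + GWC + PWC1 + PWC2
  2 * C + p$up * p$up_s + p$lo * p$lo_s + (p$up_s / p$g) * C * k * k +
    p$up_s * C + p$lo_s * p$pwc2_out
}

scrconv_macs_per_px <- function(C, ...) {
  p <- scrconv_plan(C, ...)
  k <- p$kernel
  p$up * p$up_s + p$lo * p$lo_s + (p$up_s / p$g) * C * k * k +
    p$up_s * C + p$lo_s * p$pwc2_out
}

conv_params <- function(c1, c2, k) c1 * c2 * k * k + 2 * c2

c2f_hidden <- function(c2) as.integer(c2 / 2)

head_hidden <- function(ch_p3, nc, reg_bins) {
  list(c2 = max(16L, ch_p3 %/% 4L, 4L * reg_bins),
       c3 = max(ch_p3, min(nc, 100L)))
}

# Propagate output channels and strides through the graph.
propagate_graph <- function(g) {
  ch <- c(input = 3L)
  st <- c(input = 1L)
  for (i in seq_along(g$layers)) {
    sp <- g$layers[[i]]
    cin <- unname(ch[sp$from]); sin <- unname(st[sp$from])
    if (anyNA(cin)) stop("layer ", sp$name, ": unknown input ", sp$from)
    cout <- switch(sp$kind,
      Conv = sp$args$c2,
      C2f = sp$args$c2,
      SPPF = sp$args$c2,
      Upsample = cin[1],
      Concat = sum(cin),
      SimAM = cin[1],
      DetectHead = NA_integer_,
      stop("unknown layer kind: ", sp$kind))
    sout <- switch(sp$kind,
      Conv = sin[1] * sp$args$s,
      Upsample = sin[1] %/% 2L,
      DetectHead = NA_integer_,
      sin[1])
    if (sp$kind == "Concat" && length(unique(sin)) != 1L)
      stop("concat inputs at different strides")
    g$layers[[i]]$c_in <- cin
    g$layers[[i]]$c_out <- cout
    g$layers[[i]]$stride <- sout
    ch[sp$name] <- cout
    st[sp$name] <- sout
  }
  head <- g$layers[[which(vapply(g$layers, `[[`, "", "kind") ==
                            "DetectHead")]]
  g$head_strides <- unname(st[head$from])
  g$head_channels <- unname(ch[head$from])
  g
}

layer_parameters <- function(sp, g) {
  a <- sp$args
  switch(sp$kind,
    Conv = conv_params(sp$c_in, a$c2, a$k),
    C2f = {
      c <- c2f_hidden(a$c2)
      bott <- if (isTRUE(a$scr)) 2 * scrconv_params(c) else
        2 * conv_params(c, c, 3)
      conv_params(sp$c_in, 2 * c, 1) +
        conv_params((2 + a$n) * c, a$c2, 1) + a$n * bott
    },
    SPPF = {
      h <- sp$c_in %/% 2L
      conv_params(sp$c_in, h, 1) + conv_params(4 * h, a$c2, 1)
    },
    DetectHead = {
      hh <- head_hidden(sp$c_in[1], a$nc, a$reg_bins)
      sum(vapply(sp$c_in, function(p)
        conv_params(p, hh$c2, 3) + conv_params(hh$c2, hh$c2, 3) +
          (hh$c2 * 4 * a$reg_bins + 4 * a$reg_bins) +
          conv_params(p, hh$c3, 3) + conv_params(hh$c3, hh$c3, 3) +
          (hh$c3 * a$nc + a$nc), numeric(1)))
    },
    0)
}

layer_flops <- function(sp, g, input_size) {
  a <- sp$args
  px <- function(stride) (input_size / stride)^2
  mac <- switch(sp$kind,
    Conv = (sp$c_in * a$k^2) * a$c2 * px(sp$stride),
    C2f = {
      c <- c2f_hidden(a$c2)
      p <- px(sp$stride)
      bott <- if (isTRUE(a$scr)) 2 * scrconv_macs_per_px(c) * p else
        2 * c * c * 9 * p
      sp$c_in * 2 * c * p + (2 + a$n) * c * a$c2 * p + a$n * bott
    },
    SPPF = {
      h <- sp$c_in %/% 2L
      p <- px(sp$stride)
      sp$c_in * h * p + 4 * h * a$c2 * p
    },
    DetectHead = {
      hh <- head_hidden(sp$c_in[1], a$nc, a$reg_bins)
      s <- 0
      for (i in seq_along(sp$c_in)) {
        p <- px(g$head_strides[i])
        s <- s + (sp$c_in[i] * 9 * hh$c2 + 9 * hh$c2^2 +
                    hh$c2 * 4 * a$reg_bins) * p +
          (sp$c_in[i] * 9 * hh$c3 + 9 * hh$c3^2 + hh$c3 * a$nc) * p
      }
      s
    },
    0)
  2 * mac
}

#' Count learnable parameters of a model graph
#'
#' Sum of learnable scalar entries (convolution weights, normalization
#' affines, head biases) over all layers; deterministic, and equal to the
#' number of weight scalars the instantiated network trains. SimAM layers
#' contribute exactly zero.
#'
#' @param g a `model_graph`.
#' @return integer parameter count.
#' @export
count_parameters <- function(g) {
  stopifnot(inherits(g, "model_graph"))
  sum(vapply(g$layers, layer_parameters, numeric(1), g = g))
}

#' Count forward-pass FLOPs of a model graph
#'
#' FLOPs are counted as 2 x multiply-accumulate operations of the
#' convolution and linear layers at batch 1 for a square input;
#' normalizations, activations, pooling and the parameter-free attention are
#' excluded as fusable or negligible.
#'
#' @param g a `model_graph`.
#' @param input_size square input size in px (default: the graph's).
#' @return FLOP count (numeric).
#' @export
count_flops <- function(g, input_size = g$input_size) {
  stopifnot(inherits(g, "model_graph"), input_size %% 32 == 0)
  sum(vapply(g$layers, layer_flops, numeric(1), g = g,
             input_size = input_size))
}

#' Profile a model graph (and optionally compare to a baseline)
#'
#' @param g a `model_graph`.
#' @param baseline optional second `model_graph` to report reductions
#'   against.
#' @param input_size square input size for the FLOP count.
#' @return an object of class `profile_report` with totals, a per-layer
#'   breakdown, and (with a baseline) percentage reductions.
#' @export
profile_model <- function(g, baseline = NULL, input_size = g$input_size) {
  per <- data.frame(
    name = vapply(g$layers, `[[`, "", "name"),
    kind = vapply(g$layers, `[[`, "", "kind"),
    params = vapply(g$layers, layer_parameters, numeric(1), g = g),
    flops = vapply(g$layers, layer_flops, numeric(1), g = g,
                   input_size = input_size))
  rep <- list(parameters = sum(per$params), flops = sum(per$flops),
              per_layer = per, input_size = input_size,
              size_mb = sum(per$params) * 2 / 1e6,   # half-precision weights
              variant = g$variant)
  if (!is.null(baseline)) {
    bp <- count_parameters(baseline)
    bf <- count_flops(baseline, input_size)
    rep$param_reduction_pct <- 100 * (bp - rep$parameters) / bp
    rep$flop_reduction_pct <- 100 * (bf - rep$flops) / bf
    rep$baseline_parameters <- bp
    rep$baseline_flops <- bf
  }
  class(rep) <- "profile_report"
  rep
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("%s @ %d px\n", x$variant, x$input_size))
  cat(sprintf("  parameters: %.2f M\n", x$parameters / 1e6))
  cat(sprintf("  FLOPs: %.1f G\n", x$flops / 1e9))
  cat(sprintf("  size: %.1f MB (fp16)\n", x$size_mb))
  if (!is.null(x$param_reduction_pct)) {
    cat(sprintf("  parameter reduction vs baseline: %.2f%%\n",
                x$param_reduction_pct))
    cat(sprintf("  FLOP reduction vs baseline: %.2f%%\n",
                x$flop_reduction_pct))
  }
  invisible(x)
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("model_graph '%s': %d layers, nc=%d, width=%.3g, depth=%.3g, loss=%s\n",
              x$variant, length(x$layers), x$nc, x$width_mult, x$depth_mult,
              x$loss))
  cat(sprintf("  parameters %.3f M, FLOPs %.2f G @ %d px\n",
              count_parameters(x) / 1e6, count_flops(x) / 1e9,
              x$input_size))
  invisible(x)
}

#' Write or read a model graph as a plain-text layer table
#'
#' One row per layer: name, kind, comma-separated inputs, and key=value
#' arguments; header lines carry the scalar graph fields.
#'
#' @param g a `model_graph`.
#' @param path file path.
#' @return `read_model_table` returns a `model_graph`.
#' @export
write_model_table <- function(g, path) {
  hdr <- sprintf("# nc=%d width=%g depth=%g ratio=%g reg_bins=%d input=%d loss=%s variant=%s",
                 g$nc, g$width_mult, g$depth_mult, g$ratio, g$reg_bins,
                 g$input_size, g$loss, g$variant)
  rows <- vapply(g$layers, function(sp) {
    args <- sp$args
    kv <- if (length(args))
      paste(names(args), vapply(args, function(v)
        format(v, digits = 10), character(1)), sep = "=", collapse = ",")
    else "-"
    paste(sp$name, sp$kind, paste(sp$from, collapse = ","), kv, sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_model_table
#' @export
read_model_table <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kvh <- strsplit(hdr, "=")
  hv <- setNames(vapply(kvh, `[`, "", 2), vapply(kvh, `[`, "", 1))
  layers <- lapply(lines[-1], function(l) {
    f <- strsplit(l, "\t")[[1]]
    args <- list()
    if (f[4] != "-") {
      for (kv in strsplit(f[4], ",")[[1]]) {
        p <- strsplit(kv, "=")[[1]]
        v <- suppressWarnings(as.numeric(p[2]))
        if (is.na(v)) v <- as.logical(p[2])
        if (p[1] %in% c("c2", "k", "s", "n", "nc", "reg_bins"))
          v <- as.integer(v)
        args[[p[1]]] <- v
      }
    }
    layer_spec(f[1], f[2], strsplit(f[3], ",")[[1]], args)
  })
  g <- structure(list(layers = layers, nc = as.integer(hv["nc"]),
                      width_mult = as.numeric(hv["width"]),
                      depth_mult = as.numeric(hv["depth"]),
                      ratio = as.numeric(hv["ratio"]),
                      reg_bins = as.integer(hv["reg_bins"]),
                      input_size = as.integer(hv["input"]),
                      loss = unname(hv["loss"]),
                      variant = unname(hv["variant"])),
                 class = "model_graph")
  propagate_graph(g)
}
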