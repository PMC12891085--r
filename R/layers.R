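# Trainable network modules. Every module is an environment exposing
#   $fw(xs, train)  - forward on a list of input arrays (N,C,H,W)
#   $bw(dys)        - backward given the output gradient, returning the list
#                     of input gradients; parameter gradients accumulate in
#                     the module
# and (for parameterized primitives) $par / $grad lists of arrays. Composite
# modules register their primitives in $prims so the optimizer and the
# parameter count can walk a flat list. Gradients are hand-derived and
# checked against finite differences in the tests.

new_module <- function() {
  e <- new.env(parent = emptyenv())
  e$prims <- list()
  e
}

kaiming <- function(dims) {
  fan_in <- prod(dims[-1])
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# conv + batch norm + optional SiLU
prim_conv <- function(c1, c2, k, s = 1L, groups = 1L, act = TRUE) {
  e <- new_module()
  e$kind <- "conv_bn"
  e$k <- as.integer(k); e$s <- as.integer(s); e$g <- as.integer(groups)
  e$pad <- (e$k - 1L) %/% 2L
  e$act <- act
  e$par <- list(w = kaiming(c(c2, c1 %/% groups, k, k)),
                gamma = rep(1, c2), beta = rep(0, c2))
  e$grad <- lapply(e$par, function(p) p * 0)
  e$rm <- rep(0, c2); e$rv <- rep(1, c2)   # running stats (eval mode)
  e$eps <- 1e-3; e$mom <- 0.03
  e$prims <- list(e)
  e$fw <- function(xs, train = FALSE) {
    x <- xs[[1]]
    z <- .conv2d_fw(x, e$par$w, NULL, e$s, e$pad, e$g)
    d <- dim(z)
    N <- d[1]; C <- d[2]
    # (N,C,H,W) column-major is already (N*C) x (H*W); length-(N*C)
    # vectors recycle down the columns, so all BN algebra is copy-free
    zm <- matrix(z, N * C)
    if (train) {
      mu <- colMeans(matrix(rowMeans(zm), N, C))
      v <- colMeans(matrix(rowMeans(zm * zm), N, C)) - mu^2
      e$rm <- (1 - e$mom) * e$rm + e$mom * mu
      e$rv <- (1 - e$mom) * e$rv + e$mom * v
    } else {
      mu <- e$rm; v <- e$rv
    }
    invr <- rep(1 / sqrt(v + e$eps), each = N)
    xh <- (zm - rep(mu, each = N)) * invr
    ym <- xh * rep(e$par$gamma, each = N) + rep(e$par$beta, each = N)
    y <- array(ym, d)
    if (train) { e$x <- x; e$xh <- xh; e$invr <- invr; e$dims <- d
                 e$ypre <- if (e$act) y else NULL }
    if (e$act) silu(y) else y
  }
  e$bw <- function(dy) {
    d <- e$dims
    N <- d[1]; C <- d[2]
    if (e$act) dy <- dy * silu_grad(e$ypre)
    dym <- matrix(dy, N * C)
    M <- N * d[3] * d[4]
    csum <- function(m) colSums(matrix(rowSums(m), N, C))
    e$grad$beta <- e$grad$beta + csum(dym)
    e$grad$gamma <- e$grad$gamma + csum(dym * e$xh)
    dxh <- dym * rep(e$par$gamma, each = N)
    s1 <- csum(dxh); s2 <- csum(dxh * e$xh)
    dzm <- e$invr * (dxh - e$xh * rep(s2 / M, each = N) -
                       rep(s1 / M, each = N))
    dz <- array(dzm, d)
    r <- .conv2d_bw(e$x, e$par$w, dz, e$s, e$pad, e$g, FALSE)
    e$grad$w <- e$grad$w + r$dw
    e$x <- e$xh <- e$ypre <- e$invr <- NULL
    list(r$dx)
  }
  e
}

# plain convolution, optional bias, no norm, no activation
prim_raw <- function(c1, c2, k, groups = 1L, bias = TRUE, pad = NULL) {
  e <- new_module()
  e$kind <- "conv_raw"
  e$k <- as.integer(k); e$g <- as.integer(groups)
  e$pad <- if (is.null(pad)) (e$k - 1L) %/% 2L else as.integer(pad)
  e$par <- list(w = kaiming(c(c2, c1 %/% groups, k, k)))
  if (bias) e$par$b <- rep(0, c2)
  e$grad <- lapply(e$par, function(p) p * 0)
  e$prims <- list(e)
  e$fw <- function(xs, train = FALSE) {
    x <- xs[[1]]
    if (train) e$x <- x
    .conv2d_fw(x, e$par$w, if (is.null(e$par$b)) NULL else e$par$b,
               1L, e$pad, e$g)
  }
  e$bw <- function(dy) {
    r <- .conv2d_bw(e$x, e$par$w, dy, 1L, e$pad, e$g, !is.null(e$par$b))
    e$grad$w <- e$grad$w + r$dw
    if (!is.null(e$par$b)) e$grad$b <- e$grad$b + r$db
    e$x <- NULL
    list(r$dx)
  }
  e
}

mod_upsample <- function() {
  e <- new_module()
  e$kind <- "upsample"
  e$fw <- function(xs, train = FALSE) .upsample2x_fw(xs[[1]])
  e$bw <- function(dy) list(.upsample2x_bw(dy))
  e
}

mod_concat <- function() {
  e <- new_module()
  e$kind <- "concat"
  e$fw <- function(xs, train = FALSE) {
    e$splits <- vapply(xs, function(x) dim(x)[2], integer(1))
    d <- dim(xs[[1]])
    out <- array(0, c(d[1], sum(e$splits), d[3], d[4]))
    off <- 0L
    for (x in xs) {
      out[, off + seq_len(dim(x)[2]), , ] <- x
      off <- off + dim(x)[2]
    }
    out
  }
  e$bw <- function(dy) {
    off <- 0L
    out <- vector("list", length(e$splits))
    for (i in seq_along(e$splits)) {
      out[[i]] <- dy[, off + seq_len(e$splits[i]), , , drop = FALSE]
      off <- off + e$splits[i]
    }
    out
  }
  e
}

mod_simam <- function(lam = 1e-4) {
  e <- new_module()
  e$kind <- "simam"
  e$lam <- lam
  e$fw <- function(xs, train = FALSE) {
    x <- xs[[1]]
    d <- dim(x)
    st <- channel_stats(x)
    mu <- channel_scale(array(1, d), st$mean)
    v <- channel_scale(array(1, d), st$var)
    A <- 4 * (v + e$lam)
    u <- (x - mu)^2 / A + 0.5
    w <- sigmoid(u)
    if (train) { e$x <- x; e$mu <- mu; e$A <- A; e$w <- w; e$d <- d }
    w * x
  }
  e$bw <- function(dy) {
    x <- e$x; mu <- e$mu; A <- e$A; w <- e$w; d <- e$d
    M <- d[3] * d[4]
    h <- dy * x * w * (1 - w)          # g_i x_i sigma'(u_i), per position
    xc <- x - mu
    # per-channel sums (N x C)
    rs <- function(a) matrix(rowSums(matrix(a, nrow = d[1] * d[2])),
                             d[1], d[2])
    S1 <- rs(h * xc)
    S2 <- rs(h * xc^2)
    dx <- dy * w + 2 * h * xc / A -
      channel_scale(array(1, d) / A, 2 * S1 / M) -
      (8 * xc / (M * A^2)) * channel_scale(array(1, d), S2)
    e$x <- e$mu <- e$A <- e$w <- NULL
    list(dx)
  }
  e
}

# SRCU + CRCU (+ SiLU) as a drop-in for a 3x3 conv-bn-act. The SRCU group
# normalization drives only the hard gate, so its affine parameters receive
# no gradient (listed with zero gradient for completeness).
mod_scrconv <- function(C, act = TRUE) {
  e <- new_module()
  e$kind <- "scrconv"
  plan <- scrconv_plan(C)
  e$plan <- plan
  e$srcu <- srcu_config(C)
  e$par <- list(gn_gamma = rep(1, C), gn_beta = rep(0, C))
  e$grad <- lapply(e$par, function(p) p * 0)
  pad <- (plan$kernel - 1L) %/% 2L
  e$sq_up <- prim_raw(plan$up, plan$up_s, 1L, bias = FALSE)
  e$sq_lo <- prim_raw(plan$lo, plan$lo_s, 1L, bias = FALSE)
  e$gwc <- prim_raw(plan$up_s, C, plan$kernel, groups = plan$g, bias = FALSE)
  e$pwc1 <- prim_raw(plan$up_s, C, 1L, bias = FALSE)
  e$pwc2 <- prim_raw(plan$lo_s, plan$pwc2_out, 1L, bias = FALSE)
  e$act <- act
  e$prims <- c(list(e), e$sq_up$prims, e$sq_lo$prims, e$gwc$prims,
               e$pwc1$prims, e$pwc2$prims)
  e$fw <- function(xs, train = FALSE) {
    x <- xs[[1]]
    e$srcu$gamma <- e$par$gn_gamma
    e$srcu$beta <- e$par$gn_beta
    gate <- srcu_gate_weights(x, e$srcu)
    xw <- srcu_reconstruct(gate$W1 * x, gate$W2 * x)
    if (train) { e$W1 <- gate$W1; e$W2 <- gate$W2 }
    p <- e$plan
    x_up <- xw[, seq_len(p$up), , , drop = FALSE]
    x_lo <- xw[, p$up + seq_len(p$lo), , , drop = FALSE]
    us <- e$sq_up$fw(list(x_up), train)
    ls <- e$sq_lo$fw(list(x_lo), train)
    y1 <- e$gwc$fw(list(us), train) + e$pwc1$fw(list(us), train)
    y2a <- e$pwc2$fw(list(ls), train)
    d <- dim(xw)
    y2 <- array(0, d)
    y2[, seq_len(p$pwc2_out), , ] <- y2a
    y2[, p$pwc2_out + seq_len(p$lo_s), , ] <- ls
    # channel soft-attention fusion
    s1 <- channel_stats(y1)$mean; s2 <- channel_stats(y2)$mean
    m <- pmax(s1, s2)
    e1 <- exp(s1 - m); e2 <- exp(s2 - m)
    b1 <- e1 / (e1 + e2)
    out <- channel_scale(y1, b1) + channel_scale(y2, 1 - b1)
    if (train) {
      e$y1 <- y1; e$y2 <- y2; e$b1 <- b1; e$ls <- ls; e$d <- d
      e$ypre <- out
    }
    if (e$act) silu(out) else out
  }
  e$bw <- function(dy) {
    p <- e$plan; d <- e$d
    if (e$act) dy <- dy * silu_grad(e$ypre)
    b1 <- e$b1; b2 <- 1 - b1
    HW <- d[3] * d[4]
    diff <- e$y1 - e$y2
    tsum <- matrix(rowSums(matrix(dy * diff, nrow = d[1] * d[2])),
                   d[1], d[2])
    db <- tsum * b1 * b2 / HW           # dL/ds1 spread per pixel
    dy1 <- channel_scale(dy, b1) + channel_scale(array(1, d), db)
    dy2 <- channel_scale(dy, b2) - channel_scale(array(1, d), db)
    dls <- dy2[, p$pwc2_out + seq_len(p$lo_s), , , drop = FALSE]
    dy2a <- dy2[, seq_len(p$pwc2_out), , , drop = FALSE]
    dls <- dls + e$pwc2$bw(dy2a)[[1]]
    dus <- e$gwc$bw(dy1)[[1]] + e$pwc1$bw(dy1)[[1]]
    dx_up <- e$sq_up$bw(dus)[[1]]
    dx_lo <- e$sq_lo$bw(dls)[[1]]
    dxw <- array(0, d)
    dxw[, seq_len(p$up), , ] <- dx_up
    dxw[, p$up + seq_len(p$lo), , ] <- dx_lo
    # backward through cross-reconstruction, then the hard gate
    C <- d[2]; h <- C %/% 2L
    a <- seq_len(h); b <- h + seq_len(h)
    dx1w <- dxw; dx2w <- dxw
    dx1w[, a, , ] <- dxw[, a, , , drop = FALSE]
    dx1w[, b, , ] <- dxw[, b, , , drop = FALSE]
    dx2w[, a, , ] <- dxw[, b, , , drop = FALSE]
    dx2w[, b, , ] <- dxw[, a, , , drop = FALSE]
    dx <- e$W1 * dx1w + e$W2 * dx2w
    e$y1 <- e$y2 <- e$ypre <- e$W1 <- e$W2 <- e$ls <- NULL
    list(dx)
  }
  e
}

mod_bottleneck <- function(c, shortcut = TRUE, scr = FALSE) {
  e <- new_module()
  e$kind <- "bottleneck"
  e$shortcut <- shortcut
  mk <- function() if (scr) mod_scrconv(c) else prim_conv(c, c, 3L)
  e$cv1 <- mk(); e$cv2 <- mk()
  e$prims <- c(e$cv1$prims, e$cv2$prims)
  e$fw <- function(xs, train = FALSE) {
    x <- xs[[1]]
    y <- e$cv2$fw(list(e$cv1$fw(xs, train)), train)
    if (e$shortcut) x + y else y
  }
  e$bw <- function(dy) {
    dx <- e$cv1$bw(e$cv2$bw(dy)[[1]])[[1]]
    list(if (e$shortcut) dy + dx else dx)
  }
  e
}

mod_c2f <- function(c1, c2, n, shortcut = FALSE, scr = FALSE) {
  e <- new_module()
  e$kind <- "c2f"
  e$c <- c2f_hidden(c2)
  e$n <- n
  e$cv1 <- prim_conv(c1, 2L * e$c, 1L)
  e$cv2 <- prim_conv((2L + n) * e$c, c2, 1L)
  e$bott <- lapply(seq_len(n), function(i) mod_bottleneck(e$c, shortcut, scr))
  e$prims <- c(e$cv1$prims, e$cv2$prims,
               do.call(c, lapply(e$bott, `[[`, "prims")))
  e$fw <- function(xs, train = FALSE) {
    y <- e$cv1$fw(xs, train)
    c <- e$c
    ys <- list(y[, seq_len(c), , , drop = FALSE],
               y[, c + seq_len(c), , , drop = FALSE])
    for (b in e$bott)
      ys[[length(ys) + 1L]] <- b$fw(list(ys[[length(ys)]]), train)
    d <- dim(y)
    cat_in <- array(0, c(d[1], (2L + e$n) * c, d[3], d[4]))
    for (i in seq_along(ys))
      cat_in[, (i - 1L) * c + seq_len(c), , ] <- ys[[i]]
    e$d <- d
    e$cv2$fw(list(cat_in), train)
  }
  e$bw <- function(dy) {
    dcat <- e$cv2$bw(dy)[[1]]
    c <- e$c
    dys <- lapply(seq_len(2L + e$n), function(i)
      dcat[, (i - 1L) * c + seq_len(c), , , drop = FALSE])
    for (i in rev(seq_len(e$n))) {
      dprev <- e$bott[[i]]$bw(dys[[i + 2L]])[[1]]
      dys[[i + 1L]] <- dys[[i + 1L]] + dprev
    }
    d <- e$d
    dxy <- array(0, d)
    dxy[, seq_len(c), , ] <- dys[[1]]
    dxy[, c + seq_len(c), , ] <- dys[[2]]
    e$cv1$bw(dxy)
  }
  e
}

mod_sppf <- function(c1, c2, k = 5L) {
  e <- new_module()
  e$kind <- "sppf"
  h <- c1 %/% 2L
  e$cv1 <- prim_conv(c1, h, 1L)
  e$cv2 <- prim_conv(4L * h, c2, 1L)
  e$k <- as.integer(k)
  e$prims <- c(e$cv1$prims, e$cv2$prims)
  e$fw <- function(xs, train = FALSE) {
    y <- e$cv1$fw(xs, train)
    pad <- (e$k - 1L) %/% 2L
    p1 <- .maxpool2d_fw(y, e$k, 1L, pad)
    p2 <- .maxpool2d_fw(p1$y, e$k, 1L, pad)
    p3 <- .maxpool2d_fw(p2$y, e$k, 1L, pad)
    if (train) {
      e$am <- list(p1$argmax, p2$argmax, p3$argmax)
      e$ydim <- dim(y)
    }
    d <- dim(y)
    out <- array(0, c(d[1], 4L * d[2], d[3], d[4]))
    out[, seq_len(d[2]), , ] <- y
    out[, d[2] + seq_len(d[2]), , ] <- p1$y
    out[, 2L * d[2] + seq_len(d[2]), , ] <- p2$y
    out[, 3L * d[2] + seq_len(d[2]), , ] <- p3$y
    e$cv2$fw(list(out), train)
  }
  e$bw <- function(dy) {
    dcat <- e$cv2$bw(dy)[[1]]
    d <- e$ydim
    g <- function(i) dcat[, (i - 1L) * d[2] + seq_len(d[2]), , ,
                          drop = FALSE]
    d3 <- .maxpool2d_bw(g(4), e$am[[3]], d)
    d2 <- .maxpool2d_bw(g(3) + d3, e$am[[2]], d)
    d1 <- .maxpool2d_bw(g(2) + d2, e$am[[1]], d)
    e$cv1$bw(g(1) + d1)
  }
  e
}

mod_detect <- function(ch, nc, reg_bins = 16L) {
  e <- new_module()
  e$kind <- "detect"
  e$nc <- as.integer(nc); e$reg_bins <- as.integer(reg_bins)
  hh <- head_hidden(ch[1], nc, reg_bins)
  e$branches <- lapply(ch, function(p) {
    reg <- list(prim_conv(p, hh$c2, 3L), prim_conv(hh$c2, hh$c2, 3L),
                prim_raw(hh$c2, 4L * reg_bins, 1L, bias = TRUE))
    cls <- list(prim_conv(p, hh$c3, 3L), prim_conv(hh$c3, hh$c3, 3L),
                prim_raw(hh$c3, nc, 1L, bias = TRUE))
    # start with a small-distance box prior and low class probabilities
    reg[[3]]$par$b[] <- rep(1 - 0.3 * (0:(reg_bins - 1)), 4)
    cls[[3]]$par$b[] <- stats::qlogis(0.01)
    list(reg = reg, cls = cls)
  })
  e$prims <- do.call(c, lapply(e$branches, function(br)
    do.call(c, lapply(c(br$reg, br$cls), `[[`, "prims"))))
  e$fw <- function(xs, train = FALSE) {
    lapply(seq_along(xs), function(i) {
      br <- e$branches[[i]]
      r <- xs[i]
      for (m in br$reg) r <- list(m$fw(r, train))
      cl <- xs[i]
      for (m in br$cls) cl <- list(m$fw(cl, train))
      d <- dim(r[[1]])
      out <- array(0, c(d[1], 4L * e$reg_bins + e$nc, d[3], d[4]))
      out[, seq_len(4L * e$reg_bins), , ] <- r[[1]]
      out[, 4L * e$reg_bins + seq_len(e$nc), , ] <- cl[[1]]
      out
    })
  }
  e$bw <- function(dys) {
    lapply(seq_along(dys), function(i) {
      br <- e$branches[[i]]
      dr <- dys[[i]][, seq_len(4L * e$reg_bins), , , drop = FALSE]
      dc <- dys[[i]][, 4L * e$reg_bins + seq_len(e$nc), , , drop = FALSE]
      for (m in rev(br$reg)) dr <- m$bw(dr)[[1]]
      for (m in rev(br$cls)) dc <- m$bw(dc)[[1]]
      dr + dc
    })
  }
  e
}

#' Instantiate a model graph into a trainable network
#'
#' Allocates weights for every layer of the graph (Kaiming-initialized
#' convolutions, unit batch-norm affines) under the given seed. The number
#' of weight scalars equals [count_parameters()] of the graph.
#'
#' @param g a `model_graph` from [build_yolov8s()] or [build_trdnet()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `trdnet_network`.
#' @export
instantiate_network <- function(g, seed = 0L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  mods <- list()
  for (sp in g$layers) {
    a <- sp$args
    mods[[sp$name]] <- switch(sp$kind,
      Conv = prim_conv(sp$c_in, a$c2, a$k, a$s),
      C2f = mod_c2f(sp$c_in, a$c2, a$n, isTRUE(a$shortcut), isTRUE(a$scr)),
      SPPF = mod_sppf(sp$c_in, a$c2, a$k),
      Upsample = mod_upsample(),
      Concat = mod_concat(),
      SimAM = mod_simam(a$lam %||% 1e-4),
      DetectHead = mod_detect(sp$c_in, a$nc, a$reg_bins),
      stop("unknown kind ", sp$kind))
  }
  prims <- do.call(c, lapply(mods, `[[`, "prims"))
  structure(list(graph = g, mods = mods, prims = prims),
            class = "trdnet_network")
}

# Number of weight scalars held by the instantiated network.
network_num_params <- function(net) {
  sum(vapply(net$prims, function(p)
    sum(vapply(p$par, length, numeric(1))), numeric(1)))
}

#' Run the network forward
#'
#' @param net a `trdnet_network`.
#' @param x input array (N, 3, H, W) with H, W multiples of 32.
#' @param train train mode flag (batch statistics + caches for backward).
#' @param keep_outputs if TRUE, all per-layer outputs are returned for
#'   inspection (feature hooks, Grad-CAM).
#' @return list with `head` (list of raw per-scale outputs, channels
#'   `4*reg_bins + nc`) and optionally `outputs`.
#' @export
network_forward <- function(net, x, train = FALSE, keep_outputs = FALSE) {
  outs <- list(input = x)
  for (sp in net$graph$layers) {
    xs <- outs[sp$from]
    outs[[sp$name]] <- net$mods[[sp$name]]$fw(xs, train)
  }
  head_name <- net$graph$layers[[length(net$graph$layers)]]$name
  res <- list(head = outs[[head_name]])
  if (keep_outputs) res$outputs <- outs
  res
}

# Backward from head gradients; accumulates parameter gradients in the
# modules and returns per-layer output gradients (for feature attribution).
network_backward <- function(net, dhead) {
  L <- net$graph$layers
  d <- list()
  d[[L[[length(L)]]$name]] <- dhead
  for (i in rev(seq_along(L))) {
    sp <- L[[i]]
    dy <- d[[sp$name]]
    if (is.null(dy)) next
    dxs <- net$mods[[sp$name]]$bw(dy)
    for (j in seq_along(sp$from)) {
      nm <- sp$from[j]
      if (nm == "input") next
      d[[nm]] <- if (is.null(d[[nm]])) dxs[[j]] else d[[nm]] + dxs[[j]]
    }
  }
  invisible(d)
}

zero_grads <- function(net) {
  for (p in net$prims)
    if (!is.null(p$grad)) p$grad <- lapply(p$grad, function(g) g * 0)
  invisible(net)
}
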