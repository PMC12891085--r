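# Feature-processing blocks: the spatial reconstruction convolution unit
# (SRCU), the channel reconstruction convolution unit (CRCU), their
# composition SCRConv, and the parameter-free SimAM attention mechanism.
#
# All functions operate on plain 4-D arrays dim (N, C, H, W).

#' Configuration for the spatial reconstruction convolution unit
#'
#' The SRCU normalizes the input with group normalization, derives a
#' per-position informativeness weight from the (normalized) per-channel
#' scale parameters gamma, and splits the input into an informative part and
#' a redundant part with a hard complementary gate, which are then
#' cross-reconstructed.
#'
#' @param channels number of input channels C.
#' @param gn_groups number of group-normalization groups; must divide
#'   `channels`. Default: 16 when 16 divides C, otherwise the largest divisor
#'   of C not exceeding 16 (so C itself when C < 16).
#' @param gate_threshold gate threshold on the sigmoid weights, in (0,1).
#' @param gamma,beta per-channel affine scale and shift (length C).
#' @param epsilon small positive stabilizer for the normalization.
#' @return an object of class `srcu_config`.
#' @export
srcu_config <- function(channels, gn_groups = NULL, gate_threshold = 0.5,
                        gamma = NULL, beta = NULL, epsilon = 1e-5) {
  channels <- as.integer(channels)
  stopifnot(channels >= 1L, epsilon > 0,
            gate_threshold > 0, gate_threshold < 1)
  if (is.null(gn_groups)) gn_groups <- largest_divisor_leq(channels, 16L)
  gn_groups <- as.integer(gn_groups)
  if (channels %% gn_groups != 0L)
    stop("gn_groups must divide the channel count")
  gamma <- gamma %||% rep(1, channels)
  beta <- beta %||% rep(0, channels)
  if (length(gamma) != channels || length(beta) != channels)
    stop("gamma and beta must have length equal to the channel count")
  structure(list(channels = channels, gn_groups = gn_groups,
                 gate_threshold = gate_threshold, gamma = gamma,
                 beta = beta, epsilon = epsilon),
            class = "srcu_config")
}

#' Group normalization
#'
#' Normalizes each (sample, group) slice of the input to zero mean and unit
#' variance over its channels and spatial positions, then applies the
#' per-channel affine transform gamma, beta.
#'
#' @param x feature map array (N, C, H, W).
#' @param cfg an [srcu_config()] whose `gn_groups` divides `dim(x)[2]`.
#' @return normalized feature map, same shape as `x`.
#' @export
group_normalize <- function(x, cfg) {
  check_feature_map(x)
  d <- dim(x)
  C <- d[2]
  if (cfg$channels != C) stop("config channel count does not match input")
  g <- cfg$gn_groups
  cg <- C %/% g
  # reshape to (N, g, cg*H*W) statistics
  out <- x
  for (gi in seq_len(g)) {
    ch <- ((gi - 1L) * cg + 1L):(gi * cg)
    sl <- x[, ch, , , drop = FALSE]
    for (n in seq_len(d[1])) {
      v <- sl[n, , , , drop = FALSE]
      mu <- mean(v)
      s2 <- mean((v - mu)^2)     # population variance
      out[n, ch, , ] <- (v - mu) / sqrt(s2 + cfg$epsilon)
    }
  }
  out <- channel_scale(out, cfg$gamma)
  out + array(rep(cfg$beta, each = d[1]), dim = d)
}

#' SRCU informativeness gate
#'
#' Computes the per-position informative/redundant masks. The per-channel
#' correlation weight is the normalized affine scale, `gamma_i / sum(gamma)`;
#' the group-normalized input is reweighted by it, squashed through a sigmoid
#' per position, and hard-thresholded: positions with weight at or above the
#' gate threshold form the informative mask W1, the rest W2 = 1 - W1.
#'
#' @inheritParams group_normalize
#' @return a list with binary arrays `W1`, `W2` (shape of `x`) and the
#'   pre-threshold sigmoid weights `w`.
#' @export
srcu_gate_weights <- function(x, cfg) {
  check_feature_map(x)
  if (sum(cfg$gamma) == 0)
    stop("degenerate affine: sum of gamma is zero")
  gn <- group_normalize(x, cfg)
  w_gamma <- cfg$gamma / sum(cfg$gamma)
  w <- sigmoid(channel_scale(gn, w_gamma))
  W1 <- (w >= cfg$gate_threshold) * 1
  list(W1 = W1, W2 = 1 - W1, w = w, w_gamma = w_gamma)
}

#' SRCU cross-reconstruction
#'
#' Splits each weighted feature into channel halves and cross-adds them:
#' the first half of `x1w` plus the second half of `x2w`, and the first half
#' of `x2w` plus the second half of `x1w`, concatenated back along channels.
#' Addition conserves the total activation mass.
#'
#' @param x1w,x2w weighted feature maps of identical shape with an even
#'   channel count.
#' @return reconstructed feature map, same shape as the inputs.
#' @export
srcu_reconstruct <- function(x1w, x2w) {
  check_feature_map(x1w)
  if (!identical(dim(x1w), dim(x2w))) stop("inputs must share a shape")
  C <- dim(x1w)[2]
  if (C %% 2L != 0L) stop("cross-reconstruction needs an even channel count")
  h <- C %/% 2L
  a <- seq_len(h); b <- h + seq_len(h)
  out <- x1w
  out[, a, , ] <- x1w[, a, , , drop = FALSE] + x2w[, b, , , drop = FALSE]
  out[, b, , ] <- x2w[, a, , , drop = FALSE] + x1w[, b, , , drop = FALSE]
  out
}

#' SRCU forward pass
#'
#' Gate, multiply, cross-reconstruct. Because the hard gate is complementary
#' (W1 + W2 = 1) and reconstruction is additive, the sum over all elements of
#' the output equals the sum over the input, and the unit is the identity when
#' every position is gated informative.
#'
#' @inheritParams group_normalize
#' @return spatially refined feature map, same shape as `x`.
#' @export
srcu_forward <- function(x, cfg) {
  g <- srcu_gate_weights(x, cfg)
  srcu_reconstruct(g$W1 * x, g$W2 * x)
}

#' Configuration (and weights) for the channel reconstruction convolution unit
#'
#' The CRCU splits its input into an upper part (fraction `alpha` of the
#' channels) and a lower part, squeezes each with a 1x1 convolution by
#' `squeeze_ratio`, transforms the upper part with a group-wise k x k
#' convolution (GWC) plus a point-wise 1x1 convolution (PWC) summed to a
#' C-channel feature, completes the lower part to C channels by concatenating
#' a cheap PWC output with the squeezed lower feature itself, and fuses the
#' two C-channel candidates with channel soft attention.
#'
#' @param channels number of input channels C.
#' @param alpha upper-split ratio in (0,1).
#' @param squeeze_ratio channel squeeze ratio r (integer >= 1).
#' @param gwc_groups requested group count g for the GWC; automatically
#'   reduced to the largest feasible divisor of both operand channel counts.
#' @param kernel odd GWC kernel size k.
#' @param init weight initialization: `"kaiming"` (scaled Gaussian) or
#'   `"zero"`.
#' @param seed optional seed so that random initialization is reproducible.
#' @return an object of class `crcu_config` carrying the derived channel
#'   bookkeeping and the weight arrays `sq_up`, `sq_low`, `gwc`, `pwc1`,
#'   `pwc2` (conv layout: out, in/groups, k, k).
#' @export
crcu_config <- function(channels, alpha = 0.5, squeeze_ratio = 2L,
                        gwc_groups = 2L, kernel = 3L,
                        init = c("kaiming", "zero"), seed = NULL) {
  init <- match.arg(init)
  C <- as.integer(channels)
  stopifnot(C >= 2L, alpha > 0, alpha < 1, squeeze_ratio >= 1,
            kernel %% 2L == 1L)
  up <- as.integer(round(alpha * C))
  lo <- C - up
  if (up < 1L || lo < 1L) stop("alpha split leaves an empty branch")
  up_s <- max(1L, as.integer(round(up / squeeze_ratio)))
  lo_s <- max(1L, as.integer(round(lo / squeeze_ratio)))
  pwc2_out <- C - lo_s
  if (pwc2_out < 1L)
    stop("channel bookkeeping cannot reach C output channels")
  g <- largest_divisor_leq(gcd2(up_s, C), as.integer(gwc_groups))
  mk <- function(o, i, k) {
    w <- if (init == "zero") array(0, c(o, i, k, k)) else
      array(rnorm(o * i * k * k, sd = sqrt(2 / (i * k * k))), c(o, i, k, k))
    w
  }
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  structure(list(channels = C, alpha = alpha, squeeze_ratio = squeeze_ratio,
                 gwc_groups = g, kernel = as.integer(kernel),
                 up = up, lo = lo, up_s = up_s, lo_s = lo_s,
                 pwc2_out = pwc2_out,
                 sq_up = mk(up_s, up, 1L),
                 sq_low = mk(lo_s, lo, 1L),
                 gwc = mk(C, up_s %/% g, kernel),
                 pwc1 = mk(C, up_s, 1L),
                 pwc2 = mk(pwc2_out, lo_s, 1L)),
            class = "crcu_config")
}

gcd2 <- function(a, b) if (b == 0L) a else Recall(b, a %% b)

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Channel soft-attention fusion
#'
#' Pools both candidates globally over space per channel, converts the two
#' pooled vectors into importance weights with a pairwise softmax
#' (beta1 + beta2 = 1 per channel) and returns the weighted sum.
#'
#' @param y1,y2 feature maps of identical shape.
#' @return fused feature map with attributes `beta1`, `beta2` (N x C
#'   matrices of fusion weights).
#' @export
channel_fuse <- function(y1, y2) {
  check_feature_map(y1)
  if (!identical(dim(y1), dim(y2))) stop("inputs must share a shape")
  s1 <- channel_stats(y1)$mean      # N x C pooled means
  s2 <- channel_stats(y2)$mean
  m <- pmax(s1, s2)                 # stabilized pairwise softmax
  e1 <- exp(s1 - m); e2 <- exp(s2 - m)
  b1 <- e1 / (e1 + e2); b2 <- e2 / (e1 + e2)
  out <- channel_scale(y1, b1) + channel_scale(y2, b2)
  attr(out, "beta1") <- b1
  attr(out, "beta2") <- b2
  out
}

#' CRCU forward pass
#'
#' @param xw feature map array (N, C, H, W), typically the spatially refined
#'   output of [srcu_forward()].
#' @param cfg a [crcu_config()] for `C = dim(xw)[2]` channels.
#' @return channel-refined feature map, same shape as `xw`.
#' @export
crcu_forward <- function(xw, cfg) {
  check_feature_map(xw)
  C <- dim(xw)[2]
  if (cfg$channels != C) stop("config channel count does not match input")
  x_up <- xw[, seq_len(cfg$up), , , drop = FALSE]
  x_lo <- xw[, cfg$up + seq_len(cfg$lo), , , drop = FALSE]
  up_s <- .conv2d_fw(x_up, cfg$sq_up, NULL, 1L, 0L, 1L)
  lo_s <- .conv2d_fw(x_lo, cfg$sq_low, NULL, 1L, 0L, 1L)
  pad <- (cfg$kernel - 1L) %/% 2L
  y1 <- .conv2d_fw(up_s, cfg$gwc, NULL, 1L, pad, cfg$gwc_groups) +
    .conv2d_fw(up_s, cfg$pwc1, NULL, 1L, 0L, 1L)
  y2a <- .conv2d_fw(lo_s, cfg$pwc2, NULL, 1L, 0L, 1L)
  d <- dim(xw)
  y2 <- array(0, d)
  y2[, seq_len(cfg$pwc2_out), , ] <- y2a
  y2[, cfg$pwc2_out + seq_len(cfg$lo_s), , ] <- lo_s
  channel_fuse(y1, y2)
}

#' SCRConv forward pass
#'
#' Sequential composition of the spatial reconstruction unit and the channel
#' reconstruction unit; channel- and resolution-preserving, a drop-in
#' replacement for a stride-1 3x3 convolution.
#'
#' @param x feature map array (N, C, H, W).
#' @param srcu an [srcu_config()].
#' @param crcu a [crcu_config()].
#' @return refined feature map, same shape as `x`.
#' @export
scrconv_forward <- function(x, srcu, crcu) {
  crcu_forward(srcu_forward(x, srcu), crcu)
}

#' SimAM configuration
#'
#' @param lam nonnegative regularization strength lambda of the energy
#'   function.
#' @return an object of class `simam_config`.
#' @export
simam_config <- function(lam = 1e-4) {
  stopifnot(is.numeric(lam), lam >= 0)
  structure(list(lam = lam), class = "simam_config")
}

#' Minimal per-neuron energy map
#'
#' For every activation t the minimal value of the linear-separability energy
#' has the closed form `e* = 4(s2 + lam) / ((t - mu)^2 + 2 s2 + 2 lam)`,
#' where mu and s2 are the mean and (population) variance of the channel.
#' With `stats = "pooled"` the statistics include the target neuron (the
#' shortcut that avoids recomputing leave-one-out statistics per neuron);
#' `stats = "exclusive"` uses the leave-one-out statistics of the literal
#' binary-label energy.
#'
#' @param x feature map array (N, C, H, W) with at least 2 spatial positions.
#' @param lam nonnegative regularization lambda.
#' @param stats statistics convention, `"pooled"` (default) or
#'   `"exclusive"`.
#' @return array of minimal energies, same shape as `x`; all entries are
#'   strictly positive when `lam > 0`.
#' @export
simam_energy <- function(x, lam = 1e-4, stats = c("pooled", "exclusive")) {
  stats <- match.arg(stats)
  check_feature_map(x)
  d <- dim(x)
  M <- d[3] * d[4]
  if (M < 2L) stop("SimAM needs at least 2 neurons per channel")
  st <- channel_stats(x)
  if (stats == "pooled") {
    mu <- channel_scale(array(1, d), st$mean)
    v <- channel_scale(array(1, d), st$var)
  } else {
    # leave-one-out mean/variance per position
    mu_all <- channel_scale(array(1, d), st$mean)
    ex2 <- channel_scale(array(1, d), st$var + st$mean^2)
    mu <- (M * mu_all - x) / (M - 1)
    v <- pmax((M * ex2 - x^2) / (M - 1) - mu^2, 0)
  }
  4 * (v + lam) / ((x - mu)^2 + 2 * v + 2 * lam)
}

#' SimAM forward pass
#'
#' Rescales every activation by `sigmoid(1/e*)`, where `e*` is its minimal
#' energy ([simam_energy()], pooled statistics). Lower energy marks a neuron
#' as more distinctive, hence a larger weight. The module adds no learnable
#' parameters.
#'
#' @param x feature map array (N, C, H, W), `H*W >= 2`.
#' @param cfg a [simam_config()].
#' @return attended feature map, same shape as `x`; the attention weights
#'   used are attached as attribute `"weights"` and lie strictly in (0, 1).
#' @export
simam_forward <- function(x, cfg = simam_config()) {
  e <- simam_energy(x, cfg$lam, stats = "pooled")
  w <- sigmoid(1 / e)
  out <- w * x
  attr(out, "weights") <- w
  out
}

#' Numeric oracle for the SimAM energy minimum
#'
#' Minimizes the binary-label energy of one channel numerically over the
#' neuron's linear transform (w_t, b_t) — a coarse grid search refined by
#' quasi-Newton iterations — and returns the minimum. Used to verify the
#' closed form in [simam_energy()]; independent of it.
#'
#' With `convention = "pooled"` the target neuron is also included among the
#' -1-labelled neighbours (so both terms share the full-channel mean — the
#' same shortcut the closed form uses); `"exclusive"` uses only the other
#' M - 1 neurons, each form matching the corresponding closed-form statistics.
#'
#' @param channel numeric vector of the M channel activations (M >= 2).
#' @param t_index index of the target neuron in `channel`.
#' @param lam nonnegative regularization lambda.
#' @param convention `"pooled"` (default) or `"exclusive"`.
#' @return the numerically minimized energy (a scalar).
#' @export
simam_oracle <- function(channel, t_index, lam,
                         convention = c("pooled", "exclusive")) {
  convention <- match.arg(convention)
  M <- length(channel)
  stopifnot(M >= 2L, t_index >= 1L, t_index <= M, lam >= 0)
  t <- channel[t_index]
  others <- if (convention == "pooled") channel else channel[-t_index]
  obj <- function(p) {
    w <- p[1]; b <- p[2]
    mean((-1 - (w * others + b))^2) + (1 - (w * t + b))^2 + lam * w^2
  }
  # coarse grid, then local refinement
  grid <- expand.grid(w = seq(-4, 4, length.out = 17),
                      b = seq(-4, 4, length.out = 17))
  vals <- apply(grid, 1L, obj)
  best <- as.numeric(grid[which.min(vals), ])
  fit <- optim(best, obj, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                control = list(reltol = 1e-15, maxit = 2000))
  if (!is.finite(fit2$value)) stop("oracle failed to converge")
  min(fit$value, fit2$value)
}
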