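# Internal numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

# d/dx silu(x)
silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

#' Validate a feature map array
#'
#' A feature map is a 4-D numeric array with dimensions
#' (batch N, channels C, height H, width W); all dimensions must be at least
#' one and all values finite.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @export
check_feature_map <- function(x) {
  if (!is.numeric(x) || length(dim(x)) != 4L)
    stop("feature map must be a 4-D numeric array (N, C, H, W)")
  if (any(dim(x) < 1L)) stop("all feature-map dimensions must be >= 1")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

# Per-channel broadcast multiply: x (N,C,H,W) * v (length C or N x C matrix).
channel_scale <- function(x, v) {
  d <- dim(x)
  if (is.matrix(v)) {
    # N x C
    arr <- array(rep(as.vector(v), times = d[3] * d[4]), dim = d)
  } else {
    arr <- array(rep(v, each = d[1]), dim = d)
  }
  x * arr
}

# Per-channel statistics over the spatial dims: returns N x C matrices.
channel_stats <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])           # (N*C) x (H*W)
  mu <- rowMeans(m)
  v <- rowMeans(m * m) - mu^2
  list(mean = matrix(mu, d[1], d[2]), var = matrix(pmax(v, 0), d[1], d[2]))
}

# Largest divisor of n that is <= k (k >= 1).
largest_divisor_leq <- function(n, k) {
  for (d in seq(min(n, k), 1L)) if (n %% d == 0L) return(as.integer(d))
  1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
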