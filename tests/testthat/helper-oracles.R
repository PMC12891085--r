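# Independent oracles used to verify the analytic implementations.

# Rasterization oracle for IoU: boxes are discretized on a lattice of cell
# size h (cells counted by their centers); intersection and union are cell
# counts. Independent of the closed-form area arithmetic.
raster_iou <- function(a, b, h = 0.002) {
  count_1d <- function(lo, hi) {
    # number of k >= 0 with lo <= (k + 0.5) * h < hi
    max(0L, floor(hi / h - 0.5) - ceiling(lo / h - 0.5) + 1L)
  }
  cells <- function(bx) count_1d(bx[1], bx[3]) * count_1d(bx[2], bx[4])
  ib <- c(max(a[1], b[1]), max(a[2], b[2]), min(a[3], b[3]), min(a[4], b[4]))
  ni <- if (ib[3] > ib[1] && ib[4] > ib[2]) cells(ib) else 0L
  na <- cells(a); nb <- cells(b)
  ni / (na + nb - ni)
}

# Quadratic-time all-point AP: explicit precision envelope by scanning all
# operating points, independent of the cummax/cumsum implementation.
oracle_ap <- function(flags, n_gt) {
  if (n_gt == 0L || !length(flags)) return(0)
  n <- length(flags)
  area <- 0
  r_prev <- 0
  for (k in seq_len(n)) {
    tp <- sum(flags[seq_len(k)])
    r <- tp / n_gt
    if (r > r_prev) {
      # envelope: best precision at any cut with recall >= r
      pbest <- 0
      for (j in k:n) {
        tpj <- sum(flags[seq_len(j)])
        if (tpj / n_gt >= r) pbest <- max(pbest, tpj / j)
      }
      area <- area + (r - r_prev) * pbest
      r_prev <- r
    }
  }
  area
}

# Independent greedy matcher + AP on a list of single-class scenes
# (each: list(dets = data.frame, gts = data.frame)).
oracle_scene_ap <- function(scenes, iou_thr = 0.5) {
  conf <- numeric(0); tp <- logical(0); n_gt <- 0L
  for (sc in scenes) {
    d <- sc$dets[order(-sc$dets$confidence), , drop = FALSE]
    used <- rep(FALSE, nrow(sc$gts))
    for (i in seq_len(nrow(d))) {
      best <- -1; bj <- 0L
      for (j in seq_len(nrow(sc$gts))) {
        if (used[j]) next
        v <- iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                 as.numeric(sc$gts[j, c("x1", "y1", "x2", "y2")]))
        if (v > best) { best <- v; bj <- j }
      }
      hit <- bj > 0L && best >= iou_thr
      if (hit) used[bj] <- TRUE
      conf <- c(conf, d$confidence[i]); tp <- c(tp, hit)
    }
    n_gt <- n_gt + nrow(sc$gts)
  }
  o <- order(-conf)
  oracle_ap(tp[o], n_gt)
}

rand_box <- function(lim = 16, min_side = 1) {
  x1 <- runif(1, 0, lim - min_side); y1 <- runif(1, 0, lim - min_side)
  c(x1, y1, x1 + runif(1, min_side, lim - x1),
    y1 + runif(1, min_side, lim - y1))
}

# small feature map filled with reproducible noise
rand_fmap <- function(n, c, h, w, sd = 1) array(rnorm(n * c * h * w, sd = sd),
                                                c(n, c, h, w))
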