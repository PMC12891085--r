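# Training: anchor-free decoding, task-aligned assignment, the composite
# detection loss (box + classification + distribution-focal terms) with
# analytic gradients into the raw head outputs, and a small optimizer.

# Anchor metadata for a set of head output shapes.
anchor_table <- function(head_dims, strides) {
  tabs <- lapply(seq_along(head_dims), function(i) {
    H <- head_dims[[i]][3]; W <- head_dims[[i]][4]
    j <- seq_len(H * W)
    gy <- (j - 1L) %% H
    gx <- (j - 1L) %/% H
    data.frame(scale = i, j = j,
               ax = (gx + 0.5) * strides[i], ay = (gy + 0.5) * strides[i],
               stride = strides[i])
  })
  do.call(rbind, tabs)
}

# Per-image flattening of raw head outputs: A x (4R + nc) matrix in the
# anchor order of anchor_table.
flatten_image_preds <- function(preds, n) {
  do.call(rbind, lapply(preds, function(p) {
    d <- dim(p)
    t(matrix(p[n, , , ], nrow = d[2]))
  }))
}

# softmax rows of an A x R matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Decode distances and boxes from the flattened logits.
decode_boxes <- function(m, anch, reg_bins, nc) {
  R <- reg_bins
  v <- 0:(R - 1)
  dist <- matrix(0, nrow(m), 4)
  probs <- vector("list", 4)
  for (s in 1:4) {
    p <- softmax_rows(m[, (s - 1) * R + seq_len(R), drop = FALSE])
    probs[[s]] <- p
    dist[, s] <- as.vector(p %*% v) * anch$stride
  }
  boxes <- cbind(anch$ax - dist[, 1], anch$ay - dist[, 2],
                 anch$ax + dist[, 3], anch$ay + dist[, 4])
  cls <- sigmoid(m[, 4 * R + seq_len(nc), drop = FALSE])
  list(dist = dist, boxes = boxes, cls = cls, probs = probs)
}

# Task-aligned assignment of ground truths to anchors (no gradient).
# Returns assigned anchor indices, their gt index, and the target score.
assign_targets <- function(boxes, cls, gt, anch, topk = 10L,
                           alpha = 0.5, beta = 6.0) {
  G <- nrow(gt)
  A <- nrow(anch)
  if (G == 0L)
    return(list(idx = integer(0), gt = integer(0), score = numeric(0)))
  align <- matrix(0, A, G)
  iou_m <- matrix(0, A, G)
  for (g in seq_len(G)) {
    inb <- anch$ax > gt$x1[g] & anch$ax < gt$x2[g] &
      anch$ay > gt$y1[g] & anch$ay < gt$y2[g]
    if (!any(inb)) next
    ii <- which(inb)
    gb <- matrix(c(gt$x1[g], gt$y1[g], gt$x2[g], gt$y2[g]),
                 length(ii), 4, byrow = TRUE)
    iv <- iou(gb, boxes[ii, , drop = FALSE])
    iou_m[ii, g] <- iv
    align[ii, g] <- cls[ii, gt$class_id[g] + 1L]^alpha * iv^beta
  }
  mask <- matrix(FALSE, A, G)
  for (g in seq_len(G)) {
    cand <- which(align[, g] > 0)
    if (!length(cand)) next
    top <- cand[order(-align[cand, g])][seq_len(min(topk, length(cand)))]
    mask[top, g] <- TRUE
  }
  # resolve anchors claimed by several gts: keep the highest-IoU gt
  amb <- which(rowSums(mask) > 1L)
  for (a in amb) {
    gbest <- which.max(ifelse(mask[a, ], iou_m[a, ], -1))
    mask[a, ] <- FALSE
    mask[a, gbest] <- TRUE
  }
  idx <- integer(0); gtv <- integer(0); score <- numeric(0)
  for (g in seq_len(G)) {
    aa <- which(mask[, g])
    if (!length(aa)) next
    mal <- max(align[aa, g])
    mio <- max(iou_m[aa, g])
    sc <- align[aa, g] * mio / (mal + 1e-9)
    idx <- c(idx, aa); gtv <- c(gtv, rep(g, length(aa)))
    score <- c(score, sc)
  }
  list(idx = idx, gt = gtv, score = score)
}

#' Composite detection loss
#'
#' Assembles the anchor-free detection loss from assigned prediction-target
#' pairs: the box term uses the configured IoU-based regression loss (MPDIoU
#' or the CIoU reference), the classification term is per-class binary
#' cross-entropy against the task-aligned target scores, and the
#' distribution-focal term supervises the discretized box-edge
#' distributions. The total is the weighted sum.
#'
#' @param preds list of raw per-scale head outputs (N, 4*reg_bins+nc, H, W).
#' @param targets list (length N) of annotation data frames.
#' @param weights list or vector with `box`, `cls`, `dfl` weights.
#' @param extent image extent `c(w, h)` in pixels.
#' @param strides head strides, default `c(8, 16, 32)`.
#' @param nc number of classes.
#' @param reg_bins distribution-focal bins per side.
#' @param loss_type `"mpdiou"` or `"ciou"` for the box term.
#' @param with_grad if TRUE, analytic gradients w.r.t. the raw head outputs
#'   are returned under `$dhead`.
#' @return list with `total`, `box`, `cls`, `dfl` (per-image means of the
#'   weighted terms) and optionally `dhead`.
#' @export
detection_loss <- function(preds, targets, weights = list(box = 7.5,
                                                          cls = 0.5,
                                                          dfl = 1.5),
                           extent, strides = c(8, 16, 32),
                           nc = 3L, reg_bins = 16L,
                           loss_type = c("mpdiou", "ciou"),
                           with_grad = FALSE) {
  loss_type <- match.arg(loss_type)
  weights <- as.list(weights)
  R <- reg_bins
  N <- dim(preds[[1]])[1]
  head_dims <- lapply(preds, dim)
  anch <- anchor_table(head_dims, strides)
  A <- nrow(anch)
  v <- 0:(R - 1)
  loss_box <- loss_cls <- loss_dfl <- 0
  dhead <- if (with_grad)
    lapply(preds, function(p) array(0, dim(p))) else NULL
  for (n in seq_len(N)) {
    m <- flatten_image_preds(preds, n)
    dec <- decode_boxes(m, anch, R, nc)
    gt <- targets[[n]]
    asg <- assign_targets(dec$boxes, dec$cls, gt, anch)
    Tm <- matrix(0, A, nc)
    if (length(asg$idx))
      Tm[cbind(asg$idx, gt$class_id[asg$gt] + 1L)] <- asg$score
    tsum <- max(sum(Tm), 1)
    # classification: BCE over all anchors and classes
    p <- dec$cls
    eps <- 1e-9
    loss_cls_n <- sum(-Tm * log(p + eps) - (1 - Tm) * log(1 - p + eps)) /
      tsum
    dm <- if (with_grad) matrix(0, A, 4 * R + nc) else NULL
    if (with_grad)
      dm[, 4 * R + seq_len(nc)] <- (p - Tm) * weights$cls / tsum *
        p_sig_identity()
    loss_box_n <- 0; loss_dfl_n <- 0
    if (length(asg$idx)) {
      ai <- asg$idx
      gb <- as.matrix(gt[asg$gt, c("x1", "y1", "x2", "y2")])
      pb <- dec$boxes[ai, , drop = FALSE]
      w_a <- asg$score
      if (loss_type == "mpdiou") {
        lb <- 1 - mpdiou(gb, pb, extent)
        gcoord <- -mpdiou_grad_pred(gb, pb, extent)
      } else {
        lb <- 1 - ciou(gb, pb)
        gcoord <- -ciou_grad_pred(gb, pb)
      }
      loss_box_n <- sum(w_a * lb) / tsum
      # distribution-focal targets in stride units
      st <- anch$stride[ai]
      tdist <- cbind((anch$ax[ai] - gb[, 1]) / st,
                     (anch$ay[ai] - gb[, 2]) / st,
                     (gb[, 3] - anch$ax[ai]) / st,
                     (gb[, 4] - anch$ay[ai]) / st)
      tdist <- pmin(pmax(tdist, 0), R - 1 - 1e-3)
      fl <- floor(tdist)
      wr <- tdist - fl
      dfl_n <- 0
      for (s in 1:4) {
        ps <- dec$probs[[s]][ai, , drop = FALSE]
        pf <- ps[cbind(seq_along(ai), fl[, s] + 1L)]
        pc <- ps[cbind(seq_along(ai), pmin(fl[, s] + 2L, R))]
        dfl_n <- dfl_n +
          sum(w_a * (-(1 - wr[, s]) * log(pf + eps) -
                       wr[, s] * log(pc + eps))) / 4
        if (with_grad) {
          two <- matrix(0, length(ai), R)
          two[cbind(seq_along(ai), fl[, s] + 1L)] <-
            two[cbind(seq_along(ai), fl[, s] + 1L)] + (1 - wr[, s])
          two[cbind(seq_along(ai), pmin(fl[, s] + 2L, R))] <-
            two[cbind(seq_along(ai), pmin(fl[, s] + 2L, R))] + wr[, s]
          dz_dfl <- (ps - two) * w_a * weights$dfl / (4 * tsum)
          # box-term gradient through the softmax expectation
          dcoord_s <- switch(s, -gcoord[, 1], -gcoord[, 2],
                             gcoord[, 3], gcoord[, 4])
          ev <- as.vector(ps %*% v)
          dz_box <- ps * (matrix(v, length(ai), R, byrow = TRUE) - ev) *
            (dcoord_s * st * w_a * weights$box / tsum)
          dm[ai, (s - 1) * R + seq_len(R)] <-
            dm[ai, (s - 1) * R + seq_len(R)] + dz_dfl + dz_box
        }
      }
      loss_dfl_n <- dfl_n / tsum
    }
    loss_box <- loss_box + loss_box_n / N
    loss_cls <- loss_cls + loss_cls_n / N
    loss_dfl <- loss_dfl + loss_dfl_n / N
    if (with_grad) {
      # classification gradient must pass through the sigmoid: d z = p - T
      # (already in dm); scatter flattened rows back into the head arrays
      off <- 0L
      for (i in seq_along(preds)) {
        d <- head_dims[[i]]
        HW <- d[3] * d[4]
        rows <- off + seq_len(HW)
        dhead[[i]][n, , , ] <- dhead[[i]][n, , , ] +
          array(t(dm[rows, , drop = FALSE]) / N, c(d[2], d[3], d[4]))
        off <- off + HW
      }
    }
  }
  out <- list(total = weights$box * loss_box + weights$cls * loss_cls +
                weights$dfl * loss_dfl,
              box = loss_box, cls = loss_cls, dfl = loss_dfl)
  if (with_grad) out$dhead <- dhead
  out
}

# The BCE gradient w.r.t. the logit is sigmoid(z) - target; dec$cls is
# already the sigmoid, so the factor is exactly 1. Kept as a named constant
# for readability at the call site.
p_sig_identity <- function() 1

make_optimizer <- function(net, type = c("sgd", "adam"), lr = 0.01,
                           momentum = 0.937, weight_decay = 5e-4) {
  type <- match.arg(type)
  st <- lapply(net$prims, function(p)
    lapply(p$par, function(w) list(m = w * 0, v = w * 0)))
  t_step <- 0L
  list(
    step = function(lr_now = lr) {
      t_step <<- t_step + 1L
      for (i in seq_along(net$prims)) {
        p <- net$prims[[i]]
        if (is.null(p$grad)) next
        for (nm in names(p$par)) {
          g <- p$grad[[nm]]
          if (nm == "w" && weight_decay > 0)
            g <- g + weight_decay * p$par[[nm]]
          if (type == "sgd") {
            st[[i]][[nm]]$m <<- momentum * st[[i]][[nm]]$m + g
            p$par[[nm]] <- p$par[[nm]] - lr_now * st[[i]][[nm]]$m
          } else {
            st[[i]][[nm]]$m <<- 0.9 * st[[i]][[nm]]$m + 0.1 * g
            st[[i]][[nm]]$v <<- 0.999 * st[[i]][[nm]]$v + 0.001 * g^2
            mh <- st[[i]][[nm]]$m / (1 - 0.9^t_step)
            vh <- st[[i]][[nm]]$v / (1 - 0.999^t_step)
            p$par[[nm]] <- p$par[[nm]] - lr_now * mh / (sqrt(vh) + 1e-8)
          }
        }
      }
    })
}

samples_to_batch <- function(samples) {
  S1 <- dim(samples[[1]]$image)[1]; S2 <- dim(samples[[1]]$image)[2]
  x <- array(0, c(length(samples), 3L, S1, S2))
  for (i in seq_along(samples))
    x[i, , , ] <- aperm(samples[[i]]$image, c(3, 1, 2))
  x
}

#' Fit a detector to a set of annotated images
#'
#' Desk-scale training loop: mini-batch gradient descent on the composite
#' detection loss of the instantiated graph, with optional mosaic
#' augmentation (applied to every draw except during the final 10 epochs).
#' Deterministic under `seed` up to floating-point reassociation.
#'
#' @param graph a `model_graph` (the graph's `loss` field selects MPDIoU or
#'   CIoU box regression).
#' @param data list of samples, each a list with `image` (H x W x 3 array in
#'   `[0,1]`) and `annotations` (data frame `class_id`, `x1`, `y1`, `x2`,
#'   `y2`).
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr learning rate (Adam).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param momentum SGD momentum (ignored for Adam).
#' @param weight_decay L2 penalty on convolution weights.
#' @param mosaic logical, enable 4-image mosaic augmentation.
#' @param loss_weights list with `box`, `cls`, `dfl` term weights.
#' @param seed integer seed (weights, shuffling, augmentation).
#' @param schedule_epochs horizon of the cosine learning-rate decay
#'   (defaults to `epochs`); set it to the horizon of a longer reference
#'   run to train a shorter, epoch-for-epoch comparable companion run.
#' @param verbose print per-epoch losses.
#' @return an object of class `trdnet_fit` with the trained network, the
#'   per-epoch loss `history`, and the resolved configuration.
#' @export
trdnet_fit <- function(graph, data, epochs = 30L, batch_size = 8L,
                       lr = 2e-3, optimizer = "adam", momentum = 0.937,
                       weight_decay = 1e-4, mosaic = FALSE,
                       loss_weights = list(box = 7.5, cls = 0.5, dfl = 1.5),
                       seed = 0L, schedule_epochs = epochs,
                       verbose = FALSE) {
  stopifnot(inherits(graph, "model_graph"), length(data) >= 1L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  net <- instantiate_network(graph, seed = seed)
  opt <- make_optimizer(net, optimizer, lr, momentum, weight_decay)
  S <- dim(data[[1]]$image)[1]
  hist <- data.frame()
  nb <- ceiling(length(data) / batch_size)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(data))
    ep_loss <- c(total = 0, box = 0, cls = 0, dfl = 0)
    # cosine decay to a tenth of the initial rate
    lr_ep <- lr * (0.1 + 0.45 *
                     (1 + cos(pi * (ep - 1) / max(schedule_epochs, 1))))
    use_mosaic <- mosaic && ep <= max(0L, epochs - 10L)
    for (b in seq_len(nb)) {
      take <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size,
                                                   length(data))]
      batch <- data[take]
      if (use_mosaic) {
        batch <- lapply(batch, function(s) {
          picks <- c(list(s), data[sample(length(data), 3L)])
          mosaic4(picks, out_size = S,
                  seed = sample.int(.Machine$integer.max, 1L))
        })
      }
      x <- samples_to_batch(batch)
      fwd <- network_forward(net, x, train = TRUE)
      ls <- detection_loss(fwd$head,
                           lapply(batch, `[[`, "annotations"),
                           weights = loss_weights, extent = c(S, S),
                           strides = c(8, 16, 32), nc = graph$nc,
                           reg_bins = graph$reg_bins,
                           loss_type = graph$loss, with_grad = TRUE)
      zero_grads(net)
      network_backward(net, ls$dhead)
      opt$step(lr_ep)
      w <- length(take) / length(data)
      ep_loss <- ep_loss + w * c(ls$total, ls$box, ls$cls, ls$dfl)
    }
    hist <- rbind(hist, data.frame(epoch = ep, t(ep_loss)))
    if (verbose)
      message(sprintf("epoch %d  total %.4f  box %.4f  cls %.4f  dfl %.4f",
                      ep, ep_loss["total"], ep_loss["box"],
                      ep_loss["cls"], ep_loss["dfl"]))
  }
  structure(list(network = net, graph = graph, history = hist,
                 config = list(epochs = epochs, batch_size = batch_size,
                               lr = lr, optimizer = optimizer,
                               momentum = momentum,
                               weight_decay = weight_decay,
                               mosaic = mosaic, loss_weights = loss_weights,
                               seed = seed, image_size = S)),
            class = "trdnet_fit")
}

#' Predict detections for images
#'
#' Runs the trained network on one image (H x W x 3 array) or a list of
#' images, decodes the distribution-focal boxes, filters by confidence, and
#' applies class-wise non-maximum suppression.
#'
#' @param object a `trdnet_fit`.
#' @param newdata image array or list of image arrays.
#' @param conf_thr confidence threshold.
#' @param iou_thr NMS IoU threshold.
#' @param max_det maximum detections per image.
#' @param ... unused.
#' @return a detection data frame (single image) or list of them.
#' @export
predict.trdnet_fit <- function(object, newdata, conf_thr = 0.25,
                               iou_thr = 0.7, max_det = 100L, ...) {
  single <- is.array(newdata) && length(dim(newdata)) == 3L
  imgs <- if (single) list(newdata) else newdata
  res <- lapply(imgs, function(img) {
    x <- array(0, c(1L, 3L, dim(img)[1], dim(img)[2]))
    x[1, , , ] <- aperm(img, c(3, 1, 2))
    fwd <- network_forward(object$network, x, train = FALSE)
    detect_from_head(fwd$head, object$graph, conf_thr, iou_thr, max_det)
  })
  if (single) res[[1]] else res
}

detect_from_head <- function(head_out, graph, conf_thr = 0.25,
                             iou_thr = 0.7, max_det = 100L) {
  strides <- c(8, 16, 32)
  anch <- anchor_table(lapply(head_out, dim), strides)
  m <- flatten_image_preds(head_out, 1L)
  dec <- decode_boxes(m, anch, graph$reg_bins, graph$nc)
  conf <- apply(dec$cls, 1L, max)
  cid <- max.col(dec$cls) - 1L
  keep <- which(conf >= conf_thr)
  dets <- data.frame(class_id = cid[keep], confidence = conf[keep],
                     x1 = dec$boxes[keep, 1], y1 = dec$boxes[keep, 2],
                     x2 = dec$boxes[keep, 3], y2 = dec$boxes[keep, 4])
  dets <- dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, , drop = FALSE]
  dets <- nms(dets, iou_thr)
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  head(dets, max_det)
}

#' Evaluate a fitted detector on annotated samples
#'
#' @param fit a `trdnet_fit`.
#' @param samples list of samples (`image`, `annotations`, optional `id`).
#' @param conf_thr detection confidence threshold used for the PR pooling
#'   (kept low so the full PR curve is available to the AP integral).
#' @param nms_thr NMS IoU threshold at evaluation time.
#' @return an `eval_summary`.
#' @export
evaluate_model <- function(fit, samples, conf_thr = 0.01, nms_thr = 0.5) {
  ids <- vapply(seq_along(samples), function(i)
    samples[[i]]$id %||% sprintf("img%04d", i), character(1))
  dets <- predict(fit, lapply(samples, `[[`, "image"), conf_thr = conf_thr,
                  iou_thr = nms_thr)
  names(dets) <- ids
  gts <- setNames(lapply(samples, `[[`, "annotations"), ids)
  evaluate_map50(dets, gts, classes = seq_len(fit$graph$nc) - 1L)
}

#' @export
print.trdnet_fit <- function(x, ...) {
  cat(sprintf("fitted %s detector (%d classes, %d px input)\n",
              x$graph$variant, x$graph$nc, x$config$image_size))
  cat(sprintf("  %.3f M parameters, %d epochs, final total loss %.4f\n",
              count_parameters(x$graph) / 1e6, nrow(x$history),
              tail(x$history$total, 1)))
  invisible(x)
}

#' @export
summary.trdnet_fit <- function(object, ...) {
  print(object)
  cat("\nloss history (last 5 epochs):\n")
  print(tail(object$history, 5), row.names = FALSE)
  cat("\nprofile:\n")
  print(profile_model(object$graph,
                      input_size = 32 * (object$config$image_size %/% 32)))
  invisible(object)
}

#' Plot detections over an image
#'
#' @param x a `trdnet_fit`.
#' @param image H x W x 3 array in `[0,1]`.
#' @param conf_thr confidence threshold.
#' @param ... passed to `predict`.
#' @export
plot.trdnet_fit <- function(x, image, conf_thr = 0.25, ...) {
  dets <- predict(x, image, conf_thr = conf_thr, ...)
  plot_detections(image, dets)
  invisible(dets)
}

#' @rdname plot.trdnet_fit
#' @param dets detection (or annotation) data frame.
#' @export
plot_detections <- function(image, dets) {
  H <- dim(image)[1]; W <- dim(image)[2]
  graphics::plot(c(0, W), c(0, H), type = "n", asp = 1, xlab = "",
                 ylab = "", xaxt = "n", yaxt = "n")
  graphics::rasterImage(image, 0, 0, W, H)
  cols <- c("red", "orange", "pink")
  if (nrow(dets)) {
    for (i in seq_len(nrow(dets))) {
      graphics::rect(dets$x1[i], H - dets$y2[i], dets$x2[i], H - dets$y1[i],
                     border = cols[dets$class_id[i] + 1L], lwd = 2)
      lab <- ripeness_class_names()[dets$class_id[i] + 1L]
      if (!is.null(dets$confidence))
        lab <- sprintf("%s %.2f", lab, dets$confidence[i])
      graphics::text(dets$x1[i], H - dets$y1[i], lab, adj = c(0, -0.3),
                     col = cols[dets$class_id[i] + 1L], cex = 0.7)
    }
  }
  invisible(NULL)
}
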