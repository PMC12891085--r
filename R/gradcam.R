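# Grad-CAM heatmaps: gradient-weighted sums of convolutional feature maps,
# rectified, locating the image regions that drive a class score.

#' Grad-CAM map from activations and gradients
#'
#' Each of the K feature maps is weighted by the spatial mean of the
#' class-score gradient over that map, the weighted maps are summed and
#' rectified. Permuting the feature maps together with their gradients
#' leaves the result unchanged, and scaling the class score scales the
#' pre-ReLU map linearly.
#'
#' @param A activations, array (K, H, W) — or (1, K, H, W).
#' @param dYdA gradients of the class score w.r.t. `A`, same shape.
#' @return H x W nonnegative heatmap matrix.
#' @export
gradcam_map <- function(A, dYdA) {
  if (length(dim(A)) == 4L) {
    A <- array(A[1, , , ], dim(A)[-1])
    dYdA <- array(dYdA[1, , , ], dim(dYdA)[-1])
  }
  if (!identical(dim(A), dim(dYdA))) stop("activation/gradient shape mismatch")
  K <- dim(A)[1]
  alpha <- vapply(seq_len(K), function(k) mean(dYdA[k, , ]), numeric(1))
  m <- matrix(0, dim(A)[2], dim(A)[3])
  for (k in seq_len(K)) m <- m + alpha[k] * A[k, , ]
  pmax(m, 0)
}

#' Grad-CAM heatmaps of a fitted detector
#'
#' Computes the gradient of the maximum class logit (over all head locations
#' and scales) for the target class with respect to the hooked feature maps,
#' and returns one rectified, bilinearly upsampled, max-normalized heatmap
#' per hook. Default hooks are the mid- and deep-neck fusion outputs.
#'
#' @param fit a `trdnet_fit`.
#' @param image H x W x 3 array in `[0, 1]`.
#' @param class_id target ripeness class (0, 1, 2); default: the class of
#'   the most confident prediction.
#' @param layers character vector of graph layer names to hook; default the
#'   mid-neck and last-neck outputs.
#' @return named list of H x W heatmap matrices in `[0, 1]`.
#' @export
grad_cam <- function(fit, image, class_id = NULL, layers = NULL) {
  net <- fit$network
  g <- fit$graph
  names_all <- vapply(g$layers, `[[`, "", "name")
  if (is.null(layers)) {
    layers <- intersect(c("att_n3", "att_n4", "n3", "n4"), names_all)
    layers <- layers[!duplicated(sub("^att_", "", layers))]
  }
  stopifnot(all(layers %in% names_all))
  x <- array(0, c(1L, 3L, dim(image)[1], dim(image)[2]))
  x[1, , , ] <- aperm(image, c(3, 1, 2))
  fwd <- network_forward(net, x, train = TRUE, keep_outputs = TRUE)
  R <- g$reg_bins; nc <- g$nc
  cls_slabs <- lapply(fwd$head, function(h)
    h[, 4 * R + seq_len(nc), , , drop = FALSE])
  if (is.null(class_id)) {
    best <- which.max(vapply(cls_slabs, max, numeric(1)))
    flat <- which.max(cls_slabs[[best]])
    class_id <- (arrayInd(flat, dim(cls_slabs[[best]]))[2] - 1L)
  }
  # seed gradient: 1 at the location of the maximum logit for the class
  dhead <- lapply(fwd$head, function(h) array(0, dim(h)))
  per_scale <- vapply(seq_along(cls_slabs), function(i)
    max(cls_slabs[[i]][, class_id + 1L, , ]), numeric(1))
  si <- which.max(per_scale)
  slab <- cls_slabs[[si]][1, class_id + 1L, , ]
  pos <- arrayInd(which.max(slab), dim(slab))
  dhead[[si]][1, 4 * R + class_id + 1L, pos[1], pos[2]] <- 1
  zero_grads(net)
  dtab <- network_backward(net, dhead)
  out <- list()
  for (ly in layers) {
    hm <- gradcam_map(fwd$outputs[[ly]], dtab[[ly]])
    hm3 <- array(hm, c(dim(hm), 1L))
    up <- .resize_bilinear(hm3, dim(image)[1], dim(image)[2])[, , 1]
    if (max(up) > 0) up <- up / max(up)
    out[[ly]] <- up
  }
  attr(out, "class_id") <- class_id
  out
}

#' Write a side-by-side original/heatmap overlay image
#'
#' @param fit a `trdnet_fit`.
#' @param image H x W x 3 array in `[0, 1]`.
#' @param file output PNG path.
#' @param ... passed to [grad_cam()].
#' @return invisibly, the heatmap list.
#' @export
save_gradcam <- function(fit, image, file, ...) {
  maps <- grad_cam(fit, image, ...)
  panels <- c(list(image), lapply(maps, function(m) overlay_heat(image, m)))
  H <- dim(image)[1]; W <- dim(image)[2]
  canvas <- array(0, c(H, W * length(panels), 3))
  for (i in seq_along(panels))
    canvas[, (i - 1L) * W + seq_len(W), ] <- panels[[i]]
  png::writePNG(canvas, file)
  invisible(maps)
}

# blue -> red blend of a [0,1] heatmap over the image
overlay_heat <- function(image, m) {
  out <- image
  out[, , 1] <- pmin(1, 0.4 * image[, , 1] + 0.6 * m)
  out[, , 2] <- 0.4 * image[, , 2]
  out[, , 3] <- pmin(1, 0.4 * image[, , 3] + 0.6 * (1 - m) * 0.5)
  out
}
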