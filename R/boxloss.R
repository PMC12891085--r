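# Box geometry and regression losses. Boxes are axis-aligned, continuous,
# 0-based corner coordinates (x1, y1, x2, y2) with x2 > x1, y2 > y1 and
# area (x2-x1)*(y2-y1); there is no +1 pixel convention. Functions accept a
# single box (length-4 vector) or an n x 4 matrix and vectorize row-wise.

as_box_matrix <- function(b, arg = "box") {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) != 4) stop(arg, " must have 4 coordinates (x1, y1, x2, y2)")
  if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
    stop(arg, ": degenerate box (x2 must exceed x1 and y2 exceed y1)")
  b
}

#' Intersection over union of axis-aligned boxes
#'
#' @param a,b boxes as length-4 vectors `(x1, y1, x2, y2)` or n x 4 matrices
#'   (paired row-wise).
#' @return numeric vector of IoU values in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as_box_matrix(a, "a"); b <- as_box_matrix(b, "b")
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  ua <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  inter / ua
}

#' Minimum-point-distance IoU
#'
#' IoU penalized by the squared distances between the corresponding top-left
#' and bottom-right corners of the two boxes, each normalized by the squared
#' image diagonal: `MPDIoU = IoU - d1^2/(h^2+w^2) - d2^2/(h^2+w^2)`. Always
#' at most the IoU, equal to 1 exactly for identical boxes, and invariant
#' under a common translation of both boxes.
#'
#' @param gt,pred ground-truth and predicted boxes (vector or n x 4 matrix).
#' @param extent image extent as `c(w, h)` in pixels, both positive.
#' @return numeric vector of MPDIoU values (can be negative).
#' @export
mpdiou <- function(gt, pred, extent) {
  if (length(extent) != 2 || any(extent <= 0))
    stop("extent must be positive (w, h)")
  gt <- as_box_matrix(gt, "gt"); pred <- as_box_matrix(pred, "pred")
  diag2 <- extent[1]^2 + extent[2]^2
  d1 <- (pred[, 1] - gt[, 1])^2 + (pred[, 2] - gt[, 2])^2
  d2 <- (pred[, 3] - gt[, 3])^2 + (pred[, 4] - gt[, 4])^2
  iou(gt, pred) - d1 / diag2 - d2 / diag2
}

#' MPDIoU bounding-box regression loss
#'
#' `1 - MPDIoU`; zero exactly when the boxes coincide.
#'
#' @inheritParams mpdiou
#' @return nonnegative numeric vector of losses.
#' @export
mpdiou_loss <- function(gt, pred, extent) 1 - mpdiou(gt, pred, extent)

#' Complete IoU (reference implementation)
#'
#' The baseline box regression measure: IoU minus the normalized center
#' distance minus an aspect-ratio consistency term. Provided only as the
#' comparison loss for training-curve experiments.
#'
#' @inheritParams iou
#' @return numeric vector of CIoU values.
#' @export
ciou <- function(a, b) {
  a <- as_box_matrix(a, "a"); b <- as_box_matrix(b, "b")
  i <- iou(a, b)
  # enclosing box diagonal
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  c2 <- cw^2 + ch^2 + 1e-9
  rho2 <- ((a[, 1] + a[, 3]) - (b[, 1] + b[, 3]))^2 / 4 +
    ((a[, 2] + a[, 4]) - (b[, 2] + b[, 4]))^2 / 4
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  wb <- b[, 3] - b[, 1]; hb <- b[, 4] - b[, 2]
  v <- (4 / pi^2) * (atan(wa / ha) - atan(wb / hb))^2
  alpha <- v / (1 - i + v + 1e-9)
  i - rho2 / c2 - alpha * v
}

#' @rdname ciou
#' @export
ciou_loss <- function(gt, pred) 1 - ciou(gt, pred)

# Analytic gradient of IoU w.r.t. the predicted box coordinates.
# Returns n x 4 matrix d(iou)/d(pred).
iou_grad_pred <- function(gt, pred) {
  gt <- as_box_matrix(gt); pred <- as_box_matrix(pred)
  iw <- pmin(gt[, 3], pred[, 3]) - pmax(gt[, 1], pred[, 1])
  ih <- pmin(gt[, 4], pred[, 4]) - pmax(gt[, 2], pred[, 2])
  pos <- iw > 0 & ih > 0
  iw <- pmax(iw, 0); ih <- pmax(ih, 0)
  inter <- iw * ih
  area_g <- (gt[, 3] - gt[, 1]) * (gt[, 4] - gt[, 2])
  area_p <- (pred[, 3] - pred[, 1]) * (pred[, 4] - pred[, 2])
  u <- area_g + area_p - inter
  # d inter / d pred coords (0 where the clamp is inactive)
  dI <- matrix(0, nrow(pred), 4)
  dI[, 1] <- ifelse(pos & pred[, 1] > gt[, 1], -ih, 0)
  dI[, 2] <- ifelse(pos & pred[, 2] > gt[, 2], -iw, 0)
  dI[, 3] <- ifelse(pos & pred[, 3] < gt[, 3], ih, 0)
  dI[, 4] <- ifelse(pos & pred[, 4] < gt[, 4], iw, 0)
  dA <- cbind(-(pred[, 4] - pred[, 2]), -(pred[, 3] - pred[, 1]),
              pred[, 4] - pred[, 2], pred[, 3] - pred[, 1])
  # iou = I/u, u = Ag + Ap - I  =>  d iou = (dI*u - I*(dA - dI)) / u^2
  (dI * u - inter * (dA - dI)) / u^2
}

# Gradient of mpdiou w.r.t. predicted coords (n x 4 matrix).
mpdiou_grad_pred <- function(gt, pred, extent) {
  gt <- as_box_matrix(gt); pred <- as_box_matrix(pred)
  diag2 <- extent[1]^2 + extent[2]^2
  g <- iou_grad_pred(gt, pred)
  g[, 1] <- g[, 1] - 2 * (pred[, 1] - gt[, 1]) / diag2
  g[, 2] <- g[, 2] - 2 * (pred[, 2] - gt[, 2]) / diag2
  g[, 3] <- g[, 3] - 2 * (pred[, 3] - gt[, 3]) / diag2
  g[, 4] <- g[, 4] - 2 * (pred[, 4] - gt[, 4]) / diag2
  g
}

# Exact gradient of ciou w.r.t. predicted coords (alpha's dependence on
# IoU and on the aspect term is differentiated through, so the gradient is
# the true derivative of ciou()).
ciou_grad_pred <- function(gt, pred) {
  gt <- as_box_matrix(gt); pred <- as_box_matrix(pred)
  eps <- 1e-9
  i <- iou(gt, pred)
  gi <- iou_grad_pred(gt, pred)
  cw <- pmax(gt[, 3], pred[, 3]) - pmin(gt[, 1], pred[, 1])
  ch <- pmax(gt[, 4], pred[, 4]) - pmin(gt[, 2], pred[, 2])
  c2 <- cw^2 + ch^2 + eps
  dcx <- ((pred[, 1] + pred[, 3]) - (gt[, 1] + gt[, 3])) / 2
  dcy <- ((pred[, 2] + pred[, 4]) - (gt[, 2] + gt[, 4])) / 2
  rho2 <- dcx^2 + dcy^2
  wa <- gt[, 3] - gt[, 1]; ha <- gt[, 4] - gt[, 2]
  wp <- pred[, 3] - pred[, 1]; hp <- pred[, 4] - pred[, 2]
  datan <- atan(wa / ha) - atan(wp / hp)
  v <- (4 / pi^2) * datan^2
  u <- 1 - i + v + eps
  # d(rho2/c2): through the centers and the enclosing box diagonal
  dc2_dp <- 2 * cbind(ifelse(pred[, 1] < gt[, 1], -1, 0) * cw,
                      ifelse(pred[, 2] < gt[, 2], -1, 0) * ch,
                      ifelse(pred[, 3] > gt[, 3], 1, 0) * cw,
                      ifelse(pred[, 4] > gt[, 4], 1, 0) * ch)
  drho_dp <- cbind(dcx, dcy, dcx, dcy)
  g <- gi * (1 - v^2 / u^2) - (drho_dp * c2 - rho2 * dc2_dp) / c2^2
  # d v / d pred through atan(wp/hp); alpha*v = v^2/u
  dv_dw <- -(8 / pi^2) * datan * hp / (wp^2 + hp^2)
  dv_dh <- (8 / pi^2) * datan * wp / (wp^2 + hp^2)
  coef_v <- (2 * v * u - v^2) / u^2
  g[, 1] <- g[, 1] + coef_v * dv_dw
  g[, 3] <- g[, 3] - coef_v * dv_dw
  g[, 2] <- g[, 2] + coef_v * dv_dh
  g[, 4] <- g[, 4] - coef_v * dv_dh
  g
}
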