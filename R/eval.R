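# Detection evaluation: greedy matching at an IoU threshold, all-point
# interpolated average precision, and mAP@0.5 pooled over images per class.
#
# Detections are data frames with columns class_id, confidence, x1, y1,
# x2, y2 (one row per box); ground truths are data frames with class_id,
# x1, y1, x2, y2. Class ids follow the ripeness order 0 = ripe,
# 1 = half-ripe, 2 = unripe.

#' Match detections of one class on one image to ground truths
#'
#' Detections are sorted by descending confidence and each is greedily
#' matched to the unmatched ground-truth box of highest IoU, provided that
#' IoU reaches the threshold. Every ground truth is matched at most once;
#' unmatched detections are false positives.
#'
#' @param dets data frame with `confidence`, `x1`, `y1`, `x2`, `y2` (single
#'   class, single image); may have zero rows.
#' @param gts data frame with `x1`, `y1`, `x2`, `y2`; may have zero rows.
#' @param iou_thr IoU threshold (0.5 for mAP@0.5).
#' @return logical vector of TP flags, one per detection, in descending
#'   confidence order, with the matching order as attribute `"order"`.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  if (nrow(dets) == 0L)
    return(structure(logical(0), order = integer(0)))
  ord <- order(-dets$confidence)
  tp <- logical(nrow(dets))
  used <- rep(FALSE, nrow(gts))
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (nrow(gts) == 0L) break
    ious <- iou(as.matrix(gts[, c("x1", "y1", "x2", "y2")]),
                matrix(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                       nrow(gts), 4, byrow = TRUE))
    ious[used] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_thr) {
      tp[k] <- TRUE
      used[j] <- TRUE
    }
  }
  structure(tp, order = ord)
}

#' All-point interpolated average precision
#'
#' Area under the precision-recall curve using the precision envelope
#' (continuous all-point interpolation, not the 11-point variant): precision
#' at each recall level is replaced by the maximum precision at any equal or
#' higher recall, and the area is the sum over recall increments.
#'
#' @param flags logical TP flags ordered by descending confidence.
#' @param n_gt number of ground-truth boxes of this class.
#' @return average precision in `[0, 1]`.
#' @export
average_precision <- function(flags, n_gt) {
  if (n_gt == 0L) {
    if (any(flags)) stop("true positives reported with zero ground truths")
    return(0)
  }
  if (length(flags) == 0L) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # precision envelope
  penv <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * penv)
}

#' Evaluate detections at IoU 0.5
#'
#' Pools detections per class across images (standard VOC protocol), computes
#' per-class all-point AP at the IoU threshold, and averages the APs of the
#' classes present in the ground truth into mAP. Precision and recall are
#' reported both at the confidence operating point maximizing F1 and at a
#' fixed confidence of 0.5.
#'
#' @param dets_by_image named list of detection data frames (columns
#'   `class_id`, `confidence`, `x1`, `y1`, `x2`, `y2`).
#' @param gts_by_image named list of ground-truth data frames (columns
#'   `class_id`, `x1`, `y1`, `x2`, `y2`); names must cover those of
#'   `dets_by_image`.
#' @param classes integer vector of class ids to evaluate.
#' @param iou_thr IoU threshold, default 0.5.
#' @return an object of class `eval_summary`: list with `precision`,
#'   `recall` (max-F1 operating point), `precision_at_0.5`,
#'   `recall_at_0.5`, `ap_per_class` (named by class id; `NA` for classes
#'   absent from the ground truth) and `map50`.
#' @export
evaluate_map50 <- function(dets_by_image, gts_by_image, classes = 0:2,
                           iou_thr = 0.5) {
  imgs <- names(gts_by_image)
  if (is.null(imgs)) stop("gts_by_image must be a named list")
  extra <- setdiff(names(dets_by_image), imgs)
  if (length(extra)) stop("detections for unknown images: ",
                          paste(extra, collapse = ", "))
  ap <- setNames(rep(NA_real_, length(classes)), classes)
  all_conf <- numeric(0); all_tp <- logical(0); total_gt <- 0L
  for (cl in classes) {
    conf <- numeric(0); tp <- logical(0); n_gt <- 0L
    for (im in imgs) {
      g <- gts_by_image[[im]]
      g <- g[g$class_id == cl, , drop = FALSE]
      d <- dets_by_image[[im]]
      if (is.null(d)) d <- empty_detections()
      d <- d[d$class_id == cl, , drop = FALSE]
      fl <- match_detections(d, g, iou_thr)
      ord <- attr(fl, "order")
      conf <- c(conf, d$confidence[ord])
      tp <- c(tp, as.logical(fl))
      n_gt <- n_gt + nrow(g)
    }
    if (n_gt > 0L) {
      o <- order(-conf)
      ap[as.character(cl)] <- average_precision(tp[o], n_gt)
      all_conf <- c(all_conf, conf)
      all_tp <- c(all_tp, tp)
      total_gt <- total_gt + n_gt
    }
  }
  pr <- pr_operating_points(all_conf, all_tp, total_gt)
  res <- list(precision = pr$p_f1, recall = pr$r_f1,
              precision_at_0.5 = pr$p_05, recall_at_0.5 = pr$r_05,
              ap_per_class = ap,
              map50 = mean(ap, na.rm = TRUE))
  if (all(is.na(ap))) res$map50 <- NA_real_
  class(res) <- "eval_summary"
  res
}

empty_detections <- function() {
  data.frame(class_id = integer(0), confidence = numeric(0),
             x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0))
}

pr_operating_points <- function(conf, tp, n_gt) {
  if (length(conf) == 0L || n_gt == 0L)
    return(list(p_f1 = 0, r_f1 = 0, p_05 = 0, r_05 = 0))
  o <- order(-conf)
  conf <- conf[o]; tp <- tp[o]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  p <- ctp / (ctp + cfp); r <- ctp / n_gt
  f1 <- 2 * p * r / pmax(p + r, 1e-12)
  k <- which.max(f1)
  k5 <- sum(conf >= 0.5)
  list(p_f1 = p[k], r_f1 = r[k],
       p_05 = if (k5 > 0) p[k5] else 0,
       r_05 = if (k5 > 0) r[k5] else 0)
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("Detection evaluation (IoU 0.5)\n")
  cat(sprintf("  precision (max-F1): %.4f   recall: %.4f\n",
              x$precision, x$recall))
  cat(sprintf("  precision (conf 0.5): %.4f   recall: %.4f\n",
              x$precision_at_0.5, x$recall_at_0.5))
  cls <- names(x$ap_per_class)
  lab <- ripeness_class_names()
  for (i in seq_along(cls)) {
    nm <- lab[as.integer(cls[i]) + 1L]
    if (is.na(nm)) nm <- cls[i]
    cat(sprintf("  AP  %-10s %s\n", nm,
                ifelse(is.na(x$ap_per_class[i]), "  (absent)",
                       sprintf("%.4f", x$ap_per_class[i]))))
  }
  cat(sprintf("  mAP@0.5: %.4f\n", x$map50))
  invisible(x)
}

#' Class-wise non-maximum suppression
#'
#' Greedy NMS per class: keep the highest-confidence box, drop all boxes of
#' the same class whose IoU with a kept box exceeds the threshold.
#'
#' @param dets detection data frame (`class_id`, `confidence`, `x1`, `y1`,
#'   `x2`, `y2`).
#' @param iou_thr suppression IoU threshold.
#' @return the surviving subset of `dets`.
#' @export
nms <- function(dets, iou_thr = 0.7) {
  if (nrow(dets) == 0L) return(dets)
  keep <- integer(0)
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    idx <- idx[order(-dets$confidence[idx])]
    while (length(idx)) {
      i <- idx[1]
      keep <- c(keep, i)
      idx <- idx[-1]
      if (length(idx)) {
        ious <- iou(matrix(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                           length(idx), 4, byrow = TRUE),
                    as.matrix(dets[idx, c("x1", "y1", "x2", "y2")]))
        idx <- idx[ious <= iou_thr]
      }
    }
  }
  dets[sort(keep), , drop = FALSE]
}

#' Read and write per-image detection text files
#'
#' One detection per line: `class confidence x1 y1 x2 y2`.
#'
#' @param dets detection data frame.
#' @param path file path.
#' @return `read_detections` returns a detection data frame.
#' @export
write_detections <- function(dets, path) {
  lines <- sprintf("%d %.6f %.3f %.3f %.3f %.3f", dets$class_id,
                   dets$confidence, dets$x1, dets$y1, dets$x2, dets$y2)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_detections())
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(class_id = as.integer(m[, 1]), confidence = m[, 2],
             x1 = m[, 3], y1 = m[, 4], x2 = m[, 5], y2 = m[, 6])
}
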