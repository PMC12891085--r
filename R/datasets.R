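# Annotation I/O and dataset plumbing. Internal coordinates are 0-based,
# continuous box corners; the 1-based PASCAL VOC convention is normalized at
# the reader/writer boundary. Annotations are data frames with columns
# class_id (0 = ripe, 1 = half-ripe, 2 = unripe), x1, y1, x2, y2.

#' Ripeness class names
#'
#' Fixed class order of the ripeness grading task: surface more than 40% red
#' is ripe; an orange-red surface share of at most 40% is half-ripe; green or
#' white-green fruit is unripe.
#'
#' @return character vector `c("ripe", "half-ripe", "unripe")`, so class id
#'   k maps to `ripeness_class_names()[k + 1]`.
#' @export
ripeness_class_names <- function() c("ripe", "half-ripe", "unripe")

empty_annotations <- function() {
  data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0))
}

#' Parse PASCAL VOC XML annotations
#'
#' Reads the `<object>` elements of a VOC annotation document. Coordinates
#' are converted from the 1-based VOC convention to 0-based internal
#' coordinates by subtracting 1 from the min corners; unknown class names and
#' inverted boxes are rejected.
#'
#' @param xml_text VOC annotation document as a string (or an `xml2`
#'   document).
#' @param class_names ordered class names; position determines the class id
#'   (0-based). Default [ripeness_class_names()].
#' @return annotation data frame with the image size in attributes
#'   `width`/`height`.
#' @export
parse_voc_xml <- function(xml_text, class_names = ripeness_class_names()) {
  doc <- if (inherits(xml_text, "xml_document")) xml_text else
    xml2::read_xml(xml_text)
  size <- xml2::xml_find_first(doc, ".//size")
  w <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  h <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  ann <- empty_annotations()
  for (o in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    cid <- match(nm, class_names)
    if (is.na(cid)) stop("unknown class name in VOC annotation: ", nm)
    bb <- xml2::xml_find_first(o, "./bndbox")
    co <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(t)
      as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", t)))),
      numeric(1))
    x1 <- co[1] - 1; y1 <- co[2] - 1
    if (co[3] <= x1 || co[4] <= y1)
      stop("inverted or empty bounding box in VOC annotation")
    ann <- rbind(ann, data.frame(class_id = cid - 1L, x1 = x1, y1 = y1,
                                 x2 = co[3], y2 = co[4]))
  }
  attr(ann, "width") <- w
  attr(ann, "height") <- h
  ann
}

#' Write PASCAL VOC XML annotations
#'
#' Inverse of [parse_voc_xml()]: internal 0-based corners are written as
#' 1-based VOC `bndbox` coordinates.
#'
#' @param ann annotation data frame.
#' @param img_w,img_h image size in pixels.
#' @param filename image file name recorded in the annotation.
#' @param class_names ordered class names.
#' @return the XML document as a string.
#' @export
write_voc_xml <- function(ann, img_w, img_h, filename = "image.png",
                          class_names = ripeness_class_names()) {
  obj <- vapply(seq_len(nrow(ann)), function(i) {
    paste0("  <object>\n    <name>", class_names[ann$class_id[i] + 1L],
           "</name>\n    <difficult>0</difficult>\n    <bndbox>\n",
           sprintf("      <xmin>%d</xmin>\n      <ymin>%d</ymin>\n",
                   as.integer(round(ann$x1[i] + 1)),
                   as.integer(round(ann$y1[i] + 1))),
           sprintf("      <xmax>%d</xmax>\n      <ymax>%d</ymax>\n",
                   as.integer(round(ann$x2[i])),
                   as.integer(round(ann$y2[i]))),
           "    </bndbox>\n  </object>\n")
  }, character(1))
  paste0("<annotation>\n  <filename>", filename, "</filename>\n",
         "  <size>\n    <width>", img_w, "</width>\n    <height>", img_h,
         "</height>\n    <depth>3</depth>\n  </size>\n",
         paste(obj, collapse = ""), "</annotation>\n")
}

#' Convert between pixel boxes and normalized YOLO labels
#'
#' `voc_to_yolo` maps an annotation data frame to normalized
#' `(class, cx, cy, w, h)` rows in `[0, 1]`; `yolo_to_voc` is its inverse.
#'
#' @param ann annotation data frame (pixel corners).
#' @param img_w,img_h image size in pixels, both positive.
#' @return `voc_to_yolo`: data frame with columns `class_id`, `cx`, `cy`,
#'   `w`, `h`; `yolo_to_voc`: annotation data frame.
#' @export
voc_to_yolo <- function(ann, img_w, img_h) {
  if (img_w <= 0 || img_h <= 0) stop("image dimensions must be positive")
  data.frame(class_id = ann$class_id,
             cx = (ann$x1 + ann$x2) / 2 / img_w,
             cy = (ann$y1 + ann$y2) / 2 / img_h,
             w = (ann$x2 - ann$x1) / img_w,
             h = (ann$y2 - ann$y1) / img_h)
}

#' @rdname voc_to_yolo
#' @param yolo data frame with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
yolo_to_voc <- function(yolo, img_w, img_h) {
  if (img_w <= 0 || img_h <= 0) stop("image dimensions must be positive")
  data.frame(class_id = yolo$class_id,
             x1 = (yolo$cx - yolo$w / 2) * img_w,
             y1 = (yolo$cy - yolo$h / 2) * img_h,
             x2 = (yolo$cx + yolo$w / 2) * img_w,
             y2 = (yolo$cy + yolo$h / 2) * img_h)
}

#' Read and write YOLO label text files
#'
#' One object per line: `class cx cy w h`, normalized to `[0, 1]`.
#'
#' @param yolo data frame with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @param path file path.
#' @return `read_yolo_labels` returns a YOLO label data frame.
#' @export
write_yolo_labels <- function(yolo, path) {
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", yolo$class_id, yolo$cx,
                     yolo$cy, yolo$w, yolo$h), path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(class_id = integer(0), cx = numeric(0),
                      cy = numeric(0), w = numeric(0), h = numeric(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Split sample ids into train/validation/test sets
#'
#' Deterministic shuffle under the seed, then allocation by the given ratios
#' (default 7:2:1): validation and test receive their floor share and the
#' remainder goes to training, so bucket sizes deviate from the exact ratios
#' by less than one sample.
#'
#' @param ids character or integer vector of sample ids (at least 10).
#' @param ratios length-3 numeric ratios for train, validation, test.
#' @param seed integer seed for the shuffle.
#' @return an object of class `dataset_split`: list with disjoint `train`,
#'   `val`, `test` id vectors whose union is `ids`.
#' @export
split_dataset <- function(ids, ratios = c(7, 2, 1), seed = 0L) {
  n <- length(ids)
  if (n < 10L) stop("need at least 10 ids to split")
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  p <- ratios / sum(ratios)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  perm <- sample(n)
  n_val <- floor(n * p[2])
  n_test <- floor(n * p[3])
  n_train <- n - n_val - n_test
  structure(list(train = ids[perm[seq_len(n_train)]],
                 val = ids[perm[n_train + seq_len(n_val)]],
                 test = ids[perm[n_train + n_val + seq_len(n_test)]]),
            class = "dataset_split")
}

#' Mosaic augmentation of four samples
#'
#' Stitches four image samples into one composite: a mosaic center is drawn
#' uniformly from the central half of a double-size canvas, each source image
#' is scaled into its quadrant, boxes are shifted along, clipped to the
#' canvas, and dropped when the clipped width or height falls below 2 px;
#' the canvas is finally resized to `out_size`. Deterministic under `seed`.
#'
#' @param samples list of exactly 4 samples, each a list with `image`
#'   (H x W x 3 array in `[0, 1]`) and `annotations` (annotation data frame).
#' @param out_size output square size in pixels.
#' @param seed integer seed.
#' @return a sample list (`image`, `annotations`) of size `out_size`.
#' @export
mosaic4 <- function(samples, out_size = 320L, seed = 0L) {
  if (length(samples) != 4L) stop("mosaic needs exactly 4 samples")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  S <- 2L * out_size
  cx <- round(runif(1, 0.25 * S, 0.75 * S))
  cy <- round(runif(1, 0.25 * S, 0.75 * S))
  canvas <- array(0.05, c(S, S, 3))
  ann <- empty_annotations()
  # quadrant extents on the canvas: (x1,y1,x2,y2), 0-based
  quads <- list(c(0, 0, cx, cy), c(cx, 0, S, cy),
                c(0, cy, cx, S), c(cx, cy, S, S))
  for (q in 1:4) {
    qx <- quads[[q]]
    qw <- qx[3] - qx[1]; qh <- qx[4] - qx[2]
    if (qw < 2 || qh < 2) next
    img <- samples[[q]]$image
    a <- samples[[q]]$annotations
    sh <- dim(img)[1]; sw <- dim(img)[2]
    res <- .resize_bilinear(img, as.integer(qh), as.integer(qw))
    canvas[(qx[2] + 1):qx[4], (qx[1] + 1):qx[3], ] <- res
    if (nrow(a)) {
      sx <- qw / sw; sy <- qh / sh
      b <- data.frame(class_id = a$class_id,
                      x1 = pmax(a$x1 * sx + qx[1], 0),
                      y1 = pmax(a$y1 * sy + qx[2], 0),
                      x2 = pmin(a$x2 * sx + qx[1], S),
                      y2 = pmin(a$y2 * sy + qx[2], S))
      keep <- (b$x2 - b$x1) >= 2 & (b$y2 - b$y1) >= 2
      ann <- rbind(ann, b[keep, , drop = FALSE])
    }
  }
  out <- .resize_bilinear(canvas, as.integer(out_size), as.integer(out_size))
  sc <- out_size / S
  ann[, c("x1", "y1", "x2", "y2")] <- ann[, c("x1", "y1", "x2", "y2")] * sc
  keep <- (ann$x2 - ann$x1) >= 1 & (ann$y2 - ann$y1) >= 1
  list(image = out, annotations = ann[keep, , drop = FALSE])
}

#' Write or read a dataset manifest
#'
#' The manifest is a YAML file naming the class list and, per split, the
#' sample ids; images and labels live beside it in `images/`, `voc/` and
#' `labels/` subdirectories.
#'
#' @param dir dataset directory.
#' @param split a [split_dataset()] result.
#' @param class_names ordered class names.
#' @return `read_manifest` returns the manifest as a list.
#' @export
write_manifest <- function(dir, split, class_names = ripeness_class_names()) {
  m <- list(classes = as.list(class_names),
            train = as.list(split$train), val = as.list(split$val),
            test = as.list(split$test))
  yaml::write_yaml(m, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  yaml::read_yaml(file.path(dir, "manifest.yaml"))
}

#' Convert a directory of VOC XML annotations to YOLO label files
#'
#' @param voc_dir directory of `.xml` files.
#' @param out_dir output directory for `.txt` files (created if needed).
#' @param class_names ordered class names.
#' @return invisibly, the vector of written files.
#' @export
convert_voc_dir <- function(voc_dir, out_dir,
                            class_names = ripeness_class_names()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(voc_dir, pattern = "\\.xml$", full.names = TRUE)
  out <- character(0)
  for (f in files) {
    ann <- parse_voc_xml(paste(readLines(f), collapse = "\n"), class_names)
    y <- voc_to_yolo(ann, attr(ann, "width"), attr(ann, "height"))
    dest <- file.path(out_dir, sub("\\.xml$", ".txt", basename(f)))
    write_yolo_labels(y, dest)
    out <- c(out, dest)
  }
  invisible(out)
}
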