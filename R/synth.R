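# Synthetic greenhouse-scene generator. Scenes emulate the imaging
# conditions of greenhouse tomato photography at desk scale: a dark
# green-brown textured background with leaf clutter, clustered ellipsoidal
# fruits whose ripeness class follows the red-surface-fraction rule
# (> 40% red = ripe; up to 40% orange-red = half-ripe; no red = unripe),
# optional leaf occlusion, brightness jitter and linear motion blur.
# The red fraction is realized geometrically as an elliptical cap of the
# target area share, so the class rule is pixel-verifiable on the rendering
# masks, not just a label.

#' Scene generation parameters
#'
#' @param n_fruits number of fruits attempted per scene.
#' @param fruit_radius_range range (px) of the fruit semi-axes.
#' @param red_fraction_sampler function(n) returning n red-surface fractions
#'   in `[0, 1]`. The default mixes the three ripeness stages roughly in the
#'   proportions of a mid-season greenhouse crop (39% ripe with red fraction
#'   0.45-1, 26% half-ripe with 0.05-0.4, 35% unripe with 0).
#' @param occlusion_level `"none"`, `"slight"`, `"moderate"` or `"heavy"`,
#'   mapped to a maximum leaf-cover fraction per fruit of 0, 0.15, 0.35,
#'   0.6.
#' @param brightness_jitter multiplicative brightness range.
#' @param blur_kernel_len linear motion-blur kernel length in px (0 = none).
#' @param image_size square image size in px.
#' @param seed integer seed making the scene deterministic.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(n_fruits = 5L,
                         fruit_radius_range = c(14, 26),
                         red_fraction_sampler = default_red_sampler,
                         occlusion_level = c("slight", "none", "moderate",
                                             "heavy"),
                         brightness_jitter = c(0.8, 1.2),
                         blur_kernel_len = 0L,
                         image_size = 160L,
                         seed = 0L) {
  occlusion_level <- match.arg(occlusion_level)
  stopifnot(n_fruits >= 0L, length(fruit_radius_range) == 2L,
            fruit_radius_range[1] > 1, blur_kernel_len >= 0L,
            image_size >= 32L)
  structure(list(n_fruits = as.integer(n_fruits),
                 fruit_radius_range = fruit_radius_range,
                 red_fraction_sampler = red_fraction_sampler,
                 occlusion_level = occlusion_level,
                 max_cover = c(none = 0, slight = 0.15, moderate = 0.35,
                               heavy = 0.6)[[occlusion_level]],
                 brightness_jitter = brightness_jitter,
                 blur_kernel_len = as.integer(blur_kernel_len),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' @rdname scene_params
#' @param n number of fractions to draw.
#' @export
default_red_sampler <- function(n) {
  u <- runif(n)
  f <- numeric(n)
  ripe <- u < 0.39
  half <- !ripe & u < 0.65
  f[ripe] <- runif(sum(ripe), 0.45, 1)
  f[half] <- runif(sum(half), 0.05, 0.40)
  f
}

# Chord height (in unit-circle coordinates, in [-1, 1]) such that the cap
# {y < k} covers fraction f of the disc area. f = 0 -> -1, f = 1 -> 1.
cap_chord <- function(f) {
  if (f <= 0) return(-1)
  if (f >= 1) return(1)
  seg <- function(k) (acos(-k) - (-k) * sqrt(1 - k^2)) / pi - f
  stats::uniroot(seg, c(-1, 1), tol = 1e-10)$root
}

#' Assign a ripeness class from a red surface fraction
#'
#' @param f red (or orange-red) surface fraction in `[0, 1]`.
#' @return integer class id: 0 (ripe) if `f > 0.40`, 1 (half-ripe) if
#'   `0 < f <= 0.40`, 2 (unripe) if `f = 0`.
#' @export
ripeness_from_red_fraction <- function(f) {
  ifelse(f > 0.40, 0L, ifelse(f > 0, 1L, 2L))
}

# Draw a filled ellipse mask on a logical matrix grid (H x W, row = y).
ellipse_mask <- function(H, W, cx, cy, a, b, theta = 0) {
  ys <- matrix(seq_len(H) - 0.5, H, W)
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  ct <- cos(theta); st <- sin(theta)
  xr <- (xs - cx) * ct + (ys - cy) * st
  yr <- -(xs - cx) * st + (ys - cy) * ct
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate one synthetic greenhouse scene
#'
#' @param p a [scene_params()].
#' @return an object of class `scene_sample`: list with `image` (H x W x 3
#'   array in `[0, 1]`), `annotations` (one row per rendered fruit, full
#'   fruit extent even when partially occluded), and `truth_meta` (data frame
#'   with per-fruit target and pixel-realized red fraction, occluded
#'   fraction, and placement metadata; attribute `n_dropped` counts fruits
#'   that could not be placed). With masks: `fruit_mask` (integer matrix,
#'   0 = background, k = fruit k's unoccluded extent), `red_mask` (logical,
#'   red/orange-red cap pixels) and `leaf_mask` (logical, occluding leaf
#'   pixels), for pixel-level verification.
#' @export
generate_scene <- function(p = scene_params()) {
  stopifnot(inherits(p, "scene_params"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(p$seed)
  S <- p$image_size
  img <- render_background(S)
  # --- place fruits (clustered) ---
  fruits <- list()
  n_dropped <- 0L
  if (p$n_fruits > 0L) {
    n_clusters <- max(1L, min(2L, ceiling(p$n_fruits / 4)))
    ccx <- runif(n_clusters, 0.25 * S, 0.75 * S)
    ccy <- runif(n_clusters, 0.25 * S, 0.75 * S)
    for (i in seq_len(p$n_fruits)) {
      placed <- FALSE
      for (try in 1:40) {
        k <- sample.int(n_clusters, 1L)
        a <- runif(1, p$fruit_radius_range[1], p$fruit_radius_range[2])
        b <- a * runif(1, 0.85, 1.1)
        cx <- rnorm(1, ccx[k], 0.22 * S)
        cy <- rnorm(1, ccy[k], 0.22 * S)
        if (cx - a < 1 || cx + a > S - 1 || cy - b < 1 || cy + b > S - 1)
          next
        box <- c(cx - a, cy - b, cx + a, cy + b)
        ok <- TRUE
        for (fr in fruits)
          if (iou(box, fr$box) > 0.35) { ok <- FALSE; break }
        if (ok) {
          fruits[[length(fruits) + 1L]] <-
            list(cx = cx, cy = cy, a = a, b = b, box = box)
          placed <- TRUE
          break
        }
      }
      if (!placed) n_dropped <- n_dropped + 1L
    }
  }
  nf <- length(fruits)
  f_red <- if (nf) p$red_fraction_sampler(nf) else numeric(0)
  cls <- ripeness_from_red_fraction(f_red)
  fruit_mask <- matrix(0L, S, S)
  red_mask <- matrix(FALSE, S, S)
  red_real <- numeric(nf)
  # --- render fruits back-to-front ---
  for (i in seq_len(nf)) {
    fr <- fruits[[i]]
    m <- ellipse_mask(S, S, fr$cx, fr$cy, fr$a, fr$b)
    fruit_mask[m] <- i
    # shading: radial falloff from an offset highlight
    ys <- matrix(seq_len(S) - 0.5, S, S)
    xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)
    rr <- sqrt(((xs - fr$cx + 0.3 * fr$a) / fr$a)^2 +
                 ((ys - fr$cy + 0.3 * fr$b) / fr$b)^2)
    shade <- pmax(0.55, 1.05 - 0.35 * rr)
    if (cls[i] == 2L) {
      body <- c(0.38, 0.56, 0.22)
      hi <- c(0.62, 0.72, 0.48)          # white-green highlight
      himask <- m & ellipse_mask(S, S, fr$cx - 0.25 * fr$a,
                                 fr$cy - 0.30 * fr$b,
                                 0.45 * fr$a, 0.40 * fr$b)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[m] <- body[ch] * shade[m]
        pl[himask] <- hi[ch] * shade[himask]
        img[, , ch] <- pl
      }
    } else {
      # red (ripe) or orange-red (half-ripe) cap of area share f over a
      # green-orange body; cap below chord y' < k in fruit coordinates
      k <- cap_chord(f_red[i])
      ydash <- (ys - fr$cy) / fr$b
      capmask <- m & (ydash >= -k)   # area of {y' >= -k} equals cap share f
      cap_col <- if (cls[i] == 0L) c(0.82, 0.12, 0.08) else
        c(0.86, 0.44, 0.10)
      body <- c(0.48, 0.58, 0.20)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[m] <- body[ch] * shade[m]
        pl[capmask] <- cap_col[ch] * shade[capmask]
        img[, , ch] <- pl
      }
      red_mask[capmask] <- TRUE
      # pixel-counted cap share of this fruit's own surface (counted at
      # paint time, before neighbouring fruits may overpaint it)
      red_real[i] <- sum(capmask) / max(sum(m), 1L)
    }
  }
  # --- leaf occlusion ---
  leaf_mask <- matrix(FALSE, S, S)
  occ <- numeric(nf)
  if (p$max_cover > 0 && nf > 0) {
    for (i in seq_len(nf)) {
      target <- runif(1, 0, p$max_cover)
      if (target < 0.02) next
      fr <- fruits[[i]]
      fpix <- sum(fruit_mask == i)
      for (try in 1:25) {
        la <- fr$a * runif(1, 0.5, 1.1)
        lb <- fr$b * runif(1, 0.35, 0.8)
        ang <- runif(1, 0, pi)
        side <- runif(1, 0, 2 * pi)
        lx <- fr$cx + cos(side) * fr$a * runif(1, 0.7, 1.15)
        ly <- fr$cy + sin(side) * fr$b * runif(1, 0.7, 1.15)
        lm <- ellipse_mask(S, S, lx, ly, la, lb, ang)
        cov <- sum(lm & fruit_mask == i) / max(fpix, 1L)
        if (cov > 0.2 * target && cov <= p$max_cover) {
          leaf_mask <- leaf_mask | lm
          img <- paint_leaf(img, lm)
          break
        }
      }
    }
    occ <- vapply(seq_len(nf), function(i) {
      tot <- sum(fruit_mask == i)
      if (tot == 0L) return(0)
      sum(leaf_mask & fruit_mask == i) / tot
    }, numeric(1))
  }
  # --- photometric effects ---
  jit <- runif(1, p$brightness_jitter[1], p$brightness_jitter[2])
  img <- pmin(pmax(img * jit, 0), 1)
  blur_angle <- NA_real_
  if (p$blur_kernel_len >= 2L) {
    blur_angle <- runif(1, 0, pi)
    img <- motion_blur(img, p$blur_kernel_len, blur_angle)
  }
  ann <- if (nf) data.frame(
    class_id = cls,
    x1 = vapply(fruits, function(f) max(f$box[1], 0), numeric(1)),
    y1 = vapply(fruits, function(f) max(f$box[2], 0), numeric(1)),
    x2 = vapply(fruits, function(f) min(f$box[3], S), numeric(1)),
    y2 = vapply(fruits, function(f) min(f$box[4], S), numeric(1))) else
      empty_annotations()
  meta <- data.frame(fruit = seq_len(nf),
                     red_fraction_target = f_red,
                     red_fraction = red_real,
                     occluded_fraction = occ,
                     class_id = cls)
  attr(meta, "n_dropped") <- n_dropped
  attr(meta, "brightness") <- jit
  attr(meta, "blur_angle") <- blur_angle
  structure(list(image = img, annotations = ann, truth_meta = meta,
                 fruit_mask = fruit_mask, red_mask = red_mask,
                 leaf_mask = leaf_mask),
            class = "scene_sample")
}

render_background <- function(S) {
  base <- c(0.10, 0.16, 0.09)
  img <- array(0, c(S, S, 3))
  # coarse low-frequency mottle upsampled to full size
  g <- 8L
  coarse <- array(runif(g * g * 3, -0.04, 0.04), c(g, g, 3))
  mottle <- .resize_bilinear(coarse, S, S)
  for (ch in 1:3) img[, , ch] <- base[ch] + mottle[, , ch]
  # background foliage blobs
  for (b in seq_len(6)) {
    m <- ellipse_mask(S, S, runif(1, 0, S), runif(1, 0, S),
                      runif(1, 0.08, 0.2) * S, runif(1, 0.05, 0.12) * S,
                      runif(1, 0, pi))
    col <- c(0.12, 0.22, 0.10) * runif(1, 0.7, 1.3)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[m] <- 0.5 * pl[m] + 0.5 * col[ch]
      img[, , ch] <- pl
    }
  }
  img + array(rnorm(S * S * 3, 0, 0.01), c(S, S, 3))
}

paint_leaf <- function(img, lm) {
  col <- c(0.16, 0.34, 0.13) * runif(1, 0.8, 1.2)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[lm] <- col[ch]
    img[, , ch] <- pl
  }
  img
}

# Linear motion blur: average of the image translated along a length-L line
# at the given angle (a rotated box kernel).
motion_blur <- function(img, L, angle) {
  S1 <- dim(img)[1]; S2 <- dim(img)[2]
  acc <- array(0, dim(img))
  ts <- seq(-(L - 1) / 2, (L - 1) / 2)
  for (t in ts) {
    dx <- round(cos(angle) * t); dy <- round(sin(angle) * t)
    xs <- pmin(pmax(seq_len(S2) + dx, 1), S2)
    ys <- pmin(pmax(seq_len(S1) + dy, 1), S1)
    acc <- acc + img[ys, xs, , drop = FALSE]
  }
  acc / length(ts)
}

#' Generate a synthetic dataset on disk
#'
#' Renders `n_images` scenes, writes PNG images with PASCAL VOC XML and YOLO
#' txt annotations plus a YAML manifest with a 7:2:1 train/validation/test
#' split, and returns the split together with the per-scene truth metadata.
#'
#' @param n_images number of scenes.
#' @param p a [scene_params()] template; each scene i is rendered with seed
#'   `p$seed + i`.
#' @param out_dir writable output directory.
#' @param seed seed for the dataset split.
#' @return invisibly, a list with the `dataset_split`, the directory, and
#'   per-image `truth_meta`.
#' @export
generate_dataset <- function(n_images, p = scene_params(), out_dir,
                             seed = 0L) {
  stopifnot(n_images >= 10)
  for (d in c("", "images", "voc", "labels"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("scene_%04d", seq_len(n_images))
  meta <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    pi <- p
    pi$seed <- p$seed + i
    sc <- generate_scene(pi)
    png::writePNG(aperm(sc$image, c(1, 2, 3)),
                  file.path(out_dir, "images", paste0(ids[i], ".png")))
    writeLines(write_voc_xml(sc$annotations, p$image_size, p$image_size,
                             paste0(ids[i], ".png")),
               file.path(out_dir, "voc", paste0(ids[i], ".xml")))
    write_yolo_labels(voc_to_yolo(sc$annotations, p$image_size,
                                  p$image_size),
                      file.path(out_dir, "labels", paste0(ids[i], ".txt")))
    meta[[i]] <- sc$truth_meta
  }
  split <- split_dataset(ids, c(7, 2, 1), seed = seed)
  write_manifest(out_dir, split)
  invisible(list(split = split, dir = out_dir,
                 truth_meta = setNames(meta, ids)))
}

#' Load a generated dataset split into memory
#'
#' @param dir dataset directory written by [generate_dataset()].
#' @param subset `"train"`, `"val"` or `"test"`.
#' @return list of samples (`image`, `annotations`, `id`).
#' @export
load_split <- function(dir, subset = "train") {
  man <- read_manifest(dir)
  ids <- unlist(man[[subset]])
  lapply(ids, function(id) {
    img <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    y <- read_yolo_labels(file.path(dir, "labels", paste0(id, ".txt")))
    list(image = img, annotations = yolo_to_voc(y, dim(img)[2], dim(img)[1]),
         id = id)
  })
}
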