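# Experiment drivers: profiling with reduction reporting, and the
# desk-scale train/evaluate pipeline over a generated dataset directory.

#' Profile the baseline and the TRD-Net variant
#'
#' Builds both graphs at the requested scale, prints parameters (M, two
#' decimals), FLOPs (G, one decimal) and the percentage reductions of the
#' variant against the baseline, and returns the two profile reports.
#'
#' @param nc number of classes.
#' @param width_mult,depth_mult model scale (defaults: s-scale).
#' @param input_size square input size in px.
#' @param quiet suppress printing.
#' @return invisibly, list with `baseline` and `trdnet` profile reports.
#' @export
trd_profile <- function(nc = 3L, width_mult = 0.5, depth_mult = 0.33,
                        input_size = 640L, quiet = FALSE) {
  b <- build_yolov8s(nc, width_mult, depth_mult, input_size = input_size)
  t <- build_trdnet(nc, width_mult, depth_mult, input_size = input_size)
  pb <- profile_model(b, input_size = input_size)
  pt <- profile_model(t, baseline = b, input_size = input_size)
  if (!quiet) {
    cat(sprintf("baseline: %.2f M parameters, %.1f GFLOPs @ %d\n",
                pb$parameters / 1e6, pb$flops / 1e9, input_size))
    cat(sprintf("trd-net:  %.2f M parameters, %.1f GFLOPs @ %d\n",
                pt$parameters / 1e6, pt$flops / 1e9, input_size))
    cat(sprintf("reduction: %.2f%% parameters, %.2f%% FLOPs\n",
                pt$param_reduction_pct, pt$flop_reduction_pct))
    cat("SimAM added parameters: 0\n")
  }
  invisible(list(baseline = pb, trdnet = pt))
}

#' Desk-scale training configuration
#'
#' Default configuration for CPU-scale experiments: small input, tiny width
#' multiplier, few epochs, few hundred synthetic images. `full_config()`
#' records the full-scale recipe (640 px, batch 32, 200 epochs, learning
#' rate 1e-4, momentum 0.938) for users with the hardware to run it.
#'
#' @param epochs,n_images,image_size,width_mult,batch_size,lr overrides.
#' @return a named list of settings.
#' @export
desk_config <- function(epochs = 30L, n_images = 300L, image_size = 128L,
                        width_mult = 0.0625, batch_size = 8L, lr = 3e-3) {
  list(epochs = epochs, n_images = n_images, image_size = image_size,
       width_mult = width_mult, depth_mult = 0.33, batch_size = batch_size,
       lr = lr, optimizer = "adam", mosaic = FALSE,
       loss_weights = list(box = 7.5, cls = 0.5, dfl = 1.5))
}

#' @rdname desk_config
#' @export
full_config <- function() {
  list(epochs = 200L, n_images = NA_integer_, image_size = 640L,
       width_mult = 0.5, depth_mult = 0.33, batch_size = 32L,
       lr = 1e-4, optimizer = "sgd", momentum = 0.938, mosaic = TRUE,
       loss_weights = list(box = 7.5, cls = 0.5, dfl = 1.5))
}

#' Train and evaluate a detector on a generated dataset directory
#'
#' Loads the train and test splits of a dataset directory written by
#' [generate_dataset()], fits the requested variant, and evaluates mAP@0.5
#' on the test split.
#'
#' @param data_dir dataset directory with a manifest.
#' @param variant `"trdnet"` or `"yolov8s"`.
#' @param config settings list, see [desk_config()].
#' @param seed integer seed.
#' @param verbose print epoch losses.
#' @return list with the `fit`, the `eval` summary, and the loss `history`.
#' @export
trd_train_eval <- function(data_dir, variant = c("trdnet", "yolov8s"),
                           config = desk_config(), seed = 0L,
                           verbose = FALSE) {
  variant <- match.arg(variant)
  train <- load_split(data_dir, "train")
  test <- load_split(data_dir, "test")
  S <- dim(train[[1]]$image)[1]
  g <- if (variant == "trdnet")
    build_trdnet(nc = 3L, width_mult = config$width_mult,
                 depth_mult = config$depth_mult, input_size = S)
  else
    build_yolov8s(nc = 3L, width_mult = config$width_mult,
                  depth_mult = config$depth_mult, input_size = S)
  fit <- trdnet_fit(g, train, epochs = config$epochs,
                    batch_size = config$batch_size, lr = config$lr,
                    optimizer = config$optimizer,
                    mosaic = isTRUE(config$mosaic),
                    loss_weights = config$loss_weights,
                    seed = seed, verbose = verbose)
  ev <- evaluate_model(fit, test)
  list(fit = fit, eval = ev, history = fit$history)
}
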