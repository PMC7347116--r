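# U-Net construction, training and whole-image prediction.
#
# The network is a compact CPU U-Net implemented in the package's compiled
# code: a contracting path of paired 3x3 same-padding convolutions + ReLU
# with 2x2 max pooling and filter count doubling per level, an expanding
# path of nearest-neighbor up-sampling + 3x3 convolution with skip
# concatenations, and a final 1x1 convolution with sigmoid output. Same-size
# convolutions keep the output shape equal to the input shape, so whole
# panels map to whole heatmaps. Training minimizes pixel-wise binary
# cross-entropy on filled-area truth masks with the Adam optimizer.

#' Network configuration
#'
#' @param input_size Panel side in pixels; must be divisible by
#'   `2^depth` (default 512).
#' @param depth Number of down/up-sampling levels (default 4).
#' @param base_filters Filters in the first level, doubling per level
#'   (default 64; reduce for desk-scale CPU training).
#' @param epochs Training epochs (default 15).
#' @param batch_size Panels per optimizer step (default 1).
#' @param learning_rate Adam learning rate.
#' @param seed Seed for parameter initialization and epoch shuffling.
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_size = 512L, depth = 4L, base_filters = 64L,
                           epochs = 15L, batch_size = 1L,
                           learning_rate = 1e-3, seed = 1L) {
  check_scalar_num(input_size, "input_size", min = 2)
  check_scalar_num(depth, "depth", min = 1)
  check_scalar_num(base_filters, "base_filters", min = 1)
  check_scalar_num(epochs, "epochs", min = 1)
  check_scalar_num(batch_size, "batch_size", min = 1)
  check_scalar_num(learning_rate, "learning_rate", min = 1e-12)
  if (input_size %% 2^depth != 0)
    stop("`input_size` must be divisible by 2^depth")
  structure(list(input_size = as.integer(input_size),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "network_config")
}

# (C_in, C_out, kernel) of every conv layer in engine order.
unet_layer_dims <- function(depth, base_filters) {
  f <- function(i) base_filters * 2^i
  dims <- list()
  for (i in 0:(depth - 1)) {
    cin <- if (i == 0) 1 else f(i - 1)
    dims[[length(dims) + 1]] <- c(cin, f(i), 3)
    dims[[length(dims) + 1]] <- c(f(i), f(i), 3)
  }
  dims[[length(dims) + 1]] <- c(f(depth - 1), f(depth), 3)
  dims[[length(dims) + 1]] <- c(f(depth), f(depth), 3)
  for (i in (depth - 1):0) {
    dims[[length(dims) + 1]] <- c(f(i + 1), f(i), 3)      # up-conv
    dims[[length(dims) + 1]] <- c(2 * f(i), f(i), 3)      # after concat
    dims[[length(dims) + 1]] <- c(f(i), f(i), 3)
  }
  dims[[length(dims) + 1]] <- c(f(0), 1, 1)               # sigmoid head
  dims
}

#' Build an untrained U-Net
#'
#' Parameters are He-initialized (normal with sd `sqrt(2 / fan_in)`) from
#' the configuration seed, so identical configurations give identical
#' initial models.
#'
#' @param config A [network_config()].
#' @return An object of class `unet_model` with elements `config` and
#'   `params`.
#' @export
build_unet <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  dims <- unet_layer_dims(config$depth, config$base_filters)
  params <- with_seed(config$seed, lapply(dims, function(d) {
    fan_in <- d[1] * d[3]^2
    list(W = matrix(rnorm(d[2] * d[1] * d[3]^2, 0, sqrt(2 / fan_in)),
                    d[2], d[1] * d[3]^2),
         b = rep(0, d[2]))
  }))
  structure(list(config = config, params = params), class = "unet_model")
}

#' Apply a model forward pass to one panel
#'
#' @param model A `unet_model`, or a `unet_checkpoint`.
#' @param panel Intensity matrix on the 0-255 scale (divided by 255
#'   internally); both dimensions must be divisible by `2^depth`.
#' @return Matrix of per-pixel probabilities in `[0, 1]`.
#' @export
unet_forward <- function(model, panel) {
  cfg <- model$config
  if (any(dim(panel) %% 2^cfg$depth != 0))
    stop("panel dimensions must be divisible by 2^depth")
  cpp_unet_predict(model$params, panel / 255, cfg$depth)
}

#' Train a U-Net on MNG panels
#'
#' Runs `config$epochs` passes over the full augmented panel set, each epoch
#' starting from the parameters (and optimizer state) left by the previous
#' one, and snapshots the model after every epoch. The loss is pixel-wise
#' binary cross-entropy against the panels' filled-area mask patches.
#'
#' @param model A `unet_model` from [build_unet()].
#' @param panels Nonempty list of `mng_panel` objects whose patches are
#'   `config$input_size` squared.
#' @param config Optional [network_config()] overriding `model$config`.
#' @return List of `unet_checkpoint` objects (one per epoch), each with
#'   `epoch`, `params`, `loss` and `config`.
#' @export
train_unet <- function(model, panels, config = model$config) {
  stopifnot(inherits(model, "unet_model"))
  if (length(panels) == 0) stop("cannot train on an empty panel list")
  P <- config$input_size
  ok <- vapply(panels, function(p) all(dim(p$image_patch) == c(P, P)) &&
                 all(dim(p$mask_patch) == c(P, P)), logical(1))
  if (!all(ok)) stop("all panels must match the configured input_size")
  X <- lapply(panels, function(p) p$image_patch / 255)
  Y <- lapply(panels, function(p) (p$mask_patch > 0) * 1)
  n <- length(panels)
  ord <- with_seed(stage_seed(config$seed, "shuffle"), {
    o <- matrix(0L, config$epochs, n)
    for (e in seq_len(config$epochs)) o[e, ] <- sample.int(n)
    o
  })
  res <- cpp_unet_train(model$params, X, Y, ord, config$depth,
                        config$learning_rate, 0.9, 0.999, 1e-8,
                        config$batch_size)
  lapply(seq_len(config$epochs), function(e)
    structure(list(epoch = e, params = res$checkpoints[[e]],
                   loss = res$losses[e], config = config),
              class = "unet_checkpoint"))
}

#' @export
print.unet_checkpoint <- function(x, ...) {
  cat(sprintf("<unet_checkpoint> epoch %d, training loss %.5f\n",
              x$epoch, x$loss))
  invisible(x)
}

#' Predict a whole-image MNG-likelihood heatmap
#'
#' Tiles the image (see [tile_for_inference()]), applies the checkpoint to
#' every tile, stitches the per-tile predictions by averaging overlaps, and
#' scales model probabilities `p` to integer brightness `round(255 * p)`.
#'
#' @param checkpoint A `unet_checkpoint` (or `unet_model`).
#' @param image A [slide_image()] or intensity matrix.
#' @param panel_size Tile side; defaults to the training input size.
#' @param stride Tiling stride; defaults to `panel_size / 2` (overlapping
#'   tiles with mean blending).
#' @return Integer heatmap matrix in `[0, 255]` with attributes
#'   `checkpoint_epoch` and `source_id`.
#' @export
predict_heatmap <- function(checkpoint, image,
                            panel_size = checkpoint$config$input_size,
                            stride = panel_size / 2) {
  m <- if (inherits(image, "slide_image")) image$pixels else image
  tiles <- tile_for_inference(m, panel_size, stride)
  heat_tiles <- lapply(tiles, function(t) {
    p <- cpp_unet_predict(checkpoint$params, t$tile / 255,
                          checkpoint$config$depth)
    list(tile = 255 * p, x_offset = t$x_offset, y_offset = t$y_offset)
  })
  h <- stitch(heat_tiles, dim(m))
  attr(h, "checkpoint_epoch") <- checkpoint$epoch
  attr(h, "source_id") <- if (inherits(image, "slide_image"))
    paste(image$slide_id, image$slice_id, sep = "/") else NA_character_
  h
}

#' Save / load a checkpoint
#'
#' Checkpoints are written with R's native serialization; a run of
#' [train_unet()] is typically stored as `run_<id>/epoch_<NN>.rds` together
#' with a JSON manifest of the configuration and per-epoch losses (see
#' [run_command()]).
#'
#' @param checkpoint A `unet_checkpoint`.
#' @param path File path.
#' @return `path` (`save_checkpoint`) or the checkpoint (`load_checkpoint`).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "unet_checkpoint")) stop("not a checkpoint file: ", path)
  ckpt
}
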