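# Panel sampling, dihedral augmentation, and whole-image tiling/stitching.

#' Configuration for MNG-centered panel sampling
#'
#' @param panels_per_mng Panels sampled per annotated MNG (study value 500;
#'   reducible for desk-scale runs).
#' @param panel_size Side of the square panel, pixels (>= 32 and even).
#' @param seed Integer seed; identical seeds give identical panel sets.
#' @param edge_policy `"clip_shift"` (default) shifts windows that would
#'   leave the image back inside it; `"reflect_pad"` mirror-pads instead,
#'   which also supports images smaller than the panel.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(panels_per_mng = 500L, panel_size = 512L,
                                seed = 1L,
                                edge_policy = c("clip_shift", "reflect_pad")) {
  check_scalar_num(panels_per_mng, "panels_per_mng", min = 1)
  check_scalar_num(panel_size, "panel_size", min = 32)
  if (panel_size %% 2 != 0) stop("`panel_size` must be even")
  structure(list(panels_per_mng = as.integer(panels_per_mng),
                 panel_size = as.integer(panel_size),
                 seed = as.integer(seed),
                 edge_policy = match.arg(edge_policy)),
            class = "augmentation_config")
}

new_panel <- function(image_patch, mask_patch, slide_id, slice_id,
                      x_offset, y_offset, transform_index = 0L) {
  structure(list(image_patch = image_patch, mask_patch = mask_patch,
                 source = list(slide_id = slide_id, slice_id = slice_id,
                               x_offset = x_offset, y_offset = y_offset,
                               transform_index = as.integer(transform_index))),
            class = "mng_panel")
}

reflect_pad_matrix <- function(m, top, bottom, left, right) {
  # symmetric (edge-repeating) reflection, periodic so pads may exceed the
  # image size
  refl <- function(i, n) {
    p <- (i - 1) %% (2 * n)
    ifelse(p < n, p + 1, 2 * n - p)
  }
  ri <- refl(seq(1 - top, nrow(m) + bottom), nrow(m))
  ci <- refl(seq(1 - left, ncol(m) + right), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Sample MNG-centered training panels
#'
#' For every annotated MNG, draws `panels_per_mng` square windows whose
#' extent contains the MNG center, with the center's within-panel position
#' uniform random. This randomized placement both augments translations and
#' enlarges the negative (background) area seen in training. Mask patches
#' are the matching crops of the truth mask.
#'
#' @param image A [slide_image()].
#' @param mask Truth mask aligned with `image`
#'   (see [rasterize_annotations()]).
#' @param annotations List of [mng_annotation()] on `image`.
#' @param config An [augmentation_config()].
#' @return List of panels (class `mng_panel`), `panels_per_mng` per
#'   annotation, in annotation order.
#' @export
sample_mng_panels <- function(image, mask, annotations, config) {
  stopifnot(inherits(image, "slide_image"),
            inherits(config, "augmentation_config"))
  px <- image$pixels
  if (!all(dim(mask) == dim(px))) stop("mask is not aligned with image")
  bad <- vapply(annotations, function(a) !identical(a$slide_id, image$slide_id),
                logical(1))
  if (any(bad)) stop("annotations do not belong to this image")
  P <- config$panel_size
  H <- nrow(px); W <- ncol(px)
  if (config$edge_policy == "clip_shift" && (H < P || W < P))
    stop("image smaller than panel_size (use edge_policy = 'reflect_pad')")
  with_seed(config$seed, {
    out <- vector("list", length(annotations) * config$panels_per_mng)
    n <- 0L
    for (a in annotations) {
      cx <- round(a$center[1]); cy <- round(a$center[2])
      for (k in seq_len(config$panels_per_mng)) {
        u <- sample.int(P, 1) - 1L  # center position within the panel
        v <- sample.int(P, 1) - 1L
        x0 <- cx - u; y0 <- cy - v
        if (config$edge_policy == "clip_shift") {
          x0 <- max(0, min(x0, W - P))
          y0 <- max(0, min(y0, H - P))
          ip <- px[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P), drop = FALSE]
          mp <- mask[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P), drop = FALSE]
        } else {
          padl <- max(0, -x0); padt <- max(0, -y0)
          padr <- max(0, x0 + P - W); padb <- max(0, y0 + P - H)
          ppx <- reflect_pad_matrix(px, padt, padb, padl, padr)
          pmk <- reflect_pad_matrix(mask, padt, padb, padl, padr)
          ip <- ppx[(y0 + padt + 1):(y0 + padt + P),
                    (x0 + padl + 1):(x0 + padl + P), drop = FALSE]
          mp <- pmk[(y0 + padt + 1):(y0 + padt + P),
                    (x0 + padl + 1):(x0 + padl + P), drop = FALSE]
        }
        n <- n + 1L
        out[[n]] <- new_panel(ip, mp, image$slide_id, image$slice_id,
                              x0, y0)
      }
    }
    out
  })
}

# The 8 symmetries of the square. k = 0..3: rotation by 90k degrees
# counter-applied clockwise; k = 4..7: horizontal flip followed by rotation
# by 90(k-4) degrees. k = 0 is the identity.
dihedral_transform_matrix <- function(m, k) {
  stopifnot(k %in% 0:7)
  if (k >= 4) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  r <- k %% 4
  for (i in seq_len(r)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  m
}

#' Expand a panel by the 8 dihedral symmetries of the square
#'
#' Applies all eight unique combinations of horizontal/vertical flips and
#' 90/180 degree rotations identically to the image and mask patches.
#' Output `transform_index` runs 0-7 with 0 the identity.
#'
#' @param panel A square `mng_panel`.
#' @return List of 8 panels.
#' @export
dihedral_expand <- function(panel) {
  stopifnot(inherits(panel, "mng_panel"))
  if (nrow(panel$image_patch) != ncol(panel$image_patch))
    stop("dihedral expansion requires a square panel")
  lapply(0:7, function(k) {
    p <- panel
    p$image_patch <- dihedral_transform_matrix(panel$image_patch, k)
    p$mask_patch <- dihedral_transform_matrix(panel$mask_patch, k)
    p$source$transform_index <- as.integer(k)
    p
  })
}

#' Dump panels to paired PNG files with a provenance manifest
#'
#' Writes `image_XXXX.png` / `mask_XXXX.png` pairs plus `manifest.json`
#' recording each panel's source slide, offsets and transform index.
#'
#' @param panels List of `mng_panel` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_panels <- function(panels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- vector("list", length(panels))
  for (k in seq_along(panels)) {
    write_slide_image(panels[[k]]$image_patch,
                      file.path(dir, sprintf("image_%04d.png", k)))
    write_slide_image(panels[[k]]$mask_patch * 255,
                      file.path(dir, sprintf("mask_%04d.png", k)))
    manifest[[k]] <- panels[[k]]$source
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

tile_offsets <- function(extent, panel_size, stride) {
  offs <- seq(0L, extent - panel_size, by = stride)
  if (offs[length(offs)] != extent - panel_size)
    offs <- c(offs, extent - panel_size)
  as.integer(offs)
}

#' Tile an image for whole-image inference
#'
#' Covers every pixel at least once with `panel_size` square tiles at the
#' given stride; when the stride does not divide evenly, the final tile of
#' each row/column is shifted inward so no padding is needed.
#'
#' @param image A [slide_image()] or intensity matrix.
#' @param panel_size Tile side, pixels.
#' @param stride Step between tile origins (>= 1).
#' @return List of `list(tile, x_offset, y_offset)` with 0-based offsets.
#' @export
tile_for_inference <- function(image, panel_size, stride) {
  m <- if (inherits(image, "slide_image")) image$pixels else image
  check_scalar_num(stride, "stride", min = 1)
  if (nrow(m) < panel_size || ncol(m) < panel_size)
    stop("image smaller than panel_size in at least one dimension")
  xo <- tile_offsets(ncol(m), panel_size, stride)
  yo <- tile_offsets(nrow(m), panel_size, stride)
  out <- list()
  for (y0 in yo) for (x0 in xo)
    out[[length(out) + 1]] <-
      list(tile = m[(y0 + 1):(y0 + panel_size),
                    (x0 + 1):(x0 + panel_size), drop = FALSE],
           x_offset = x0, y_offset = y0)
  out
}

#' Stitch per-tile heat predictions into a whole-image heatmap
#'
#' Each output pixel is the arithmetic mean of all tile predictions that
#' cover it, rounded to an integer in `[0, 255]`. With non-overlapping
#' tiles this inverts [tile_for_inference()] exactly.
#'
#' @param heat_tiles List of `list(tile, x_offset, y_offset)` where `tile`
#'   holds values on the 0-255 scale (fractional values allowed before
#'   rounding).
#' @param shape Integer `(height, width)` of the output.
#' @return Integer matrix in `[0, 255]`.
#' @export
stitch <- function(heat_tiles, shape) {
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0L, shape[1], shape[2])
  for (t in heat_tiles) {
    h <- nrow(t$tile); w <- ncol(t$tile)
    ri <- (t$y_offset + 1):(t$y_offset + h)
    ci <- (t$x_offset + 1):(t$x_offset + w)
    acc[ri, ci] <- acc[ri, ci] + t$tile
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  if (any(cnt == 0)) stop("tiles do not cover every pixel of `shape`")
  clamp255(round(acc / cnt))
}
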