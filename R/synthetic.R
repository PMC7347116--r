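# Synthetic histology generator.
#
# Emulates hematoxylin-stained fetal testis sections at 1 micron/pixel:
# a light background, dense dark nuclei, mononucleated germ cells rendered
# as a single nucleus inside a cytoplasm rim, and rarer multinucleated germ
# cells (MNGs) rendered as two or more touching nuclei inside one cytoplasm
# boundary. Every MNG carries a ground-truth filled polygon, so all
# downstream stages are testable without real slides.

#' Configuration for a synthetic testis-section scene
#'
#' Defaults describe an "easy", high-contrast scene: nuclei are dark on a
#' light background and MNG nuclei form one compact clump clearly larger
#' than any single nucleus. Intensities are gray levels (0-255); lengths
#' are microns (1 px = 1 um).
#'
#' @param image_shape Integer `(height, width)`.
#' @param n_mononucleated Number of mononucleated cells (not annotated).
#' @param n_mng Number of multinucleated germ cells (annotated).
#' @param nuclei_per_mng Integer range `(min, max)` of nuclei per MNG,
#'   min >= 2.
#' @param nucleus_radius Range `(min, max)` of nucleus radii, um.
#' @param cell_margin Cytoplasm rim width beyond the nuclei, um.
#' @param background_mean,background_sd Background intensity model.
#' @param nucleus_mean,nucleus_sd Nucleus intensity model.
#' @param cytoplasm_mean,cytoplasm_sd Cytoplasm intensity model.
#' @param noise_sd Additive pixel noise applied to the whole scene.
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(192L, 192L),
                         n_mononucleated = 50L,
                         n_mng = 2L,
                         nuclei_per_mng = c(2L, 4L),
                         nucleus_radius = c(3.5, 5),
                         cell_margin = 3,
                         background_mean = 205, background_sd = 4,
                         nucleus_mean = 70, nucleus_sd = 6,
                         cytoplasm_mean = 150, cytoplasm_sd = 6,
                         noise_sd = 4,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  check_scalar_num(n_mononucleated, "n_mononucleated", min = 0)
  check_scalar_num(n_mng, "n_mng", min = 0)
  if (length(nuclei_per_mng) != 2 || nuclei_per_mng[1] < 2 ||
      nuclei_per_mng[2] < nuclei_per_mng[1])
    stop("`nuclei_per_mng` must be an increasing range with min >= 2")
  if (length(nucleus_radius) != 2 || any(nucleus_radius <= 0))
    stop("`nucleus_radius` must be a positive range")
  check_scalar_num(cell_margin, "cell_margin", min = 0)
  check_scalar_num(noise_sd, "noise_sd", min = 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_mononucleated = as.integer(n_mononucleated),
                 n_mng = as.integer(n_mng),
                 nuclei_per_mng = as.integer(nuclei_per_mng),
                 nucleus_radius = as.numeric(nucleus_radius),
                 cell_margin = as.numeric(cell_margin),
                 background_mean = background_mean,
                 background_sd = background_sd,
                 nucleus_mean = nucleus_mean, nucleus_sd = nucleus_sd,
                 cytoplasm_mean = cytoplasm_mean,
                 cytoplasm_sd = cytoplasm_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

# 0-based pixel coordinates of the disk of radius r around (cx, cy),
# restricted to the image.
disk_pixels <- function(cx, cy, r, H, W) {
  xs <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
  g <- expand.grid(x = xs, y = ys)
  g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, , drop = FALSE]
}

paint <- function(canvas, px, mean, sd) {
  if (nrow(px) == 0) return(canvas)
  idx <- cbind(px$y + 1, px$x + 1)
  canvas[idx] <- rnorm(nrow(px), mean, sd)
  canvas
}

# Rejection-sample non-overlapping object centers. `radii` are bounding
# radii; placement fails after `max_tries` rejections per object.
place_centers <- function(n, radii, H, W, existing = NULL, max_tries = 200) {
  centers <- existing
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    r <- radii[i]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cx <- runif(1, r, W - 1 - r)
      cy <- runif(1, r, H - 1 - r)
      if (is.null(centers) ||
          all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 >
              (centers[, 3] + r + 1)^2)) {
        centers <- rbind(centers, c(cx, cy, r))
        out[i, ] <- c(cx, cy)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("scene too small to place requested objects without overlap")
  }
  list(centers = out, all = centers)
}

#' Generate a synthetic testis-section scene with known MNG ground truth
#'
#' Renders `n_mng` multinucleated germ cells (each a cytoplasm blob
#' containing >= 2 dark, touching nuclei) and `n_mononucleated`
#' single-nucleus cells that are deliberately NOT annotated. The annotation
#' polygon of each MNG is the convex hull of its nuclei dilated by
#' `cell_margin`; the truth mask is exactly the rasterization of the
#' returned polygons.
#'
#' @param config A [scene_config()].
#' @param slide_id,slice_id Identity given to the generated image.
#' @return A list of class `mng_scene` with elements `image`
#'   ([slide_image()]), `annotations` (list of [mng_annotation()]) and
#'   `mask` (0/1 matrix).
#' @export
generate_scene <- function(config = scene_config(), slide_id = "synthetic",
                           slice_id = "s1") {
  stopifnot(inherits(config, "scene_config"))
  H <- config$image_shape[1]; W <- config$image_shape[2]
  with_seed(config$seed, {
    canvas <- matrix(rnorm(H * W, config$background_mean,
                           config$background_sd), H, W)
    rmax <- config$nucleus_radius[2]
    mng_bound <- 2.2 * rmax + config$cell_margin
    placed <- NULL
    annotations <- list()
    if (config$n_mng > 0) {
      pl <- place_centers(config$n_mng, rep(mng_bound, config$n_mng), H, W,
                          max_tries = 200)
      placed <- pl$all
      for (i in seq_len(config$n_mng)) {
        ctr <- pl$centers[i, ]
        k <- sample(config$nuclei_per_mng[1]:config$nuclei_per_mng[2], 1)
        radii <- runif(k, config$nucleus_radius[1], config$nucleus_radius[2])
        ang0 <- runif(1, 0, 2 * pi)
        nuc <- matrix(0, k, 2)
        nuc[1, ] <- ctr
        if (k > 1) for (j in 2:k) {
          a <- ang0 + 2 * pi * (j - 2) / max(1, k - 1) +
            runif(1, -0.2, 0.2)
          d <- 0.9 * (radii[1] + radii[j])
          nuc[j, ] <- ctr + d * c(cos(a), sin(a))
        }
        # cytoplasm boundary: convex hull of circle samples dilated by the
        # cell margin
        th <- seq(0, 2 * pi, length.out = 25)[-25]
        pts <- do.call(rbind, lapply(seq_len(k), function(j)
          cbind(nuc[j, 1] + (radii[j] + config$cell_margin) * cos(th),
                nuc[j, 2] + (radii[j] + config$cell_margin) * sin(th))))
        hull <- pts[chull(pts), , drop = FALSE]
        cyt <- cpp_fill_polygon(hull, H, W)
        cyt_px <- which(cyt == 1, arr.ind = TRUE)
        canvas <- paint(canvas,
                        data.frame(x = cyt_px[, 2] - 1, y = cyt_px[, 1] - 1),
                        config$cytoplasm_mean, config$cytoplasm_sd)
        for (j in seq_len(k))
          canvas <- paint(canvas,
                          disk_pixels(nuc[j, 1], nuc[j, 2], radii[j], H, W),
                          config$nucleus_mean, config$nucleus_sd)
        annotations[[i]] <- mng_annotation(colMeans(nuc), hull,
                                           slide_id = slide_id,
                                           slice_id = slice_id)
      }
    }
    if (config$n_mononucleated > 0) {
      mono_bound <- rmax + config$cell_margin
      pl <- place_centers(config$n_mononucleated,
                          rep(mono_bound, config$n_mononucleated), H, W,
                          existing = placed, max_tries = 200)
      for (i in seq_len(config$n_mononucleated)) {
        ctr <- pl$centers[i, ]
        r <- runif(1, config$nucleus_radius[1], config$nucleus_radius[2])
        canvas <- paint(canvas,
                        disk_pixels(ctr[1], ctr[2], r + config$cell_margin,
                                    H, W),
                        config$cytoplasm_mean, config$cytoplasm_sd)
        canvas <- paint(canvas, disk_pixels(ctr[1], ctr[2], r, H, W),
                        config$nucleus_mean, config$nucleus_sd)
      }
    }
    canvas <- canvas + rnorm(H * W, 0, config$noise_sd)
    img <- slide_image(clamp255(round(canvas)), 1,
                       slide_id = slide_id, slice_id = slice_id)
    mask <- rasterize_annotations(annotations, c(H, W))
    structure(list(image = img, annotations = annotations, mask = mask),
              class = "mng_scene")
  })
}

#' Generate a set of scenes with distinct slide identities
#'
#' Scene `i` uses seed `stage_seed(config$seed + i, "scene")`. If a seed
#' happens to produce an unplaceable object layout, the scene retries with
#' deterministically bumped seeds (up to 5 attempts) before failing, so a
#' set generation is reproducible yet robust to rare rejection-sampling
#' dead ends.
#'
#' @param n Number of scenes.
#' @param config Base [scene_config()].
#' @return List of `mng_scene` objects.
#' @export
generate_scene_set <- function(n, config = scene_config()) {
  lapply(seq_len(n), function(i) {
    ci <- config
    last <- NULL
    for (attempt in 0:4) {
      ci$seed <- stage_seed(config$seed + i + 99991L * attempt, "scene")
      s <- tryCatch(generate_scene(ci, slide_id = sprintf("synthetic_%03d", i)),
                    error = function(e) e)
      if (!inherits(s, "error")) return(s)
      last <- s
    }
    stop(last)
  })
}

#' Idealized heatmap from a truth mask
#'
#' Stands in for a network prediction so post-processing can be tested in
#' isolation: `255 * mask`, optionally blurred with a Gaussian of standard
#' deviation `blur_radius` (pixels) and corrupted with additive Gaussian
#' noise, then rounded and clamped to `[0, 255]`. With
#' `blur_radius = 0` and `noise_sd = 0` the output is exactly `255 * mask`.
#'
#' @param mask 0/1 matrix.
#' @param blur_radius Gaussian sigma in pixels (>= 0).
#' @param noise_sd Additive noise standard deviation (>= 0).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return Integer matrix in `[0, 255]` of the same shape as `mask`.
#' @export
oracle_heatmap <- function(mask, blur_radius = 0, noise_sd = 0, seed = 1L) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  check_scalar_num(blur_radius, "blur_radius", min = 0)
  check_scalar_num(noise_sd, "noise_sd", min = 0)
  h <- 255 * mask
  if (blur_radius > 0) {
    hw <- ceiling(3 * blur_radius)
    k <- dnorm(-hw:hw, sd = blur_radius)
    k <- k / sum(k)
    h <- apply(h, 2, blur_1d, k = k)
    h <- t(apply(h, 1, blur_1d, k = k))
  }
  if (noise_sd > 0)
    h <- with_seed(seed, h + rnorm(length(h), 0, noise_sd))
  clamp255(round(h))
}

# zero-padded 1-D convolution with a centered odd kernel
blur_1d <- function(x, k) {
  hw <- (length(k) - 1) / 2
  xp <- c(rep(0, hw), x, rep(0, hw))
  out <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(out[(hw + 1):(hw + length(x))])
}
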