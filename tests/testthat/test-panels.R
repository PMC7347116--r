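test_that("panel sampling contains every MNG center and is deterministic", {
  s <- tiny_scene(seed = 31)
  cfg <- augmentation_config(panels_per_mng = 25, panel_size = 64, seed = 4)
  panels <- sample_mng_panels(s$image, s$mask, s$annotations, cfg)
  expect_length(panels, 2 * 25)
  for (k in seq_along(panels)) {
    a <- s$annotations[[ceiling(k / 25)]]
    x0 <- panels[[k]]$source$x_offset; y0 <- panels[[k]]$source$y_offset
    expect_true(round(a$center[1]) >= x0 &&
                  round(a$center[1]) <= x0 + 63 &&
                  round(a$center[2]) >= y0 &&
                  round(a$center[2]) <= y0 + 63)
    # mask patch contains the MNG center pixel, so it is nonzero
    expect_gt(sum(panels[[k]]$mask_patch), 0)
    # patches really are crops of the source
    expect_equal(panels[[k]]$image_patch,
                 s$image$pixels[(y0 + 1):(y0 + 64), (x0 + 1):(x0 + 64)])
    expect_equal(panels[[k]]$mask_patch,
                 s$mask[(y0 + 1):(y0 + 64), (x0 + 1):(x0 + 64)])
  }
  expect_equal(panels, sample_mng_panels(s$image, s$mask, s$annotations, cfg))
})

test_that("clip_shift keeps windows inside the image for centers near all 4 edges", {
  # a 40x40 image with an MNG-like square polygon near each edge
  px <- matrix(100, 40, 40)
  img <- slide_image(px, slide_id = "edge")
  mk_ann <- function(cx, cy)
    mng_annotation(c(cx, cy),
                   rbind(c(cx - 2, cy - 2), c(cx + 2, cy - 2),
                         c(cx + 2, cy + 2), c(cx - 2, cy + 2)),
                   slide_id = "edge")
  anns <- list(mk_ann(3, 20), mk_ann(36, 20), mk_ann(20, 3), mk_ann(20, 36))
  mask <- rasterize_annotations(anns, c(40, 40))
  cfg <- augmentation_config(panels_per_mng = 40, panel_size = 32, seed = 9)
  panels <- sample_mng_panels(img, mask, anns, cfg)
  for (k in seq_along(panels)) {
    a <- anns[[ceiling(k / 40)]]
    x0 <- panels[[k]]$source$x_offset; y0 <- panels[[k]]$source$y_offset
    # brute-force window-containment check: window in bounds AND center in window
    expect_true(x0 >= 0 && y0 >= 0 && x0 + 32 <= 40 && y0 + 32 <= 40)
    expect_true(a$center[1] >= x0 && a$center[1] <= x0 + 31)
    expect_true(a$center[2] >= y0 && a$center[2] <= y0 + 31)
  }
})

test_that("images smaller than the panel need reflect_pad", {
  s <- tiny_scene(seed = 33)
  cfg <- augmentation_config(panels_per_mng = 2, panel_size = 128, seed = 1)
  expect_error(sample_mng_panels(s$image, s$mask, s$annotations, cfg),
               "smaller than panel_size")
  cfg$edge_policy <- "reflect_pad"
  panels <- sample_mng_panels(s$image, s$mask, s$annotations, cfg)
  expect_length(panels, 4)
  for (p in panels) expect_equal(dim(p$image_patch), c(128L, 128L))
})

test_that("dihedral expansion enumerates the 8 square symmetries", {
  p <- mngdetect:::new_panel(matrix(c(1, 3, 2, 4), 2, 2),
                             matrix(c(1, 3, 2, 4), 2, 2), "s", "s", 0, 0)
  e <- dihedral_expand(p)
  expect_length(e, 8)
  expect_equal(vapply(e, function(x) x$source$transform_index, 0L), 0:7)
  got <- lapply(e, function(x) x$image_patch)
  # hand-enumerated arrangements of [[1,2],[3,4]] (rows top to bottom)
  expected <- list(
    rbind(c(1, 2), c(3, 4)),  # identity
    rbind(c(3, 1), c(4, 2)),  # rot 90 cw
    rbind(c(4, 3), c(2, 1)),  # rot 180
    rbind(c(2, 4), c(1, 3)),  # rot 270 cw
    rbind(c(2, 1), c(4, 3)),  # horizontal flip
    rbind(c(4, 2), c(3, 1)),  # flip then rot 90
    rbind(c(3, 4), c(1, 2)),  # flip then rot 180 (= vertical flip)
    rbind(c(1, 3), c(2, 4)))  # flip then rot 270
  for (k in 1:8) expect_equal(unname(got[[k]]), expected[[k]])
  expect_length(unique(lapply(got, c)), 8)
  # image and mask receive the identical permutation
  for (x in e) expect_equal(x$image_patch, x$mask_patch)
})

test_that("the dihedral transform set is closed (group property)", {
  set.seed(5)
  m <- matrix(sample(0:255, 36), 6, 6)
  base <- lapply(0:7, function(k)
    mngdetect:::dihedral_transform_matrix(m, k))
  canon <- function(x) paste(x, collapse = ",")
  base_set <- sort(vapply(base, canon, ""))
  for (start in 1:8) {
    regenerated <- lapply(0:7, function(k)
      mngdetect:::dihedral_transform_matrix(base[[start]], k))
    expect_equal(sort(vapply(regenerated, canon, "")), base_set)
  }
  # constant panels are invariant
  cp <- mngdetect:::new_panel(matrix(7, 4, 4), matrix(1, 4, 4), "s", "s", 0, 0)
  for (x in dihedral_expand(cp)) expect_equal(x$image_patch, matrix(7, 4, 4))
  # non-square panels are rejected
  np <- mngdetect:::new_panel(matrix(0, 3, 4), matrix(0, 3, 4), "s", "s", 0, 0)
  expect_error(dihedral_expand(np), "square")
})

test_that("tiling covers every pixel and shifts the final tile inward", {
  expect_length(tile_for_inference(matrix(0, 512, 512), 512, 512), 1)
  expect_length(tile_for_inference(matrix(0, 1024, 1024), 512, 512), 4)
  t7 <- tile_for_inference(matrix(0, 700, 700), 512, 512)
  expect_length(t7, 4)
  offs <- unique(vapply(t7, function(t) t$x_offset, 0L))
  expect_equal(sort(offs), c(0L, 188L))
  # brute-force coverage check
  cov <- matrix(0, 700, 700)
  for (t in t7)
    cov[(t$y_offset + 1):(t$y_offset + 512),
        (t$x_offset + 1):(t$x_offset + 512)] <-
      cov[(t$y_offset + 1):(t$y_offset + 512),
          (t$x_offset + 1):(t$x_offset + 512)] + 1
  expect_true(all(cov >= 1))
  expect_error(tile_for_inference(matrix(0, 100, 100), 512, 512), "smaller")
})

test_that("stitching averages overlaps and inverts exact tilings", {
  hm <- matrix(sample(0:255, 96 * 96, replace = TRUE), 96, 96)
  tiles <- tile_for_inference(hm, 32, 32)
  expect_equal(unname(stitch(tiles, c(96, 96))), unname(hm))
  # overlapping constant tiles average
  t2 <- list(list(tile = matrix(100, 4, 8), x_offset = 0L, y_offset = 0L),
             list(tile = matrix(200, 4, 8), x_offset = 4L, y_offset = 0L))
  st <- stitch(t2, c(4, 12))
  expect_true(all(st[, 1:4] == 100))
  expect_true(all(st[, 5:8] == 150))
  expect_true(all(st[, 9:12] == 200))
  expect_error(stitch(t2, c(5, 12)), "cover")
})
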