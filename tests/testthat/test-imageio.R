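test_that("slide images validate intensities and dimensions", {
  expect_s3_class(slide_image(matrix(0:255, 16, 16)), "slide_image")
  expect_error(slide_image(matrix(-1, 2, 2)), "0, 255")
  expect_error(slide_image(matrix(0.5, 2, 2)), "integers")
  expect_error(slide_image(matrix(numeric(0), 0, 0)), ">= 1")
})

test_that("PNG loading is an identity at matched resolution", {
  m <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  tf <- withr::local_tempfile(fileext = ".png")
  write_slide_image(m, tf)
  im <- load_slide_image(tf, 1, 1)
  expect_equal(unname(im$pixels), unname(m))
  expect_equal(im$microns_per_pixel, 1)
})

test_that("resampling follows the scale arithmetic and preserves uniform intensity", {
  tf <- withr::local_tempfile(fileext = ".png")
  write_slide_image(matrix(137, 128, 128), tf)
  im <- load_slide_image(tf, 0.5, 1)  # 0.5 um/px down to 1 um/px
  expect_equal(dim(im$pixels), c(64L, 64L))
  expect_true(all(abs(im$pixels - 137) <= 2))
  # non-integer factor
  im2 <- load_slide_image(tf, 0.7, 1)
  expect_equal(dim(im2$pixels), c(90L, 90L))
  expect_true(all(abs(im2$pixels - 137) <= 2))
})

test_that("uniform RGB converts to the same uniform gray", {
  tf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(100 / 255, c(20, 20, 3)), tf)
  im <- load_slide_image(tf)
  expect_true(all(im$pixels == 100))
  # BT.601 weighting of a pure-channel image
  arr <- array(0, c(10, 10, 3)); arr[, , 2] <- 1
  png::writePNG(arr, tf)
  expect_true(all(load_slide_image(tf)$pixels == round(0.587 * 255)))
})

test_that("unreadable files and bad scales raise errors", {
  expect_error(load_slide_image("no/such/file.png"), "not found")
  tf <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", tf)
  expect_error(load_slide_image(tf), "decode")
  tf2 <- withr::local_tempfile(fileext = ".png")
  write_slide_image(matrix(0, 8, 8), tf2)
  expect_error(load_slide_image(tf2, -1, 1), "source_microns_per_pixel")
  expect_error(load_slide_image(tf2, 1, 0), "target_microns_per_pixel")
})

test_that("rasterization matches brute-force point-in-polygon", {
  # axis-aligned square with integer corners
  sq <- rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))
  m <- rasterize_annotations(list(mng_annotation(c(15, 15), sq)), c(30, 30))
  expect_equal(sum(m), 11 * 11)
  expect_equal(unname(m), unname(oracle_rasterize(sq, 30, 30)))
  # random simple (convex-hull) polygons with fractional vertices
  set.seed(7)
  for (k in 1:10) {
    pts <- cbind(runif(8, 2, 27), runif(8, 2, 27))
    poly <- pts[chull(pts), , drop = FALSE]
    got <- rasterize_annotations(
      list(mng_annotation(colMeans(poly), poly)), c(30, 30))
    expect_equal(unname(got), unname(oracle_rasterize(poly, 30, 30)))
  }
})

test_that("overlapping polygons union and empty lists give empty masks", {
  expect_equal(sum(rasterize_annotations(list(), c(10, 10))), 0)
  a1 <- mng_annotation(c(3, 3), rbind(c(1, 1), c(6, 1), c(6, 6), c(1, 6)))
  a2 <- mng_annotation(c(12, 3), rbind(c(10, 1), c(15, 1), c(15, 6), c(10, 6)))
  m <- rasterize_annotations(list(a1, a2), c(20, 20))
  expect_equal(sum(m), 36 + 36)  # disjoint shapes add
  m2 <- rasterize_annotations(list(a1, a1), c(20, 20))
  expect_equal(sum(m2), 36)      # union, not sum
})

test_that("annotation JSON round-trips losslessly and rejects bad records", {
  s <- tiny_scene(seed = 5)
  tf <- withr::local_tempfile(fileext = ".json")
  write_annotations(s$annotations, tf)
  expect_equal(read_annotations(tf), s$annotations)
  write_annotations(list(), tf)
  expect_equal(read_annotations(tf), list())
  # 2-vertex polygon in the file is a parse-time validation error
  writeLines(paste0('[{"slide_id":"s","slice_id":"t","center":[1,1],',
                    '"polygon":[[0,0],[2,2]]}]'), tf)
  expect_error(read_annotations(tf), "< 3 vertices")
  writeLines("{broken", tf)
  expect_error(read_annotations(tf), "cannot parse")
})

test_that("annotation invariants are enforced at construction", {
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  expect_error(mng_annotation(c(10, 10), sq), "inside")
  expect_error(mng_annotation(c(1, 1), sq[1:2, ]), ">= 3")
  bow <- rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4))  # self-intersecting
  expect_error(mng_annotation(c(2, 2), bow), "simple")
})
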