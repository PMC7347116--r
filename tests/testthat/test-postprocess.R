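test_that("brightness cutoff keeps values >= cutoff", {
  hm <- rbind(c(239, 240, 241), c(255, 0, 100))
  expect_equal(sum(apply_brightness_cutoff(hm, 240)), 3)
  expect_true(all(apply_brightness_cutoff(hm, 0) == 1))
  expect_equal(sum(apply_brightness_cutoff(hm, 255)), 1)
  expect_error(apply_brightness_cutoff(hm, 300), "cutoff")
  expect_error(apply_brightness_cutoff(hm, -1), "cutoff")
})

test_that("connected components respect the chosen connectivity", {
  m <- matrix(0L, 5, 5)
  m[2, 2] <- 1L; m[3, 3] <- 1L  # diagonal touch
  expect_length(connected_components(m, 8), 1)
  expect_length(connected_components(m, 4), 2)
  expect_length(connected_components(matrix(0L, 4, 4)), 0)
  expect_error(connected_components(m, 6), "connectivity")
})

test_that("component labelling agrees with an independent flood fill", {
  set.seed(42)
  for (k in 1:20) {
    m <- matrix(rbinom(20 * 20, 1, 0.35), 20, 20)
    for (conn in c(4, 8)) {
      comps <- connected_components(m, conn)
      lab <- oracle_label(m, conn)
      expect_length(comps, max(lab))
      # identical partition: each package component maps to one oracle label
      for (px in comps) {
        labs <- lab[cbind(px[, 2] + 1, px[, 1] + 1)]
        expect_length(unique(labs), 1)
        expect_equal(nrow(px), sum(lab == labs[1]))
      }
    }
  }
})

test_that("Green's areas follow the closed form for solid rectangles", {
  for (w in c(2, 3, 7)) for (h in c(2, 5, 9)) {
    px <- as.matrix(expand.grid(x = 0:(w - 1), y = 0:(h - 1)))
    ra <- region_area(px)
    expect_equal(ra$greens_area, (w - 1) * (h - 1))
  }
  # 3x3 square: boundary through the 8 outer pixel centers
  px <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  expect_equal(nrow(region_area(px)$boundary_polygon), 8)
  # degenerate regions have zero area
  expect_equal(region_area(cbind(x = 0:4, y = rep(0, 5)))$greens_area, 0)
  expect_equal(region_area(cbind(x = 3, y = 3))$greens_area, 0)
  expect_error(region_area(matrix(0, 0, 2)), "empty")
})

test_that("Green's areas match an independent triangulation oracle on random blobs", {
  set.seed(8)
  for (k in 1:60) {
    blob <- random_blob()
    comps <- connected_components(blob, 8)
    expect_length(comps, 1)  # blobs are connected by construction
    ra <- region_area(comps[[1]])
    expect_equal(ra$greens_area, oracle_polygon_area(ra$boundary_polygon),
                 tolerance = 1e-12)
    expect_lte(ra$greens_area, nrow(comps[[1]]))
  }
})

test_that("area filtering keeps exactly the regions at or above the cutoff", {
  mk <- function(a) list(greens_area = a)
  regions <- lapply(c(0, 4, 160), mk)
  expect_length(filter_regions(regions, 150), 1)
  expect_length(filter_regions(regions, 0), 3)
  expect_length(filter_regions(regions, 200), 0)
  expect_length(filter_regions(regions, 160), 1)  # inclusive threshold
  expect_error(filter_regions(regions, -5), "cutoff_area")
})

test_that("detect composes the stages and reports centroids and areas", {
  hm <- matrix(0L, 64, 64)
  hm[21:40, 11:30] <- 255L  # 20x20 square
  d <- detect(hm, 128, 150)
  expect_length(d$regions, 1)
  expect_equal(d$regions[[1]]$greens_area, 361)  # (20-1)^2
  expect_equal(unname(d$regions[[1]]$centroid), c((10 + 29) / 2, (20 + 39) / 2))
  expect_length(detect(matrix(0L, 16, 16), 128, 10)$regions, 0)
})

test_that("nearby blobs separate at a high cutoff and merge at a low one", {
  # two plateaus at 250 joined by a bridge at 200
  hm <- matrix(0L, 30, 60)
  hm[11:20, 6:20] <- 250L
  hm[11:20, 31:45] <- 250L
  hm[14:17, 21:30] <- 200L
  expect_length(detect(hm, 240, 10)$regions, 2)
  expect_length(detect(hm, 150, 10)$regions, 1)
})

test_that("detection is monotone in both cutoffs and deterministic", {
  s <- tiny_scene(seed = 51)
  hm <- oracle_heatmap(s$mask, 2, 25, seed = 5)
  n_px <- sapply(c(60, 120, 180, 240), function(b)
    sum(apply_brightness_cutoff(hm, b)))
  expect_true(all(diff(n_px) <= 0))
  n_det_a <- sapply(c(0, 20, 80, 200, 1000), function(a)
    length(detect(hm, 120, a)$regions))
  expect_true(all(diff(n_det_a) <= 0))
  expect_identical(detect(hm, 120, 20), detect(hm, 120, 20))
})

test_that("detections round-trip through the JSON interface", {
  hm <- matrix(0L, 32, 32); hm[5:14, 5:14] <- 255L; hm[20:28, 18:27] <- 255L
  d <- detect(hm, 128, 10)
  tf <- withr::local_tempfile(fileext = ".json")
  write_detections(d, tf)
  d2 <- read_detections(tf, c(32, 32))
  expect_equal(length(d2$regions), length(d$regions))
  expect_equal(d2$cutoff_brightness, d$cutoff_brightness)
  expect_equal(d2$cutoff_area, d$cutoff_area)
  for (k in seq_along(d$regions)) {
    expect_equal(d2$regions[[k]]$greens_area, d$regions[[k]]$greens_area)
    expect_equal(unname(d2$regions[[k]]$centroid),
                 unname(d$regions[[k]]$centroid))
  }
})
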