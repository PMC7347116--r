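test_that("stratification structure: sorted groups, one slide per group per fold", {
  set.seed(2)
  counts <- setNames(sample(0:160, 28), sprintf("sl%02d", 1:28))
  fa <- stratify_slides(counts, 5)
  tab <- fa$table
  expect_equal(nrow(tab), 28)
  expect_equal(as.integer(table(tab$group)), c(5L, 5L, 5L, 5L, 5L, 3L))
  # groups are consecutive chunks of the count-sorted slides
  expect_true(all(diff(tab$count) <= 0))
  for (g in unique(tab$group)) {
    folds <- tab$fold[tab$group == g]
    expect_equal(length(folds), length(unique(folds)))
  }
  expect_equal(sum(fa$fold_totals), sum(counts))
  expect_error(stratify_slides(c(a = 1, b = 2), 5), "at least")
})

test_that("stratification with equal counts balances folds exactly", {
  fa <- stratify_slides(setNames(rep(7, 5), letters[1:5]), 5)
  expect_equal(var(fa$fold_totals), 0)
  expect_equal(unname(fa$fold_totals), rep(7, 5))
})

test_that("stratification attains the exhaustive minimum variance on small instances", {
  set.seed(4)
  for (rep in 1:3) {
    counts <- setNames(sample(1:40, 10), sprintf("s%02d", 1:10))
    fa <- stratify_slides(counts, 5)
    # brute force over all valid assignments: permutations within both
    # count-sorted groups of 5
    sorted <- sort(counts, decreasing = TRUE)
    perms <- mngdetect:::all_permutations(5)
    best <- Inf
    for (i in seq_len(nrow(perms))) for (j in seq_len(nrow(perms))) {
      totals <- rep(0, 5)
      totals[perms[i, ]] <- totals[perms[i, ]] + sorted[1:5]
      totals[perms[j, ]] <- totals[perms[j, ]] + sorted[6:10]
      best <- min(best, var(totals))
    }
    expect_equal(var(fa$fold_totals), best)
  }
})

test_that("stratification is no worse than sorted round-robin", {
  set.seed(9)
  counts <- setNames(sample(0:100, 13), sprintf("s%02d", 1:13))
  fa <- stratify_slides(counts, 5)
  sorted <- sort(counts, decreasing = TRUE)
  rr <- tapply(sorted, rep_len(1:5, 13), sum)
  expect_lte(var(fa$fold_totals), var(as.numeric(rr)))
})

test_that("fold configurations rotate test after holdout with wraparound", {
  fc <- fold_configurations(5)
  expect_length(fc, 5)
  expect_equal(fc[[1]]$holdout, 0L)
  expect_equal(fc[[1]]$test, 1L)
  expect_equal(sort(fc[[1]]$train), c(2L, 3L, 4L))
  expect_equal(fc[[5]]$holdout, 4L)
  expect_equal(fc[[5]]$test, 0L)  # wraps back to fold 0
  expect_equal(sort(vapply(fc, function(x) x$holdout, 0L)), 0:4)
  for (x in fc) expect_length(c(x$train, x$test, x$holdout), 5)
  expect_error(fold_configurations(2), "at least 3")
})

test_that("grid-point selection equals a brute-force scan with the stated tie-break", {
  set.seed(6)
  grid <- expand.grid(epoch = 1:3, brightness = c(100L, 180L, 240L),
                      area = c(10, 150))
  grid$f1 <- runif(nrow(grid))
  k <- select_optimal(grid)
  expect_equal(grid$f1[k], max(grid$f1))
  # brute-force scan with explicit tie rule
  brute <- function(g) {
    cand <- which(g$f1 == max(g$f1))
    cand <- cand[g$epoch[cand] == min(g$epoch[cand])]
    cand <- cand[g$brightness[cand] == max(g$brightness[cand])]
    cand[which.max(g$area[cand])]
  }
  expect_equal(k, brute(grid))
  # forced ties
  grid$f1 <- rep(0.5, nrow(grid))
  k2 <- select_optimal(grid)
  expect_equal(grid$epoch[k2], 1L)
  expect_equal(grid$brightness[k2], 240L)
  expect_equal(grid$area[k2], 150)
  expect_equal(k2, brute(grid))
  # 1-point grid
  expect_equal(select_optimal(grid[4, ]), 1L)
})

test_that("grid search pools counts over images and records the full grid", {
  s <- tiny_scene(seed = 73)
  ck <- constant_model(0.01, input_size = 32, depth = 2)
  gs <- grid_search(list(ck), list(s$image), list(s$annotations),
                    brightness_grid = c(100L, 200L), area_grid = c(10, 50),
                    panel_size = 32, stride = 32)
  expect_equal(nrow(gs$grid), 4)
  expect_true(all(gs$grid$tp == 0))
  expect_true(all(gs$grid$fn == 2))
  expect_true(all(gs$grid$f1 == 0))
  expect_equal(gs$optimal$epoch, 1L)
  expect_error(grid_search(list(ck), list(), list(),
                           c(100L), c(10)), "empty test set")
})

test_that("holdout evaluation applies the selected parameters unchanged", {
  s <- tiny_scene(seed = 72)
  ck <- constant_model(0.95, input_size = 32, depth = 2)
  gs <- grid_search(list(ck), list(s$image), list(s$annotations),
                    brightness_grid = c(250L), area_grid = c(1e6),
                    panel_size = 32, stride = 32)
  # holdout identical to test set reproduces the test F1
  ho <- evaluate_holdout(gs, list(ck), list(s$image), list(s$annotations),
                         panel_size = 32, stride = 32)
  expect_equal(ho$counts$tp, gs$test_counts$tp)
  expect_equal(ho$counts$fp, gs$test_counts$fp)
  expect_equal(ho$counts$fn, gs$test_counts$fn)
})
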