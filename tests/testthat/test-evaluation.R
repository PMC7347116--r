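test_that("count identities hold for trivial matchings", {
  s <- tiny_scene(seed = 61)
  shape <- dim(s$mask)
  empty <- detect(matrix(0L, shape[1], shape[2]), 128, 10)
  cc <- match_detections(empty, s$annotations, shape)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(0L, 0L, 2L))
  # detections exactly equal to the rasterized annotations
  perfect <- detect(oracle_heatmap(s$mask, 0, 0), 128, 0)
  cc2 <- match_detections(perfect, s$annotations, shape)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(2L, 0L, 0L))
  cc3 <- match_detections(perfect, list(), shape)
  expect_equal(c(cc3$tp, cc3$fp, cc3$fn), c(0L, 2L, 0L))
})

test_that("matching is one-to-one: 3 detections, 2 annotations, 1 overlap", {
  # one detection overlapping one annotation, two detections in background
  hm <- matrix(0L, 40, 40)
  hm[6:10, 6:10] <- 255L     # overlaps annotation 1
  hm[25:28, 25:28] <- 255L   # background
  hm[33:36, 5:8] <- 255L     # background
  anns <- list(
    mng_annotation(c(7, 7), rbind(c(4, 4), c(11, 4), c(11, 11), c(4, 11))),
    mng_annotation(c(18, 33), rbind(c(15, 30), c(21, 30), c(21, 36),
                                    c(15, 36))))
  d <- detect(hm, 128, 0)
  cc <- match_detections(d, anns, c(40, 40))
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(1L, 2L, 1L))
})

test_that("greedy matching attains the optimal matching size on small instances", {
  set.seed(12)
  for (rep in 1:15) {
    n_obj <- sample(2:4, 1)
    anns <- list(); hm <- matrix(0L, 60, 60)
    for (k in seq_len(n_obj)) {
      cx <- sample(8:50, 1); cy <- sample(8:50, 1)
      anns[[k]] <- mng_annotation(
        c(cx, cy), rbind(c(cx - 4, cy - 4), c(cx + 4, cy - 4),
                         c(cx + 4, cy + 4), c(cx - 4, cy + 4)))
      # jittered detection blob near (or on) the annotation
      dx <- sample(-5:5, 1); dy <- sample(-5:5, 1)
      hm[pmax(1, pmin(60, (cy + dy - 2):(cy + dy + 2))),
         pmax(1, pmin(60, (cx + dx - 2):(cx + dx + 2)))] <- 255L
    }
    d <- detect(hm, 128, 0)
    cc <- match_detections(d, anns, c(60, 60))
    # candidate pairs for the brute-force oracle
    pairs <- matrix(0L, 0, 2)
    for (i in seq_along(d$regions)) {
      for (j in seq_along(anns)) {
        ov <- sum(apply(d$regions[[i]]$pixel_set, 1, function(p)
          oracle_point_in_polygon(p[1], p[2], anns[[j]]$polygon)))
        cin <- oracle_point_in_polygon(d$regions[[i]]$centroid[1],
                                       d$regions[[i]]$centroid[2],
                                       anns[[j]]$polygon)
        if (ov >= 1 || cin) pairs <- rbind(pairs, c(i, j))
      }
    }
    opt <- oracle_max_matching(pairs, length(d$regions), length(anns))
    expect_equal(cc$tp, opt)
    # count identities hold for any input
    expect_equal(cc$tp + cc$fp, length(d$regions))
    expect_equal(cc$tp + cc$fn, length(anns))
  }
})

test_that("precision/recall/F1 reproduce the published scorer values", {
  r1 <- precision_recall_f1(confusion_counts(34, 10, 11))
  expect_equal(round(r1$f1, 3), 0.764)
  r2 <- precision_recall_f1(confusion_counts(95, 10, 41))
  expect_equal(round(r2$f1, 3), 0.788)
  r3 <- precision_recall_f1(confusion_counts(91, 27, 17))
  expect_equal(round(r3$f1, 3), 0.805)
  perfect <- precision_recall_f1(confusion_counts(7, 0, 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  zero <- precision_recall_f1(confusion_counts(0, 3, 2))
  expect_equal(zero$f1, 0)
  expect_error(precision_recall_f1(confusion_counts(0, 0, 0)), "undefined")
})

test_that("F1 is the harmonic mean and scale-invariant", {
  set.seed(3)
  for (k in 1:10) {
    tp <- sample(1:50, 1); fp <- sample(0:30, 1); fn <- sample(0:30, 1)
    r <- precision_recall_f1(confusion_counts(tp, fp, fn))
    expect_equal(r$f1, 2 / (1 / r$precision + 1 / r$recall))
    expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
    expect_lte(r$f1, 2 * min(r$precision, r$recall) + 1e-12)
    for (s in c(2, 5)) {
      rs <- precision_recall_f1(confusion_counts(s * tp, s * fp, s * fn))
      expect_equal(rs$f1, r$f1)
    }
  }
})

test_that("FP:FN ratio handles the degenerate cases", {
  expect_equal(round(fp_fn_ratio(confusion_counts(91, 27, 17)), 2), 1.59)
  expect_equal(fp_fn_ratio(confusion_counts(5, 0, 3)), 0)
  expect_error(fp_fn_ratio(confusion_counts(5, 2, 0)), "undefined")
})

test_that("aggregation uses the sample (n-1) standard deviation", {
  a <- aggregate_scores(c(2, 4, 6))
  expect_equal(a$mean, 4)
  expect_equal(a$sd, 2)
  single <- aggregate_scores(5)
  expect_equal(single$mean, 5)
  expect_true(is.na(single$sd))
  expect_error(aggregate_scores(numeric(0)), "empty")
})

test_that("evaluation tables give one row per image", {
  tab <- evaluation_table(list(confusion_counts(3, 1, 0),
                               confusion_counts(2, 0, 2)),
                          ids = c("a", "b"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$f1[1], precision_recall_f1(confusion_counts(3, 1, 0))$f1)
  expect_named(tab, c("id", "tp", "fp", "fn", "precision", "recall", "f1"))
})
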