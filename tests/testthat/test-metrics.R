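# COCO-style evaluator: IoU, matching, AP/AR properties, and equivalence
# with the independent external evaluator.

test_that("box IoU matches hand-computed cases", {
  b <- c(0, 0, 2, 2)
  expect_identical(pairwise_iou(b, b), 1)
  expect_identical(pairwise_iou(b, c(5, 5, 2, 2)), 0)
  expect_equal(pairwise_iou(c(0, 0, 2, 2), c(1, 0, 2, 2)), 1 / 3)
  m1 <- matrix(TRUE, 4, 4); m2 <- matrix(FALSE, 4, 4); m2[1:2, ] <- TRUE
  expect_equal(pairwise_iou(m1, m2), 0.5)
  expect_identical(pairwise_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
  expect_error(pairwise_iou(b, m1), "mixed")
})

test_that("greedy matching yields the worked-example counts", {
  gts <- rbind(c(0, 0, 10, 10), c(20, 20, 10, 10), c(40, 40, 10, 10))
  perfect <- list(boxes = gts, scores = c(0.9, 0.8, 0.7))
  r <- match_predictions(gts, perfect, 0.5)
  expect_identical(r$counts, list(TP = 3L, FP = 0L, FN = 0L))
  expect_identical(c(r$precision, r$recall), c(1, 1))

  two <- rbind(c(0, 0, 10, 10), c(20, 20, 10, 10))
  preds <- list(boxes = rbind(c(0, 0, 10, 10), c(70, 70, 5, 5)),
                scores = c(0.9, 0.8))
  r <- match_predictions(two, preds, 0.5)
  expect_identical(r$counts, list(TP = 1L, FP = 1L, FN = 1L))
  expect_identical(c(r$precision, r$recall), c(0.5, 0.5))

  dup <- list(boxes = rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)),
              scores = c(0.9, 0.8))
  r <- match_predictions(gts[1, , drop = FALSE], dup, 0.5)
  expect_identical(r$counts, list(TP = 1L, FP = 1L, FN = 0L))
  expect_identical(r$tp_flags, c(TRUE, FALSE))
})

test_that("AP is 1 for a perfect detector and 0 for an empty one", {
  gts <- lapply(1:3, function(i)
    list(boxes = rbind(c(0, 0, 10, 10), c(30, 5, 8, 12))))
  perfect <- lapply(gts, function(g)
    list(boxes = g$boxes, scores = c(0.9, 0.8)))
  expect_equal(as.numeric(average_precision(gts, perfect)), 1)
  silent <- lapply(gts, function(g)
    list(boxes = matrix(numeric(0), 0, 4), scores = numeric(0)))
  expect_equal(as.numeric(average_precision(gts, silent)), 0)
  # no ground truths anywhere: sentinel
  empty_gt <- lapply(1:2, function(i) list(boxes = matrix(numeric(0), 0, 4)))
  expect_equal(as.numeric(average_precision(empty_gt, silent[1:2])), -1)
})

test_that("AR truncation arithmetic: 5 gts, one perfect top-1 detection", {
  gts <- list(list(boxes = cbind(seq(0, 80, 20), 0, 10, 10)))
  preds <- list(list(boxes = gts[[1]]$boxes, scores = c(0.99, 0.5, 0.4, 0.3, 0.2)))
  expect_equal(average_recall(gts, preds, 1), 1 / 5)
  expect_equal(average_recall(gts, preds, 10), 1)
})

test_that("AR is monotone in the detection cap and AP non-increasing in IoU", {
  samples <- make_tiny_samples(4, seed = 400)
  gt <- gt_from_samples(samples)
  res <- perturb_predictions(gt, seed = 5)
  rep <- evaluate(gt, res, "bbox")
  expect_lte(rep$AR1, rep$AR10)
  expect_lte(rep$AR10, rep$AR100)
  expect_lte(rep$AP, rep$AP50)
  # per-image structures for the per-threshold monotonicity property
  core_gt <- vineseg:::coco_gt_to_core(gt, "bbox")$per
  dts <- lapply(seq_along(core_gt), function(i) {
    sel <- Filter(function(r) r$image_id == i, res)
    list(boxes = do.call(rbind, lapply(sel, function(r) r$bbox)),
         scores = vapply(sel, function(r) r$score, 1))
  })
  ap_t <- attr(average_precision(core_gt, dts), "per_threshold")
  expect_true(all(diff(ap_t) <= 1e-12))
})

test_that("metrics are invariant to image order", {
  samples <- make_tiny_samples(4, seed = 410)
  gt <- gt_from_samples(samples)
  res <- perturb_predictions(gt, seed = 6)
  r1 <- evaluate(gt, res, "bbox")
  # permute image ids consistently
  perm <- c(3L, 1L, 4L, 2L)
  gt2 <- gt
  gt2$images <- lapply(gt$images, function(im) { im$id <- perm[im$id]; im })
  gt2$annotations <- lapply(gt$annotations, function(a) {
    a$image_id <- perm[a$image_id]; a
  })
  res2 <- lapply(res, function(r) { r$image_id <- perm[r$image_id]; r })
  r2 <- evaluate(gt2, res2, "bbox")
  for (k in c("AP", "AP50", "AP75", "AR1", "AR10", "AR100"))
    expect_equal(r1[[k]], r2[[k]])
})

test_that("ground truth evaluated against itself scores 1 everywhere", {
  samples <- make_tiny_samples(3, seed = 420)
  gt <- gt_from_samples(samples)
  res <- lapply(gt$annotations, function(a)
    list(image_id = a$image_id, category_id = 1L, bbox = a$bbox,
         score = 1, segmentation = a$segmentation))
  for (task in c("bbox", "segm")) {
    r <- evaluate(gt, res, task)
    for (k in c("AP", "AP50", "AP75", "AR10", "AR100"))
      expect_equal(r[[k]], 1)
  }
  r0 <- evaluate(gt, list(), "bbox")
  for (k in c("AP", "AP50", "AP75", "AR1", "AR10", "AR100"))
    expect_equal(r0[[k]], 0)
})

test_that("results for unknown image ids are rejected with the orphans named", {
  samples <- make_tiny_samples(2, seed = 430)
  gt <- gt_from_samples(samples)
  res <- list(list(image_id = 99L, category_id = 1L,
                   bbox = c(0, 0, 5, 5), score = 0.5))
  expect_error(evaluate(gt, res, "bbox"), "99")
})

test_that("evaluator equals the independent oracle on random fixtures", {
  dir <- withr::local_tempdir()
  generate_dataset(scene_config(image_height = 160, image_width = 160,
                                seed = 500, scale_regime = "far"), 10, dir)
  gt_json <- file.path(dir, "gt.json")
  labelme_to_coco(dir, gt_json)
  gt <- read_coco(gt_json)
  res <- perturb_predictions(gt, seed = 7)
  res_json <- write_results_json(res, file.path(dir, "res.json"))
  for (task in c("bbox", "segm")) {
    mine <- evaluate(gt_json, res_json, task)
    oracle <- run_eval_oracle(gt_json, res_json, task)
    for (k in c("AP", "AP50", "AP75", "AR1", "AR10", "AR100"))
      expect_lt(abs(mine[[k]] - oracle[[k]]), 1e-6)
  }
})

test_that("run-length masks round-trip exactly", {
  set.seed(44)
  for (rep in 1:5) {
    m <- matrix(runif(30 * 17) > 0.6, 30, 17)
    expect_identical(rle_decode(rle_encode(m)), m)
  }
  empty <- matrix(FALSE, 5, 4)
  expect_identical(rle_decode(rle_encode(empty)), empty)
})
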