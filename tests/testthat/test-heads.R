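# Anchors, proposals, RoIAlign semantics, mask loss, loss combination,
# prediction contracts.

test_that("the published anchor sets combine into exactly 15 templates", {
  tpl <- build_anchor_templates()
  expect_identical(nrow(tpl), 15L)
  expect_identical(tpl$scale, rep(c(8, 16, 32, 64, 128), each = 3))
  expect_identical(tpl$aspect_ratio, rep(c(0.5, 1, 2), 5))
  expect_identical(sort(unique(tpl$level)), 2:6)
  expect_error(build_anchor_templates(numeric(0)), "empty")
  expect_error(build_anchor_templates(c(-8, 16)), "positive")
})

test_that("anchor geometry preserves area across aspect ratios", {
  tpl <- build_anchor_templates()
  sq <- tpl[tpl$scale == 8 & tpl$aspect_ratio == 1, ]
  expect_identical(c(sq$width, sq$height), c(8, 8))
  half <- tpl[tpl$aspect_ratio == 0.5, ]
  expect_equal(half$width, round(half$scale * sqrt(2)))
  expect_equal(half$height, round(half$scale / sqrt(2)))
  expect_equal(half$height / half$width, rep(0.5, 5), tolerance = 0.1)
  for (i in seq_len(nrow(tpl)))
    expect_lt(abs(tpl$width[i] * tpl$height[i] - tpl$scale[i]^2),
              2 * tpl$scale[i] + 1)
})

test_that("anchor enumeration covers every location: H*W*3 per level", {
  m <- build_model(model_config("test"), seed = 1)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  pyr <- backbone_forward(img, m$backbone)
  anchors <- vineseg:::all_anchors(pyr, m$templates)
  for (nm in names(anchors)) {
    d <- dim(pyr[[nm]])
    expect_identical(nrow(anchors[[nm]]), d[1] * d[2] * 3L)
  }
})

test_that("zeroed RPN head gives uniform 0.5 scores and capped proposals", {
  m <- build_model(model_config("test"), seed = 2)
  for (nm in c("obj", "obj_b", "box", "box_b"))
    m$rpn[[nm]]$v <- m$rpn[[nm]]$v * 0
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  pyr <- backbone_forward(img, m$backbone)
  prop <- rpn_propose(pyr, m, c(128, 128))
  expect_true(all(prop$scores == 0.5))
  expect_identical(nrow(prop$boxes), m$config$rpn$post_nms_test)
})

test_that("proposals are clipped to the image bounds", {
  m <- build_model(model_config("test"), seed = 3)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  pyr <- backbone_forward(img, m$backbone)
  prop <- rpn_propose(pyr, m, c(128, 128))
  expect_true(all(prop$boxes >= 0))
  expect_true(all(prop$boxes[, c(1, 3)] <= 128))
  expect_true(all(prop$boxes[, c(2, 4)] <= 128))
})

test_that("RoIAlign is exact on constant and affine feature fields", {
  # constant field pools to the constant
  f <- array(3.25, c(16, 20, 2))
  out <- roi_align(f, matrix(c(2, 3, 11, 13), 1), 7, spatial_scale = 1)
  expect_identical(dim(out), c(7L, 7L, 2L, 1L))
  expect_lt(max(abs(out - 3.25)), 1e-12)
  # field linear in x reproduces the sampled x coordinates
  H <- 16L; W <- 24L
  fx <- array(0, c(H, W, 1))
  fx[, , 1] <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  box <- c(4.3, 2.1, 18.9, 11.7)
  out <- roi_align(fx, matrix(box, 1), 4, spatial_scale = 1)
  x1 <- box[1] - 0.5; x2 <- box[3] - 0.5
  bw <- (x2 - x1) / 4
  expected <- x1 + (seq_len(4) - 1) * bw + 0.5 * bw
  for (r in 1:4) expect_equal(as.numeric(out[r, , 1, 1]), expected,
                              tolerance = 1e-5)
  # the two head grids
  expect_identical(dim(roi_align(f, matrix(c(0, 0, 5, 5), 1), 7))[1:2],
                   c(7L, 7L))
  expect_identical(dim(roi_align(f, matrix(c(0, 0, 5, 5), 1), 14))[1:2],
                   c(14L, 14L))
  expect_warning(roi_align(f, matrix(c(5, 5, 5, 9), 1), 7), "degenerate")
})

test_that("mask loss matches brute-force per-pixel cross-entropy", {
  set.seed(20)
  m <- 14L
  target <- matrix(runif(m * m) > 0.5, m, m)
  logits <- array(rnorm(m * m * 2), c(m, m, 2))
  got <- mask_loss(logits, target, class_index = 2L)
  z <- logits[, , 2]
  p <- 1 / (1 + exp(-z))
  ref <- -mean(target * log(p) + (1 - target) * log(1 - p))
  expect_lt(abs(got - ref), 1e-7)
  # only the target class slice contributes
  logits2 <- logits
  logits2[, , 1] <- rnorm(m * m)
  expect_identical(mask_loss(logits2, target, 2L), got)
})

test_that("saturated correct logits give ~0 loss; zero logits give ln 2", {
  m <- 8L
  target <- matrix(FALSE, m, m); target[3:5, 2:6] <- TRUE
  sat <- array(-20, c(m, m, 2)); sat[, , 2][target] <- 20
  expect_lt(mask_loss(sat, target, 2L), 1e-6)
  expect_equal(mask_loss(array(0, c(m, m, 2)), target, 2L), log(2),
               tolerance = 1e-12)
  expect_equal(mask_loss(array(0, c(m, m, 2)), !target, 2L), log(2),
               tolerance = 1e-12)
  expect_error(mask_loss(sat, matrix(FALSE, 4, 4), 2L), "shape")
})

test_that("the total loss is the exact sum of its three terms", {
  l <- total_loss(0, 0, 0)
  expect_identical(l$L_total, 0)
  l <- total_loss(0.5, 0.25, 0.25)
  expect_identical(l$L_total, 1)
  expect_identical(l$L_total, l$L_cls + l$L_box + l$L_mask)
  expect_error(total_loss(NaN, 0, 0), "L_cls")
  expect_error(total_loss(0, Inf, 0), "L_box")
})

test_that("prediction is deterministic and masks stay inside their boxes", {
  m <- build_model(model_config("test"), seed = 30)
  scene <- generate_scene(scene_config_tiny(seed = 7))
  d1 <- predict_instances(m, scene$image, score_threshold = 0)
  d2 <- predict_instances(m, scene$image, score_threshold = 0)
  expect_identical(d1, d2)
  expect_gt(length(d1), 0)
  expect_identical(order(-vapply(d1, function(d) d$score, 1)),
                   seq_along(d1))
  for (d in d1) {
    expect_gte(d$score, 0); expect_lte(d$score, 1)
    if (!any(d$mask)) next
    idx <- which(d$mask, arr.ind = TRUE)
    bb <- d$bbox
    expect_gte(min(idx[, 2]) - 1, floor(bb[1]))
    expect_lte(max(idx[, 2]), ceiling(bb[1] + bb[3]))
    expect_gte(min(idx[, 1]) - 1, floor(bb[2]))
    expect_lte(max(idx[, 1]), ceiling(bb[2] + bb[4]))
  }
})
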