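# Backbone: ECA kernel rule and gating, DUC sub-pixel oracle, ResNet stage
# geometry, pyramid shape contract.

test_that("adaptive kernel size follows the floor-then-odd rule", {
  expect_identical(eca_kernel_size(2), 1L)
  expect_identical(eca_kernel_size(256), 5L)
  expect_identical(eca_kernel_size(2048), 7L)
  # brute-force application of the rule for C in 2..4096
  for (C in 2:4096) {
    t <- abs(log2(C) / 2 + 1 / 2)
    k <- floor(t)
    if (k %% 2 == 0) k <- k + 1
    expect_identical(eca_kernel_size(C), as.integer(max(k, 1)))
  }
  expect_error(eca_kernel_size(0), ">= 1")
})

test_that("kernel size is odd and non-decreasing in channel count", {
  ks <- eca_kernel_size(1:4096)
  expect_true(all(ks %% 2L == 1L))
  expect_true(all(diff(ks) >= 0))
})

test_that("ECA is a sigmoid-gated pure channel rescaling", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 32), c(6, 5, 32))
  k <- rnorm(eca_kernel_size(32))
  y <- eca_forward(x, k)
  expect_identical(dim(y), dim(x))
  ratio <- y / x
  # constant ratio per channel across all spatial positions
  for (c in 1:32) {
    rc <- ratio[, , c]
    expect_lt(diff(range(rc)), 1e-12)
    expect_gt(rc[1], 0)
    expect_lt(rc[1], 1)
  }
  # zero input stays zero; zero kernel gates at exactly 0.5
  expect_identical(eca_forward(array(0, c(4, 4, 8)), numeric(3)),
                   array(0, c(4, 4, 8)))
  expect_equal(eca_forward(x, numeric(eca_kernel_size(32))), 0.5 * x)
  expect_error(eca_forward(x, numeric(4)), "odd")
})

test_that("ECA parameter count is exactly the sum of its kernel sizes", {
  bb <- build_backbone(backbone_config("full"), seed = 1)
  widths <- c(256L, 512L, 1024L, 2048L)
  expect_identical(vapply(bb$eca, function(p) length(p$v), 1L),
                   eca_kernel_size(widths))
  expect_identical(sum(vapply(bb$eca, function(p) length(p$v), 1L)),
                   sum(eca_kernel_size(widths)))
})

test_that("DUC equals the brute-force sub-pixel rearrangement oracle", {
  set.seed(2)
  for (rep in 1:3) {
    C <- sample(c(4L, 8L), 1)
    h <- sample(3:6, 1); w <- sample(3:6, 1); r <- 2L
    x <- array(rnorm(h * w * C), c(h, w, C))
    wt <- array(rnorm(9 * C * C * r^2), c(3, 3, C, C * r^2))
    b <- rnorm(C * r^2)
    y <- duc_upsample(x, wt, b, r = r)
    expect_identical(dim(y), c(h * r, w * r, C))
    inter <- vineseg:::cpp_conv2d_fwd(x, wt, b, 1L, 1L)
    # independent loop over output pixels
    for (c0 in 0:(C - 1)) for (yy in 0:(h * r - 1)) for (xx in 0:(w * r - 1)) {
      dy <- yy %% r; dx <- xx %% r
      expect_lt(abs(y[yy + 1, xx + 1, c0 + 1] -
                    inter[yy %/% r + 1, xx %/% r + 1,
                          c0 * r^2 + dy * r + dx + 1]), 1e-6)
    }
  }
})

test_that("DUC with ratio 1 is a plain 3x3 convolution", {
  set.seed(3)
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  wt <- array(rnorm(9 * 16), c(3, 3, 4, 4))
  expect_equal(duc_upsample(x, wt, r = 1),
               vineseg:::cpp_conv2d_fwd(x, wt, NULL, 1L, 1L))
})

test_that("ResNet50 stages have the published widths, strides and depth", {
  cfg <- backbone_config("full")
  expect_identical(cfg$block_counts, c(3L, 4L, 6L, 3L))
  expect_identical(sum(cfg$block_counts), 16L)
  expect_identical(cfg$stage_widths, c(256L, 512L, 1024L, 2048L))
  bb <- build_backbone(cfg, seed = 1)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  st <- resnet50_stages(img, bb)
  expect_identical(dim(st$C2), c(32L, 32L, 256L))   # 1/4
  expect_identical(dim(st$C3), c(16L, 16L, 512L))   # 1/8
  expect_identical(dim(st$C4), c(8L, 8L, 1024L))    # 1/16
  expect_identical(dim(st$C5), c(4L, 4L, 2048L))    # 1/32
  expect_error(resnet50_stages(array(0, c(32, 32, 1)), bb), "RGB")
})

test_that("smallest valid input gives a 2x2 C5", {
  bb <- build_backbone(backbone_config("test"), seed = 1)
  st <- resnet50_stages(array(runif(64 * 64 * 3), c(64, 64, 3)), bb)
  expect_identical(dim(st$C5)[1:2], c(2L, 2L))
})

test_that("pyramid levels have uniform width and exactly halving sizes", {
  bb <- build_backbone(backbone_config("test"), seed = 4)
  img <- array(runif(128 * 192 * 3), c(128, 192, 3))
  p <- backbone_forward(img, bb)
  dims <- lapply(p, dim)
  expect_identical(names(dims), paste0("P", 2:6))
  for (d in dims) expect_identical(d[3], backbone_config("test")$fpn_width)
  for (i in 1:4) {
    expect_identical(dims[[i]][1], 2L * dims[[i + 1]][1])
    expect_identical(dims[[i]][2], 2L * dims[[i + 1]][2])
  }
  expect_identical(dims$P2[1:2], c(128L %/% 4L, 192L %/% 4L))
})

test_that("zeroed convolution weights give an all-zero pyramid", {
  bb <- build_backbone(backbone_config("test"), seed = 5)
  for (p in vineseg:::collect_params(bb)) p$v <- p$v * 0
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- backbone_forward(img, bb)
  for (lv in p) expect_identical(max(abs(lv)), 0)
})

test_that("swapping DUC for nearest-neighbor changes values, never shapes", {
  bb <- build_backbone(backbone_config("test"), seed = 6)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p_duc <- backbone_forward(img, bb, upsampler = "duc")
  p_nn <- backbone_forward(img, bb, upsampler = "nearest")
  for (nm in names(p_duc)) {
    expect_identical(dim(p_duc[[nm]]), dim(p_nn[[nm]]))
  }
  expect_gt(max(abs(p_duc$P2 - p_nn$P2)), 0)
})

test_that("odd-sized inputs are padded to the stride multiple and recorded", {
  bb <- build_backbone(backbone_config("test"), seed = 7)
  img <- array(runif(100 * 70 * 3), c(100, 70, 3))
  p <- backbone_forward(img, bb)
  expect_identical(attr(p, "pad"), c(28L, 58L))
  expect_identical(dim(p$P2)[1:2], c(128L %/% 4L, 128L %/% 4L))
})
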