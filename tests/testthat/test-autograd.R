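# Reverse-mode tape: gradients agree with central finite differences
# through every layer type used by the network.

fd_check <- function(build_loss, p, tol = 1e-5) {
  p$g <- NULL  # discard any gradient accumulated by an earlier check
  vineseg:::ag_begin()
  loss <- build_loss()
  vineseg:::ag_backward(loss)
  vineseg:::ag_end()
  analytic <- as.numeric(p$g)
  p$g <- NULL
  numeric <- numeric_gradient(function(z) {
    old <- p$v
    p$v <- if (is.null(dim(old))) z else array(z, dim(old))
    on.exit(p$v <- old)
    build_loss()$v
  }, as.numeric(p$v))
  expect_lt(max(abs(analytic - numeric)), tol)
}

test_that("conv / affine / pool / gap gradients match finite differences", {
  set.seed(10)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  w <- vineseg:::vs_param(array(rnorm(3 * 3 * 3 * 4, 0, 0.3), c(3, 3, 3, 4)))
  b <- vineseg:::vs_param(rnorm(4))
  s <- vineseg:::vs_param(rnorm(4, 1, 0.1))
  sh <- vineseg:::vs_param(rnorm(4, 0, 0.1))
  g <- rnorm(4)
  build <- function() {
    xn <- vineseg:::ag_const(x)
    y <- vineseg:::ag_conv2d(xn, w, b, stride = 2L, pad = 1L)
    y <- vineseg:::ag_affine_ch(y, s, sh)
    y <- vineseg:::ag_relu(y)
    y <- vineseg:::ag_maxpool(y, 2L, 2L, 0L)
    v <- vineseg:::ag_gap(y)
    vineseg:::ag_node(sum(v$v * g), list(v),
                      backward = function(gr) list(gr * g))
  }
  for (p in list(w, b, s, sh)) fd_check(build, p)
})

test_that("ECA path (1-D channel conv) gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(5 * 5 * 8), c(5, 5, 8))
  k <- vineseg:::vs_param(rnorm(3, 0, 0.5))
  build <- function() {
    y <- eca_forward(vineseg:::ag_const(x), k)
    vineseg:::ag_node(sum(y$v^2), list(y),
                      backward = function(g) list(g * 2 * y$v))
  }
  fd_check(build, k)
})

test_that("DUC path (conv + pixel shuffle) gradients match finite differences", {
  set.seed(12)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  w <- vineseg:::vs_param(array(rnorm(3 * 3 * 4 * 16, 0, 0.2), c(3, 3, 4, 16)))
  build <- function() {
    y <- duc_upsample(vineseg:::ag_const(x), w, r = 2L)
    vineseg:::ag_node(sum(y$v^2), list(y),
                      backward = function(g) list(g * 2 * y$v))
  }
  fd_check(build, w, tol = 1e-4)
})

test_that("RoIAlign propagates gradients to the feature map", {
  set.seed(13)
  xv <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  boxes <- matrix(c(2, 2, 9, 8), 1)
  xp <- vineseg:::vs_param(xv)
  vineseg:::ag_begin()
  xn <- vineseg:::ag_leaf(xp)
  y <- vineseg:::ag_roialign(xn, boxes, 1, 4L, 4L, 2L)
  loss <- vineseg:::ag_node(sum(y$v^2), list(y),
                            backward = function(g) list(g * 2 * y$v))
  vineseg:::ag_backward(loss)
  gx <- xp$g
  vineseg:::ag_end()
  f <- function(z) sum(vineseg:::cpp_roialign_fwd(array(z, dim(xv)), boxes,
                                                  1, 4L, 4L, 2L)^2)
  expect_lt(max(abs(as.numeric(gx) - numeric_gradient(f, as.numeric(xv)))),
            1e-5)
})

test_that("loss-layer gradients match finite differences", {
  set.seed(14)
  # softmax cross-entropy
  z <- vineseg:::vs_param(matrix(rnorm(10), 5, 2))
  labels <- c(1L, 2L, 1L, 2L, 2L)
  fd_check(function() vineseg:::ag_softmax_ce(vineseg:::ag_leaf(z), labels), z)
  # smooth L1 around the kink
  d <- vineseg:::vs_param(c(-2, -0.5, 0.01, 0.4, 3))
  fd_check(function() vineseg:::ag_smooth_l1(vineseg:::ag_leaf(d),
                                             rep(0.2, 5), beta = 1 / 9,
                                             divisor = 5), d, tol = 1e-4)
  # binary cross-entropy with logits
  l <- vineseg:::vs_param(rnorm(12))
  y <- rep(c(0, 1), 6)
  fd_check(function() vineseg:::ag_bce_logits_mean(vineseg:::ag_leaf(l), y), l)
  # linear layer
  W <- vineseg:::vs_param(matrix(rnorm(12, 0, 0.3), 4, 3))
  xm <- matrix(rnorm(8), 2, 4)
  fd_check(function() {
    o <- vineseg:::ag_linear(vineseg:::ag_const(xm), W)
    vineseg:::ag_node(sum(o$v^2), list(o), backward = function(g) list(g * 2 * o$v))
  }, W)
})

test_that("gradient of the summed loss equals the sum of per-term gradients", {
  set.seed(15)
  w <- vineseg:::vs_param(matrix(rnorm(6, 0, 0.5), 3, 2))
  x <- matrix(rnorm(6), 2, 3)
  labels <- c(1L, 2L)
  term_grad <- function(which_terms) {
    vineseg:::ag_begin()
    o <- vineseg:::ag_linear(vineseg:::ag_const(x), w)
    t1 <- vineseg:::ag_softmax_ce(o, labels)
    t2 <- vineseg:::ag_smooth_l1(o, matrix(0.1, 2, 2), beta = 1, divisor = 4)
    t3 <- vineseg:::ag_bce_logits_mean(o, matrix(c(1, 0, 0, 1), 2, 2))
    total <- vineseg:::ag_sum_scalars(list(t1, t2, t3)[which_terms])
    vineseg:::ag_backward(total)
    vineseg:::ag_end()
    g <- w$g; w$g <- NULL
    g
  }
  g_sum <- term_grad(1:3)
  g_parts <- term_grad(1) + term_grad(2) + term_grad(3)
  expect_equal(g_sum, g_parts, tolerance = 1e-12)
})
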