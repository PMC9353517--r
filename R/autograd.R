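# Minimal reverse-mode autodiff tape.
#
# Nodes are environments with fields:
#   v        value (array / matrix / vector / scalar)
#   parents  list of parent nodes
#   backward function(grad) -> list of gradients, one per parent (or NULL)
#   grad     accumulated gradient (filled during ag_backward)
#   param    optional parameter environment; its $g accumulates the gradient
#
# When no tape is active (inference) nodes are created but not recorded, so
# the same forward code serves both training and prediction.

.vs_tape <- new.env(parent = emptyenv())
.vs_tape$nodes <- NULL
.vs_tape$n <- 0L
.vs_tape$active <- FALSE

ag_begin <- function() {
  .vs_tape$nodes <- vector("list", 1024L)
  .vs_tape$n <- 0L
  .vs_tape$active <- TRUE
  invisible(NULL)
}

ag_end <- function() {
  .vs_tape$nodes <- NULL
  .vs_tape$n <- 0L
  .vs_tape$active <- FALSE
  invisible(NULL)
}

ag_node <- function(value, parents = list(), backward = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  nd$param <- param
  if (.vs_tape$active) {
    n <- .vs_tape$n + 1L
    if (n > length(.vs_tape$nodes))
      .vs_tape$nodes <- c(.vs_tape$nodes, vector("list", length(.vs_tape$nodes)))
    .vs_tape$nodes[[n]] <- nd
    .vs_tape$n <- n
  }
  nd
}

ag_const <- function(value) ag_node(value)

# Parameter container: $v value, $g gradient, $m momentum buffer.
vs_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$v <- value
  p$g <- NULL
  p$m <- NULL
  p
}

ag_leaf <- function(p) ag_node(p$v, param = p)

ag_backward <- function(loss) {
  stopifnot(.vs_tape$active)
  loss$grad <- 1
  for (i in seq.int(.vs_tape$n, 1L)) {
    nd <- .vs_tape$nodes[[i]]
    g <- nd$grad
    if (is.null(g)) next
    if (!is.null(nd$param)) {
      p <- nd$param
      p$g <- if (is.null(p$g)) g else p$g + g
    }
    if (!is.null(nd$backward)) {
      gs <- nd$backward(g)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        if (is.null(gs[[j]])) next
        pj <- ps[[j]]
        pj$grad <- if (is.null(pj$grad)) gs[[j]] else pj$grad + gs[[j]]
      }
    }
    nd$grad <- NULL  # free memory as we go
  }
  invisible(NULL)
}

# --- tensor ops -------------------------------------------------------------

ag_conv2d <- function(x, wp, bp = NULL, stride = 1L, pad = 0L) {
  wn <- ag_leaf(wp)
  bn <- if (!is.null(bp)) ag_leaf(bp)
  y <- cpp_conv2d_fwd(x$v, wp$v, if (is.null(bp)) NULL else bp$v,
                      as.integer(stride), as.integer(pad))
  xv <- x$v
  wv <- wp$v
  parents <- c(list(x, wn), if (!is.null(bn)) list(bn))
  has_b <- !is.null(bp)
  ag_node(y, parents, backward = function(g) {
    r <- cpp_conv2d_bwd(xv, wv, g, as.integer(stride), as.integer(pad), has_b)
    c(list(r$gx, r$gw), if (has_b) list(r$gb))
  })
}

ag_relu <- function(x) {
  keep <- x$v > 0
  ag_node(x$v * keep, list(x), backward = function(g) list(g * keep))
}

ag_add <- function(x, y) {
  if (!identical(dim(x$v), dim(y$v)))
    stop("ag_add: shape mismatch (", paste(dim(x$v), collapse = "x"), " vs ",
         paste(dim(y$v), collapse = "x"), ")")
  ag_node(x$v + y$v, list(x, y), backward = function(g) list(g, g))
}

# per-channel affine y[, , c] = x[, , c] * s[c] + b[c] (frozen-BN form)
ag_affine_ch <- function(x, sp, bp) {
  sn <- ag_leaf(sp)
  bn <- ag_leaf(bp)
  d <- dim(x$v)
  hw <- d[1] * d[2]
  C <- d[3]
  sv <- sp$v
  xv <- x$v
  y <- x$v * rep(sv, each = hw) + rep(bp$v, each = hw)
  dim(y) <- d
  ag_node(y, list(x, sn, bn), backward = function(g) {
    gm <- matrix(g, hw, C)
    list(array(g * rep(sv, each = hw), d),
         colSums(gm * matrix(xv, hw, C)),
         colSums(gm))
  })
}

ag_maxpool <- function(x, k, stride, pad = 0L) {
  r <- cpp_maxpool_fwd(x$v, as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(x$v)
  ag_node(r$y, list(x), backward = function(g)
    list(cpp_maxpool_bwd(r$idx, g, as.integer(xd))))
}

# global average pool (H,W,C) -> length-C vector
ag_gap <- function(x) {
  d <- dim(x$v)
  hw <- d[1] * d[2]
  y <- colMeans(matrix(x$v, hw, d[3]))
  ag_node(y, list(x), backward = function(g)
    list(array(rep(g / hw, each = hw), d)))
}

# zero-padded 1-D correlation along a vector (used across the channel axis)
corr1d <- function(v, kern, pad) {
  k <- length(kern)
  vp <- c(numeric(pad), v, numeric(pad))
  n <- length(v)
  m <- matrix(0, n, k)
  for (j in seq_len(k)) m[, j] <- vp[seq_len(n) + j - 1L]
  drop(m %*% kern)
}

ag_conv1d_vec <- function(x, kp) {
  kn <- ag_leaf(kp)
  k <- length(kp$v)
  if (k %% 2L == 0L) stop("1-D channel convolution requires an odd kernel")
  pad <- (k - 1L) %/% 2L
  xv <- x$v
  kv <- kp$v
  y <- corr1d(xv, kv, pad)
  ag_node(y, list(x, kn), backward = function(g) {
    n <- length(xv)
    vp <- c(numeric(pad), xv, numeric(pad))
    m <- matrix(0, n, k)
    for (j in seq_len(k)) m[, j] <- vp[seq_len(n) + j - 1L]
    list(corr1d(g, rev(kv), pad), drop(crossprod(m, g)))
  })
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$v))
  ag_node(y, list(x), backward = function(g) list(g * y * (1 - y)))
}

# multiply each channel of x (H,W,C) by w[c]
ag_scale_channels <- function(x, w) {
  d <- dim(x$v)
  hw <- d[1] * d[2]
  xv <- x$v
  wv <- w$v
  y <- x$v * rep(wv, each = hw)
  dim(y) <- d
  ag_node(y, list(x, w), backward = function(g)
    list(array(g * rep(wv, each = hw), d),
         colSums(matrix(g, hw, d[3]) * matrix(xv, hw, d[3]))))
}

# periodic sub-pixel rearrangement: (H, W, C*r^2) -> (H*r, W*r, C).
# Intermediate channel c*r^2 + dy*r + dx (0-based) lands on output pixel
# (y*r + dy, x*r + dx) of channel c.
ag_pixel_shuffle <- function(x, r) {
  d <- dim(x$v)
  if (d[3] %% (r * r) != 0L) stop("pixel shuffle: channels not divisible by r^2")
  C <- d[3] %/% (r * r)
  perm <- c(4L, 1L, 3L, 2L, 5L)
  iperm <- order(perm)
  x5 <- array(x$v, c(d[1], d[2], r, r, C))
  y <- array(aperm(x5, perm), c(d[1] * r, d[2] * r, C))
  ag_node(y, list(x), backward = function(g) {
    g5 <- array(g, c(r, d[1], r, d[2], C))
    list(array(aperm(g5, iperm), d))
  })
}

ag_upsample_nearest <- function(x, r) {
  d <- dim(x$v)
  y <- x$v[rep(seq_len(d[1]), each = r), rep(seq_len(d[2]), each = r), ,
           drop = FALSE]
  ag_node(y, list(x), backward = function(g) {
    g5 <- array(g, c(r, d[1], r, d[2], d[3]))
    list(apply(g5, c(2, 4, 5), sum))
  })
}

ag_roialign <- function(x, boxes, scale, oh, ow, sampling = 2L) {
  d <- dim(x$v)
  y <- cpp_roialign_fwd(x$v, boxes, scale, as.integer(oh), as.integer(ow),
                        as.integer(sampling))
  ag_node(y, list(x), backward = function(g)
    list(cpp_roialign_bwd(g, boxes, scale, d[1], d[2], d[3],
                          as.integer(oh), as.integer(ow),
                          as.integer(sampling))))
}

# (oh, ow, C, n) pooled block -> (n, oh*ow*C) row-per-roi matrix
ag_pool_to_mat <- function(x) {
  d <- dim(x$v)
  k <- d[1] * d[2] * d[3]
  y <- t(matrix(x$v, k, d[4]))
  ag_node(y, list(x), backward = function(g) list(array(t(g), d)))
}

ag_slice_roi <- function(x, i) {
  d <- dim(x$v)
  y <- array(x$v[, , , i], d[1:3])
  ag_node(y, list(x), backward = function(g) {
    gx <- array(0, d)
    gx[, , , i] <- g
    list(gx)
  })
}

ag_linear <- function(x, wp, bp = NULL) {
  wn <- ag_leaf(wp)
  bn <- if (!is.null(bp)) ag_leaf(bp)
  y <- x$v %*% wp$v
  if (!is.null(bp)) y <- sweep(y, 2, bp$v, "+")
  xv <- x$v
  wv <- wp$v
  parents <- c(list(x, wn), if (!is.null(bn)) list(bn))
  ag_node(y, parents, backward = function(g) {
    c(list(g %*% t(wv), crossprod(xv, g)),
      if (!is.null(bn)) list(colSums(g)))
  })
}

ag_rbind <- function(nodes) {
  if (length(nodes) == 1L) return(nodes[[1L]])
  rows <- vapply(nodes, function(n) nrow(n$v), 1L)
  y <- do.call(rbind, lapply(nodes, function(n) n$v))
  ends <- cumsum(rows)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(y, nodes, backward = function(g)
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE]))
}

ag_rows <- function(x, idx) {
  d2 <- ncol(x$v)
  nall <- nrow(x$v)
  ag_node(x$v[idx, , drop = FALSE], list(x), backward = function(g) {
    gx <- matrix(0, nall, d2)
    gx[idx, ] <- gx[idx, ] + g
    list(gx)
  })
}

# gather arbitrary flat indices (must be unique) from an array node
ag_gather <- function(x, idx) {
  dx <- dim(x$v)
  n <- length(x$v)
  ag_node(as.numeric(x$v[idx]), list(x), backward = function(g) {
    gx <- numeric(n)
    gx[idx] <- g
    if (!is.null(dx)) dim(gx) <- dx
    list(gx)
  })
}

ag_concat_vec <- function(nodes) {
  lens <- vapply(nodes, function(n) length(n$v), 1L)
  y <- unlist(lapply(nodes, function(n) as.numeric(n$v)), use.names = FALSE)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  dims <- lapply(nodes, function(n) dim(n$v))
  ag_node(y, nodes, backward = function(g)
    lapply(seq_along(nodes), function(i) {
      gi <- g[starts[i]:ends[i]]
      if (!is.null(dims[[i]])) dim(gi) <- dims[[i]]
      gi
    }))
}

# --- losses -----------------------------------------------------------------

ag_softmax_ce <- function(logits, labels) {
  z <- logits$v
  n <- nrow(z)
  zmax <- apply(z, 1, max)
  ez <- exp(z - zmax)
  p <- ez / rowSums(ez)
  lse <- log(rowSums(ez)) + zmax
  loss <- mean(lse - z[cbind(seq_len(n), labels)])
  ag_node(loss, list(logits), backward = function(g) {
    gp <- p
    gp[cbind(seq_len(n), labels)] <- gp[cbind(seq_len(n), labels)] - 1
    list(g * gp / n)
  })
}

# smooth-L1 (Huber) on a flat vector, sum / divisor
ag_smooth_l1 <- function(pred, target, beta = 1, divisor = length(target)) {
  d <- as.numeric(pred$v) - as.numeric(target)
  if (beta > 0) {
    inner <- abs(d) < beta
    l <- ifelse(inner, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
    gd <- ifelse(inner, d / beta, sign(d))
  } else {
    l <- abs(d)
    gd <- sign(d)
  }
  dx <- dim(pred$v)
  ag_node(sum(l) / divisor, list(pred), backward = function(g) {
    gx <- g * gd / divisor
    if (!is.null(dx)) dim(gx) <- dx
    list(gx)
  })
}

# mean binary cross-entropy with logits over all elements
ag_bce_logits_mean <- function(logits, targets) {
  z <- as.numeric(logits$v)
  y <- as.numeric(targets)
  if (length(z) != length(y))
    stop("bce: logit/target length mismatch (", length(z), " vs ", length(y), ")")
  n <- length(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  dx <- dim(logits$v)
  ag_node(loss, list(logits), backward = function(g) {
    gx <- g * (1 / (1 + exp(-z)) - y) / n
    if (!is.null(dx)) dim(gx) <- dx
    list(gx)
  })
}

ag_sum_scalars <- function(nodes) {
  y <- sum(vapply(nodes, function(n) n$v, 0))
  ag_node(y, nodes, backward = function(g) rep(list(g), length(nodes)))
}

ag_scale_scalar <- function(x, a) {
  ag_node(x$v * a, list(x), backward = function(g) list(g * a))
}

ag_slice_ch <- function(x, ch) {
  d <- dim(x$v)
  y <- x$v[, , ch]
  dim(y) <- d[1:2]
  ag_node(y, list(x), backward = function(g) {
    gx <- array(0, d)
    gx[, , ch] <- g
    list(gx)
  })
}
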