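# ResNet50-FPN-ED backbone: ResNet50 stages -> per-stage efficient channel
# attention (ECA) -> 1x1 lateral reduction to the pyramid width -> top-down
# fusion with dense upsampling convolution (DUC, r = 2) -> 3x3 anti-aliasing
# convolutions -> P2..P6 (P6 = stride-2 max pool of P5).
#
# Normalization is the frozen-batch-norm form (per-channel affine), the
# standard choice for the tiny batch sizes this recipe trains with.

#' Adaptive ECA kernel size
#'
#' The width of the 1-D cross-channel convolution grows with the channel
#' count: `t = |log2(C)/gamma + b/gamma|`, then `k` is the nearest odd
#' integer under the rule "floor, then +1 if even" (the convention of the
#' original ECA reference implementation; the published formula leaves the
#' tie rule ambiguous).
#'
#' @param C number of channels (>= 1).
#' @param gamma,b formula constants; defaults 2 and 1.
#' @return odd integer kernel size `k >= 1`.
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (any(C < 1)) stop("eca_kernel_size: C must be >= 1")
  if (gamma <= 0) stop("eca_kernel_size: gamma must be positive")
  t <- abs(log2(C) / gamma + b / gamma)
  k <- floor(t)
  k <- ifelse(k %% 2 == 0, k + 1, k)
  as.integer(pmax(k, 1))
}

#' Efficient channel attention gate
#'
#' Global average pooling over space, a width-`k` 1-D convolution across the
#' channel axis (zero padding `(k-1)/2`, no bias), a sigmoid, and
#' channel-wise rescaling of the input. A pure channel gate: it preserves
#' shape and scales each channel by a weight in (0, 1).
#'
#' @param x feature map, array (H, W, C) (or an autograd node).
#' @param kernel numeric vector of odd length `k`; defaults to zeros of
#'   length `eca_kernel_size(C, gamma, b)`.
#' @param gamma,b constants for the adaptive kernel size.
#' @return array of the same shape (or node when `x` is a node).
#' @export
eca_forward <- function(x, kernel = NULL, gamma = 2, b = 1) {
  plain <- !is.environment(x)
  xn <- if (plain) ag_const(x) else x
  C <- dim(xn$v)[3]
  if (is.null(kernel)) kernel <- numeric(eca_kernel_size(C, gamma, b))
  kp <- if (is.environment(kernel)) kernel else vs_param(as.numeric(kernel))
  if (length(kp$v) %% 2L == 0L) stop("eca_forward: kernel width must be odd")
  g <- ag_gap(xn)
  a <- ag_conv1d_vec(g, kp)
  wgt <- ag_sigmoid(a)
  out <- ag_scale_channels(xn, wgt)
  if (plain) out$v else out
}

#' Dense upsampling convolution
#'
#' A 3x3 convolution maps (H/r, W/r, C) to (H/r, W/r, C*r^2); the channels
#' are then rearranged into an r-times larger spatial grid (periodic
#' sub-pixel arrangement), giving (H, W, C). With `r = 1` this is a plain
#' 3x3 convolution.
#'
#' @param x input feature map (H/r, W/r, C) array or node.
#' @param weight conv weight (3, 3, C, C*r^2) array or parameter.
#' @param bias optional bias of length C*r^2.
#' @param r integer upscale ratio >= 1.
#' @return feature map (H, W, C).
#' @export
duc_upsample <- function(x, weight, bias = NULL, r = 2L) {
  stopifnot(r >= 1)
  plain <- !is.environment(x)
  xn <- if (plain) ag_const(x) else x
  wp <- if (is.environment(weight)) weight else vs_param(weight)
  bp <- if (is.null(bias) || is.environment(bias)) bias else vs_param(bias)
  C <- dim(xn$v)[3]
  wd <- dim(wp$v)
  if (wd[4] != C * r * r)
    stop("duc_upsample: weight must produce C*r^2 = ", C * r * r, " channels")
  y <- ag_conv2d(xn, wp, bp, stride = 1L, pad = 1L)
  out <- if (r == 1L) y else ag_pixel_shuffle(y, as.integer(r))
  if (plain) out$v else out
}

# --- configuration and parameters ------------------------------------------

#' Backbone configuration
#'
#' @param preset `"full"` (the published ResNet50 geometry: bottleneck
#'   counts 3/4/6/3, stage widths 256/512/1024/2048, 256-channel pyramid) or
#'   `"test"` (counts 1/1/1/1, widths divided by 4, 64-channel pyramid; same
#'   ED topology, sized for CPU tests).
#' @param eca,duc logical switches for the two backbone modifications;
#'   with `duc = FALSE` the pyramid falls back to nearest-neighbor
#'   upsampling.
#' @param gamma,b ECA kernel-size constants.
#' @export
backbone_config <- function(preset = c("full", "test"), eca = TRUE, duc = TRUE,
                            gamma = 2, b = 1) {
  preset <- match.arg(preset)
  div <- if (preset == "full") 1L else 4L
  list(preset = preset,
       stem_width = 64L %/% div,
       block_counts = if (preset == "full") c(3L, 4L, 6L, 3L) else rep(1L, 4L),
       inner_widths = c(64L, 128L, 256L, 512L) %/% div,
       stage_widths = c(256L, 512L, 1024L, 2048L) %/% div,
       fpn_width = 256L %/% div,
       eca = eca, duc = duc, gamma = gamma, b = b)
}

he_conv <- function(kh, kw, ci, co) {
  vs_param(array(rnorm(kh * kw * ci * co, 0, sqrt(2 / (kh * kw * ci))),
                 c(kh, kw, ci, co)))
}

affine_pair <- function(C) list(s = vs_param(rep(1, C)), b = vs_param(numeric(C)))

new_bottleneck <- function(cin, cmid, cout, stride) {
  blk <- list(conv1 = he_conv(1, 1, cin, cmid), a1 = affine_pair(cmid),
              conv2 = he_conv(3, 3, cmid, cmid), a2 = affine_pair(cmid),
              conv3 = he_conv(1, 1, cmid, cout), a3 = affine_pair(cout),
              stride = stride)
  if (cin != cout || stride != 1L) {
    blk$proj <- he_conv(1, 1, cin, cout)
    blk$aproj <- affine_pair(cout)
  }
  blk
}

#' Build backbone parameters
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for weight initialization.
#' @return parameter tree (list of parameter environments).
#' @export
build_backbone <- function(config = backbone_config("full"), seed = 1L) {
  set.seed(seed)
  bb <- list(config = config)
  bb$stem <- list(conv = he_conv(7, 7, 3, config$stem_width),
                  a = affine_pair(config$stem_width))
  cin <- config$stem_width
  for (s in 1:4) {
    blocks <- list()
    for (bi in seq_len(config$block_counts[s])) {
      stride <- if (s > 1 && bi == 1L) 2L else 1L
      blocks[[bi]] <- new_bottleneck(cin, config$inner_widths[s],
                                     config$stage_widths[s], stride)
      cin <- config$stage_widths[s]
    }
    bb[[paste0("stage", s + 1L)]] <- blocks
  }
  if (config$eca) {
    bb$eca <- lapply(1:4, function(s) {
      k <- eca_kernel_size(config$stage_widths[s], config$gamma, config$b)
      vs_param(numeric(k))  # zero init: gate starts at 0.5 for every channel
    })
  }
  fw <- config$fpn_width
  bb$lateral <- lapply(1:4, function(s) {
    list(w = he_conv(1, 1, config$stage_widths[s], fw), b = vs_param(numeric(fw)))
  })
  if (config$duc) {
    bb$duc <- lapply(1:3, function(i) {  # fuse into levels 4, 3, 2
      list(w = he_conv(3, 3, fw, fw * 4L), b = vs_param(numeric(fw * 4L)))
    })
  }
  bb$out <- lapply(1:4, function(i) {
    list(w = he_conv(3, 3, fw, fw), b = vs_param(numeric(fw)))
  })
  bb
}

# --- forward passes ---------------------------------------------------------

bottleneck_forward <- function(x, blk) {
  y <- ag_conv2d(x, blk$conv1, stride = 1L, pad = 0L)
  y <- ag_relu(ag_affine_ch(y, blk$a1$s, blk$a1$b))
  y <- ag_conv2d(y, blk$conv2, stride = blk$stride, pad = 1L)
  y <- ag_relu(ag_affine_ch(y, blk$a2$s, blk$a2$b))
  y <- ag_conv2d(y, blk$conv3, stride = 1L, pad = 0L)
  y <- ag_affine_ch(y, blk$a3$s, blk$a3$b)
  sc <- if (!is.null(blk$proj)) {
    p <- ag_conv2d(x, blk$proj, stride = blk$stride, pad = 0L)
    ag_affine_ch(p, blk$aproj$s, blk$aproj$b)
  } else x
  ag_relu(ag_add(y, sc))
}

#' ResNet50 stage outputs C2-C5
#'
#' The stem halves the input twice (7x7 stride-2 convolution, then 3x3
#' stride-2 max pool); the four bottleneck stages produce feature maps at
#' 1/4, 1/8, 1/16 and 1/32 of the input resolution with the configured
#' widths. Inputs whose sides are not divisible by 32 are zero-padded on the
#' right/bottom; the padding is recorded in the result attributes.
#'
#' @param image H x W x 3 array (any numeric range) or autograd node.
#' @param backbone parameters from [build_backbone()].
#' @return list of nodes `C2`, `C3`, `C4`, `C5` (values if `image` was a
#'   plain array), with attribute `pad = c(bottom, right)`.
#' @export
resnet50_stages <- function(image, backbone) {
  plain <- !is.environment(image)
  if (plain) {
    if (length(dim(image)) != 3L || dim(image)[3] != 3L)
      stop("resnet50_stages: input must be H x W x 3 RGB")
    pad <- pad_to_multiple(image, 32L)
    image <- ag_const(pad$x)
    padded <- pad$pad
  } else padded <- c(0L, 0L)
  x <- ag_conv2d(image, backbone$stem$conv, stride = 2L, pad = 3L)
  x <- ag_relu(ag_affine_ch(x, backbone$stem$a$s, backbone$stem$a$b))
  x <- ag_maxpool(x, 3L, 2L, 1L)
  out <- list()
  for (s in 1:4) {
    for (blk in backbone[[paste0("stage", s + 1L)]]) x <- bottleneck_forward(x, blk)
    out[[paste0("C", s + 1L)]] <- x
  }
  if (plain) out <- lapply(out, function(n) n$v)
  attr(out, "pad") <- padded
  out
}

pad_to_multiple <- function(image, m) {
  d <- dim(image)
  nh <- as.integer(ceiling(d[1] / m) * m)
  nw <- as.integer(ceiling(d[2] / m) * m)
  if (nh == d[1] && nw == d[2])
    return(list(x = image * 1.0, pad = c(0L, 0L)))
  x <- array(0, c(nh, nw, d[3]))
  x[seq_len(d[1]), seq_len(d[2]), ] <- image
  list(x = x, pad = c(nh - d[1], nw - d[2]))
}

#' Fuse stage features into the P2-P6 pyramid (ED pathway)
#'
#' Each stage output passes its ECA gate, is reduced to the pyramid width by
#' a 1x1 convolution, fused top-down (DUC upsampling by 2 then element-wise
#' addition), smoothed by a 3x3 convolution against aliasing, and P6 is a
#' stride-2 max pool of P5.
#'
#' @param stages list with C2..C5 from [resnet50_stages()].
#' @param backbone parameters from [build_backbone()].
#' @param upsampler `"duc"` or `"nearest"` (shape-identical fallback).
#' @return list of nodes (or arrays) `P2`..`P6`.
#' @export
fpn_ed_fuse <- function(stages, backbone, upsampler = NULL) {
  cfg <- backbone$config
  if (is.null(upsampler)) upsampler <- if (cfg$duc) "duc" else "nearest"
  plain <- !is.environment(stages[[1L]])
  cs <- lapply(1:4, function(s) {
    x <- stages[[paste0("C", s + 1L)]]
    if (plain) x <- ag_const(x)
    if (cfg$eca) x <- eca_forward(x, backbone$eca[[s]], cfg$gamma, cfg$b)
    ag_conv2d(x, backbone$lateral[[s]]$w, backbone$lateral[[s]]$b)
  })
  m <- vector("list", 4L)
  m[[4L]] <- cs[[4L]]
  for (s in 3:1) {
    up <- if (upsampler == "duc")
      duc_upsample(m[[s + 1L]], backbone$duc[[s]]$w, backbone$duc[[s]]$b, r = 2L)
    else ag_upsample_nearest(m[[s + 1L]], 2L)
    if (!identical(dim(up$v), dim(cs[[s]]$v)))
      stop("fpn_ed_fuse: shape mismatch fusing into P", s + 1L, ": ",
           paste(dim(up$v), collapse = "x"), " vs ",
           paste(dim(cs[[s]]$v), collapse = "x"))
    m[[s]] <- ag_add(cs[[s]], up)
  }
  p <- lapply(1:4, function(s)
    ag_conv2d(m[[s]], backbone$out[[s]]$w, backbone$out[[s]]$b,
              stride = 1L, pad = 1L))
  names(p) <- paste0("P", 2:5)
  p$P6 <- ag_maxpool(p$P5, 1L, 2L, 0L)
  if (plain) p <- lapply(p, function(n) n$v)
  p
}

#' Full backbone forward pass: image to feature pyramid
#'
#' @inheritParams resnet50_stages
#' @inheritParams fpn_ed_fuse
#' @return list `P2`..`P6` with strides 4, 8, 16, 32, 64 and the configured
#'   pyramid width, plus attribute `pad`.
#' @export
backbone_forward <- function(image, backbone, upsampler = NULL) {
  plain <- !is.environment(image)
  if (plain) {
    pad <- pad_to_multiple(image, 64L)
    stages <- resnet50_stages(ag_const(pad$x), backbone)
    p <- fpn_ed_fuse(stages, backbone, upsampler)
    p <- lapply(p, function(n) n$v)
    attr(p, "pad") <- pad$pad
    p
  } else {
    stages <- resnet50_stages(image, backbone)
    p <- fpn_ed_fuse(stages, backbone, upsampler)
    attr(p, "pad") <- attr(stages, "pad")
    p
  }
}
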