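# Region proposal network, RoIAlign pooling, box / mask heads, losses and
# prediction.

# --- RPN --------------------------------------------------------------------

LEVEL_STRIDES <- c(P2 = 4L, P3 = 8L, P4 = 16L, P5 = 32L, P6 = 64L)

rpn_forward <- function(pyramid, model) {
  rp <- model$rpn
  out <- list()
  for (nm in names(LEVEL_STRIDES)) {
    t <- ag_relu(ag_conv2d(pyramid[[nm]], rp$conv, rp$conv_b, pad = 1L))
    out[[nm]] <- list(obj = ag_conv2d(t, rp$obj, rp$obj_b),
                      box = ag_conv2d(t, rp$box, rp$box_b))
  }
  out
}

# all anchors over the pyramid, concatenated P2..P6 in objectness-array order
all_anchors <- function(pyramid, templates) {
  anchors <- list()
  for (nm in names(LEVEL_STRIDES)) {
    d <- dim(if (is.environment(pyramid[[nm]])) pyramid[[nm]]$v else pyramid[[nm]])
    lvl <- as.integer(substring(nm, 2))
    tpl <- templates[templates$level == lvl, , drop = FALSE]
    anchors[[nm]] <- anchors_for_level(d[1], d[2], LEVEL_STRIDES[[nm]], tpl)
  }
  anchors
}

# per-level (H*W*A, 4) delta matrix from the (H, W, 4A) conv output value
level_deltas_matrix <- function(box_value) {
  d <- dim(box_value)
  A <- d[3] %/% 4L
  do.call(rbind, lapply(seq_len(A), function(a) {
    matrix(box_value[, , (4L * a - 3L):(4L * a)], d[1] * d[2], 4L)
  }))
}

#' Generate scored region proposals from the feature pyramid
#'
#' Standard Faster R-CNN mechanics: per-location objectness and box deltas
#' for each anchor template on its level, per-level top-N preselection and
#' NMS, then a global top-N cap. Proposals are clipped to the image bounds.
#'
#' @param pyramid P2..P6 (arrays or nodes) from [backbone_forward()].
#' @param model model from [build_model()].
#' @param image_size c(height, width) for clipping.
#' @param training use training-time proposal budgets.
#' @return list with `boxes` (n x 4 xyxy) and `scores`.
#' @export
rpn_propose <- function(pyramid, model, image_size, training = FALSE) {
  plain <- !is.environment(pyramid[[1L]])
  pyr <- if (plain) lapply(pyramid, ag_const) else pyramid
  out <- rpn_forward(pyr, model)
  proposals_from_outputs(out, pyr, model, image_size, training)
}

proposals_from_outputs <- function(rpn_out, pyramid, model, image_size,
                                   training) {
  cfg <- model$config$rpn
  pre <- if (training) cfg$pre_nms_train else cfg$pre_nms_test
  post <- if (training) cfg$post_nms_train else cfg$post_nms_test
  anchors <- all_anchors(pyramid, model$templates)
  boxes_all <- list(); scores_all <- list()
  for (nm in names(LEVEL_STRIDES)) {
    scores <- 1 / (1 + exp(-as.numeric(rpn_out[[nm]]$obj$v)))
    deltas <- level_deltas_matrix(rpn_out[[nm]]$box$v)
    keep <- utils::head(order(-scores), pre)
    b <- decode_deltas(anchors[[nm]][keep, , drop = FALSE],
                       deltas[keep, , drop = FALSE], cfg$delta_weights)
    b <- clip_boxes_xyxy(b, image_size[1], image_size[2])
    s <- scores[keep]
    ok <- (b[, 3] - b[, 1]) > 1e-3 & (b[, 4] - b[, 2]) > 1e-3
    b <- b[ok, , drop = FALSE]; s <- s[ok]
    kept <- nms_boxes(b, s, cfg$nms_threshold)
    boxes_all[[nm]] <- b[kept, , drop = FALSE]
    scores_all[[nm]] <- s[kept]
  }
  boxes <- do.call(rbind, boxes_all)
  scores <- unlist(scores_all, use.names = FALSE)
  keep <- utils::head(order(-scores), post)
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep])
}

# --- RoIAlign pooling --------------------------------------------------------

#' RoIAlign: quantization-free bilinear pooling of boxes to a fixed grid
#'
#' @param feature (H, W, C) array or node.
#' @param boxes n x 4 xyxy boxes in input-pixel coordinates.
#' @param output_size pooled grid side (7 for the box head, 14 for masks).
#' @param spatial_scale feature stride reciprocal (e.g. 1/4 for P2).
#' @param sampling bilinear samples per bin side (default 2).
#' @return (output_size, output_size, C, n) array (or node).
#' @export
roi_align <- function(feature, boxes, output_size, spatial_scale = 1,
                      sampling = 2L) {
  boxes <- matrix(boxes, ncol = 4)
  degenerate <- (boxes[, 3] - boxes[, 1]) <= 0 | (boxes[, 4] - boxes[, 2]) <= 0
  if (any(degenerate))
    warning("roi_align: ", sum(degenerate), " degenerate (zero-area) box(es)")
  plain <- !is.environment(feature)
  fn <- if (plain) ag_const(feature) else feature
  out <- ag_roialign(fn, boxes, spatial_scale, output_size, output_size,
                     sampling)
  if (plain) out$v else out
}

# pool boxes from their assigned pyramid levels; returns a row-per-roi
# feature matrix node in the original box order
pool_rois_matrix <- function(pyramid, boxes, pool) {
  lv <- assign_roi_levels(boxes)
  mats <- list(); orders <- list()
  for (l in sort(unique(lv))) {
    idx <- which(lv == l)
    nd <- ag_roialign(pyramid[[paste0("P", l)]], boxes[idx, , drop = FALSE],
                      1 / LEVEL_STRIDES[[paste0("P", l)]], pool, pool, 2L)
    mats[[length(mats) + 1L]] <- ag_pool_to_mat(nd)
    orders[[length(orders) + 1L]] <- idx
  }
  combined <- ag_rbind(mats)
  ord <- unlist(orders)
  if (identical(ord, seq_along(ord))) combined
  else ag_rows(combined, match(seq_along(ord), ord))
}

box_head_forward <- function(pyramid, boxes, model) {
  bh <- model$box_head
  x <- pool_rois_matrix(pyramid, boxes, model$config$box$pool)
  x <- ag_relu(ag_linear(x, bh$fc1, bh$fc1_b))
  x <- ag_relu(ag_linear(x, bh$fc2, bh$fc2_b))
  list(cls = ag_linear(x, bh$cls, bh$cls_b),
       deltas = ag_linear(x, bh$box, bh$box_b))
}

# per-roi list of (2m, 2m, n_classes) mask logit nodes, original box order
mask_head_forward <- function(pyramid, boxes, model) {
  mh <- model$mask_head
  pool <- model$config$mask$pool
  lv <- assign_roi_levels(boxes)
  out <- vector("list", nrow(boxes))
  for (l in sort(unique(lv))) {
    idx <- which(lv == l)
    pooled <- ag_roialign(pyramid[[paste0("P", l)]], boxes[idx, , drop = FALSE],
                          1 / LEVEL_STRIDES[[paste0("P", l)]], pool, pool, 2L)
    for (j in seq_along(idx)) {
      x <- ag_slice_roi(pooled, j)
      for (cv in mh$convs) x <- ag_relu(ag_conv2d(x, cv$w, cv$b, pad = 1L))
      x <- ag_relu(ag_pixel_shuffle(
        ag_conv2d(x, mh$deconv$w, mh$deconv$b), 2L))
      out[[idx[j]]] <- ag_conv2d(x, mh$pred$w, mh$pred$b)
    }
  }
  out
}

# --- losses ------------------------------------------------------------------

#' Average binary cross-entropy mask loss
#'
#' A sigmoid is applied to every pixel of the target class's m x m logit
#' slice and the loss is the mean binary cross-entropy against the binary
#' target; other class slices do not contribute.
#'
#' @param logits (m, m, n_classes) array of mask logits for one RoI.
#' @param target m x m binary matrix.
#' @param class_index 1-based class slice to supervise.
#' @return scalar loss.
#' @export
mask_loss <- function(logits, target, class_index = 2L) {
  d <- dim(logits)
  if (length(d) != 3L) stop("mask_loss: logits must be (m, m, n_classes)")
  if (!all(d[1:2] == dim(target)))
    stop("mask_loss: target shape ", paste(dim(target), collapse = "x"),
         " does not match logits ", paste(d[1:2], collapse = "x"))
  if (class_index < 1L || class_index > d[3]) stop("mask_loss: bad class index")
  z <- as.numeric(logits[, , class_index])
  y <- as.numeric(target)
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Combine the three head losses
#'
#' The total training objective of the detector sums the classification,
#' box-regression and mask terms with no weighting coefficients.
#'
#' @param cls,box,mask scalar loss terms.
#' @return `vineseg_loss` list with `L_cls`, `L_box`, `L_mask`, `L_total`.
#' @export
total_loss <- function(cls, box, mask) {
  for (nm in c("cls", "box", "mask")) {
    v <- get(nm)
    if (!is.finite(v))
      stop("total_loss: training diverged - L_", nm, " is not finite")
  }
  structure(list(L_cls = cls, L_box = box, L_mask = mask,
                 L_total = cls + box + mask),
            class = "vineseg_loss")
}

#' @export
print.vineseg_loss <- function(x, ...) {
  cat(sprintf("loss: total=%.4f (cls=%.4f box=%.4f mask=%.4f)\n",
              x$L_total, x$L_cls, x$L_box, x$L_mask))
  invisible(x)
}

# RPN target assignment: positives by IoU >= pos_iou plus per-gt argmax
# anchors; negatives below neg_iou; the rest ignored.
rpn_targets <- function(anchors_xyxy, gt_xyxy, cfg) {
  A <- nrow(anchors_xyxy)
  G <- nrow(gt_xyxy)
  if (G == 0L) {
    return(list(pos = integer(0), neg = sample.int(A, min(cfg$batch, A)),
                matched = integer(0)))
  }
  iou <- box_iou_matrix(box_xyxy_to_xywh(anchors_xyxy),
                        box_xyxy_to_xywh(gt_xyxy))
  best <- apply(iou, 1, max)
  argmax <- max.col(iou, ties.method = "first")
  pos <- best >= cfg$pos_iou
  for (g in seq_len(G)) {
    cmax <- max(iou[, g])
    if (cmax > 0) pos[iou[, g] >= cmax - 1e-9] <- TRUE
  }
  neg <- !pos & best < cfg$neg_iou
  pos_idx <- which(pos)
  n_pos <- min(length(pos_idx), as.integer(cfg$batch * cfg$pos_fraction))
  if (length(pos_idx) > n_pos) pos_idx <- sample(pos_idx, n_pos)
  neg_idx <- which(neg)
  n_neg <- min(length(neg_idx), cfg$batch - n_pos)
  if (length(neg_idx) > n_neg) neg_idx <- sample(neg_idx, n_neg)
  list(pos = pos_idx, neg = neg_idx, matched = argmax[pos_idx])
}

rpn_loss <- function(rpn_out, pyramid, model, gt_xyxy) {
  cfg <- model$config$rpn
  anchors_by_level <- all_anchors(pyramid, model$templates)
  anchors <- do.call(rbind, anchors_by_level)
  tg <- rpn_targets(anchors, gt_xyxy, cfg)
  obj_all <- ag_concat_vec(lapply(names(LEVEL_STRIDES),
                                  function(nm) rpn_out[[nm]]$obj))
  sel <- c(tg$pos, tg$neg)
  labels <- c(rep(1, length(tg$pos)), rep(0, length(tg$neg)))
  l_obj <- ag_bce_logits_mean(ag_gather(obj_all, sel), labels)
  if (length(tg$pos) > 0L) {
    # flat indices of the 4 delta channels of each positive anchor within
    # the concatenated (H, W, 4A) box outputs
    level_sizes <- vapply(anchors_by_level, nrow, 1L)
    level_of <- rep(seq_along(level_sizes), level_sizes)
    level_start <- cumsum(c(0L, head(level_sizes, -1L)))
    box_lens <- vapply(names(LEVEL_STRIDES),
                       function(nm) length(rpn_out[[nm]]$box$v), 1L)
    box_start <- cumsum(c(0L, head(box_lens, -1L)))
    dims <- lapply(names(LEVEL_STRIDES),
                   function(nm) dim(rpn_out[[nm]]$box$v))
    idx <- integer(0)
    for (i in seq_along(tg$pos)) {
      a <- tg$pos[i]
      l <- level_of[a]
      al <- a - level_start[l] - 1L            # 0-based within level
      hw <- dims[[l]][1] * dims[[l]][2]
      cell <- al %% hw
      tpl <- al %/% hw
      idx <- c(idx, box_start[l] + cell + hw * (4L * tpl + 0:3) + 1L)
    }
    box_all <- ag_concat_vec(lapply(names(LEVEL_STRIDES),
                                    function(nm) rpn_out[[nm]]$box))
    targets <- encode_deltas(anchors[tg$pos, , drop = FALSE],
                             gt_xyxy[tg$matched, , drop = FALSE],
                             cfg$delta_weights)
    l_box <- ag_smooth_l1(ag_gather(box_all, idx), as.numeric(t(targets)),
                          beta = cfg$smooth_l1_beta, divisor = length(sel))
  } else l_box <- ag_const(0)
  list(obj = l_obj, box = l_box)
}

# sample proposals for the second stage (gt boxes appended, standard trick)
proposal_targets <- function(proposals, gt_xyxy, cfg) {
  boxes <- rbind(proposals, gt_xyxy)
  G <- nrow(gt_xyxy)
  if (G == 0L) {
    n <- min(nrow(boxes), cfg$batch)
    sel <- if (nrow(boxes) > 0) sample.int(nrow(boxes), n) else integer(0)
    return(list(boxes = boxes[sel, , drop = FALSE],
                labels = rep(0L, n), matched = rep(NA_integer_, n)))
  }
  iou <- box_iou_matrix(box_xyxy_to_xywh(boxes), box_xyxy_to_xywh(gt_xyxy))
  best <- apply(iou, 1, max)
  argmax <- max.col(iou, ties.method = "first")
  fg <- which(best >= cfg$pos_iou)
  bg <- which(best < cfg$pos_iou)
  n_fg <- min(length(fg), as.integer(cfg$batch * cfg$pos_fraction))
  if (length(fg) > n_fg) fg <- sample(fg, n_fg)
  n_bg <- min(length(bg), cfg$batch - n_fg)
  if (length(bg) > n_bg) bg <- sample(bg, n_bg)
  sel <- c(fg, bg)
  list(boxes = boxes[sel, , drop = FALSE],
       labels = c(rep(1L, length(fg)), rep(0L, length(bg))),
       matched = ifelse(c(rep(TRUE, length(fg)), rep(FALSE, length(bg))),
                        argmax[sel], NA_integer_))
}

# --- prediction ---------------------------------------------------------------

# paste an m x m mask probability grid into image space inside its box
paste_mask <- function(prob, box_xyxy, height, width, threshold = 0.5) {
  m <- nrow(prob)
  full <- matrix(FALSE, height, width)
  x0 <- max(floor(box_xyxy[1]), 0); x1 <- min(ceiling(box_xyxy[3]), width)
  y0 <- max(floor(box_xyxy[2]), 0); y1 <- min(ceiling(box_xyxy[4]), height)
  if (x1 <= x0 || y1 <= y0) return(full)
  bw <- box_xyxy[3] - box_xyxy[1]; bh <- box_xyxy[4] - box_xyxy[2]
  cols <- seq.int(x0, x1 - 1L); rows <- seq.int(y0, y1 - 1L)
  u <- pmin(pmax((cols + 0.5 - box_xyxy[1]) / bw * m - 0.5, 0), m - 1)
  v <- pmin(pmax((rows + 0.5 - box_xyxy[2]) / bh * m - 0.5, 0), m - 1)
  v0 <- pmin(floor(v), m - 1); v1 <- pmin(v0 + 1, m - 1); fv <- v - v0
  u0 <- pmin(floor(u), m - 1); u1 <- pmin(u0 + 1, m - 1); fu <- u - u0
  p00 <- prob[v0 + 1, u0 + 1, drop = FALSE]
  p01 <- prob[v0 + 1, u1 + 1, drop = FALSE]
  p10 <- prob[v1 + 1, u0 + 1, drop = FALSE]
  p11 <- prob[v1 + 1, u1 + 1, drop = FALSE]
  FV <- matrix(fv, length(v), length(u))
  FU <- matrix(fu, length(v), length(u), byrow = TRUE)
  block <- (1 - FV) * ((1 - FU) * p00 + FU * p01) +
           FV * ((1 - FU) * p10 + FU * p11)
  full[rows + 1L, cols + 1L] <- block >= threshold
  full
}

#' Run the detector on one image
#'
#' @param model model from [build_model()] or [load_checkpoint()].
#' @param image H x W x 3 array (0-255 or 0-1).
#' @param score_threshold minimum class score to keep a detection.
#' @return list of detections, score-sorted: each has `bbox` (x, y, w, h),
#'   `score`, `class`, and a full-size logical `mask` (thresholded at 0.5,
#'   supported inside the detection box).
#' @export
predict_instances <- function(model, image,
                              score_threshold = model$config$box$score_threshold) {
  cfg <- model$config
  H <- dim(image)[1]; W <- dim(image)[2]
  img <- normalize_image(image)
  pyr <- backbone_forward_nodes(img, model)
  prop <- rpn_propose(pyr, model, c(H, W), training = FALSE)
  if (nrow(prop$boxes) == 0L) return(list())
  bh <- box_head_forward(pyr, prop$boxes, model)
  probs <- softmax_rows(bh$cls$v)
  scores <- probs[, 2]
  deltas <- bh$deltas$v[, 5:8, drop = FALSE]
  boxes <- decode_deltas(prop$boxes, deltas, cfg$box$delta_weights)
  boxes <- clip_boxes_xyxy(boxes, H, W)
  keep <- which(scores >= score_threshold &
                (boxes[, 3] - boxes[, 1]) > 1e-3 &
                (boxes[, 4] - boxes[, 2]) > 1e-3)
  if (length(keep) == 0L) return(list())
  boxes <- boxes[keep, , drop = FALSE]; scores <- scores[keep]
  kept <- nms_boxes(boxes, scores, cfg$box$nms_threshold)
  kept <- kept[seq_len(min(length(kept), cfg$box$max_detections))]
  boxes <- boxes[kept, , drop = FALSE]; scores <- scores[kept]
  ord <- order(-scores)
  boxes <- boxes[ord, , drop = FALSE]; scores <- scores[ord]
  masks <- mask_head_forward(pyr, boxes, model)
  out <- vector("list", length(scores))
  for (i in seq_along(scores)) {
    logit <- masks[[i]]$v[, , 2]
    prob <- 1 / (1 + exp(-logit))
    out[[i]] <- list(bbox = as.numeric(box_xyxy_to_xywh(boxes[i, , drop = FALSE])),
                     score = scores[i],
                     class = "grape",
                     mask = paste_mask(prob, boxes[i, ], H, W))
  }
  out
}

normalize_image <- function(image) {
  img <- image * 1.0
  if (max(img) > 1.5) img <- img / 255
  img - 0.5
}

backbone_forward_nodes <- function(img, model) {
  pad <- pad_to_multiple(img, 64L)
  pyr <- backbone_forward(ag_const(pad$x), model$backbone)
  pyr
}

softmax_rows <- function(z) {
  zm <- apply(z, 1, max)
  ez <- exp(z - zm)
  ez / rowSums(ez)
}
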