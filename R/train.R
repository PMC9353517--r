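# Training, augmentation and evaluation orchestration.
#
# Published recipe defaults: SGD (momentum 0.9), initial learning rate
# 0.01 decayed by 0.1 every 5000 iterations, weight decay 1e-4, batch size
# 2, 50 epochs, online mirror / rotation / crop / color augmentation, and
# multi-scale resize with short edge in {640..800 step 32} capped at a long
# edge of 1443 pixels. The schedule is iteration-based, independent of
# epoch bookkeeping.

#' Training configuration (published defaults)
#'
#' @param epochs,batch_size,initial_lr,lr_decay_factor,lr_decay_every,
#'   weight_decay,momentum optimizer recipe.
#' @param augment logical switches: `mirror_h`, `mirror_v`, `rotate`,
#'   `crop`, `color`.
#' @param rotation_limit max |rotation| in degrees.
#' @param crop_range relative crop-size range.
#' @param short_edges multi-scale short-edge set; `max_edge` long-side cap.
#' @param multiscale enable the multi-scale resize (off for tiny fixtures).
#' @param iterations optional hard iteration budget (overrides epochs).
#' @param seed integer seed; the run is fully deterministic given it.
#' @export
train_config <- function(epochs = 50L, batch_size = 2L, initial_lr = 0.01,
                         lr_decay_factor = 0.1, lr_decay_every = 5000L,
                         weight_decay = 1e-4, momentum = 0.9,
                         augment = list(mirror_h = TRUE, mirror_v = TRUE,
                                        rotate = TRUE, crop = TRUE,
                                        color = TRUE),
                         rotation_limit = 15, crop_range = c(0.8, 1.0),
                         short_edges = seq(640L, 800L, by = 32L),
                         max_edge = 1443L, multiscale = TRUE,
                         iterations = NULL, seed = 1L) {
  stopifnot(epochs > 0, batch_size > 0, initial_lr > 0, lr_decay_factor > 0,
            lr_decay_every > 0, length(short_edges) >= 1L)
  as.list(environment())
}

#' Step learning-rate schedule
#'
#' `lr = initial_lr * factor^floor(iteration / every)`; iteration 0 is the
#' first step.
#' @param iteration 0-based iteration counter (vectorized).
#' @param initial_lr,factor,every schedule constants.
#' @export
lr_schedule <- function(iteration, initial_lr = 0.01, factor = 0.1,
                        every = 5000L) {
  stopifnot(all(iteration >= 0))
  initial_lr * factor^(iteration %/% every)
}

# --- geometric / photometric augmentation -----------------------------------

flip_image_h <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
flip_image_v <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]

transform_sample_polygons <- function(instances, fn) {
  lapply(instances, function(inst) {
    inst$parts <- lapply(inst$parts, fn)
    inst
  })
}

# re-derive masks and boxes from (possibly transformed) polygons
refresh_instances <- function(instances, height, width, min_area = 4L) {
  out <- list()
  for (inst in instances) {
    parts <- Filter(function(p) nrow(p) >= 3, inst$parts)
    if (length(parts) == 0L) next
    mask <- rasterize_polygons(parts, height, width)
    if (sum(mask) < min_area) next
    pts <- do.call(rbind, parts)
    x0 <- max(min(pts[, 1]), 0); x1 <- min(max(pts[, 1]), width)
    y0 <- max(min(pts[, 2]), 0); y1 <- min(max(pts[, 2]), height)
    if (x1 - x0 <= 1e-6 || y1 - y0 <= 1e-6) next
    inst$parts <- parts
    inst$mask <- mask
    inst$bbox <- c(x0, y0, x1 - x0, y1 - y0)
    out[[length(out) + 1L]] <- inst
  }
  out
}

rotate_image_nn <- function(img, theta, cx, cy) {
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, w), h, w)
  ct <- cos(-theta); st <- sin(-theta)  # inverse map
  sx <- cx + (xs - cx) * ct - (ys - cy) * st
  sy <- cy + (xs - cx) * st + (ys - cy) * ct
  ci <- pmin(pmax(ceiling(sx), 1L), w)
  ri <- pmin(pmax(ceiling(sy), 1L), h)
  inside <- sx >= 0 & sx <= w & sy >= 0 & sy <= h
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    plane <- img[, , ch]
    vals <- plane[cbind(as.integer(ri), as.integer(ci))]
    vals[!inside] <- mean(plane)
    out[, , ch] <- matrix(vals, h, w)
  }
  out
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle
clip_polygon_rect <- function(p, x0, y0, x1, y1) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- NULL
    for (i in seq_len(n)) {
      a <- pts[i, ]; b <- pts[if (i == n) 1L else i + 1L, ]
      ain <- inside(a); bin <- inside(b)
      if (ain) out <- rbind(out, a)
      if (xor(ain, bin)) out <- rbind(out, intersect(a, b))
    }
    if (is.null(out)) matrix(numeric(0), 0, 2) else out
  }
  ix <- function(a, b, x) c(x, a[2] + (b[2] - a[2]) * (x - a[1]) / (b[1] - a[1]))
  iy <- function(a, b, y) c(a[1] + (b[1] - a[1]) * (y - a[2]) / (b[2] - a[2]), y)
  p <- clip_edge(p, function(q) q[1] >= x0, function(a, b) ix(a, b, x0))
  p <- clip_edge(p, function(q) q[1] <= x1, function(a, b) ix(a, b, x1))
  p <- clip_edge(p, function(q) q[2] >= y0, function(a, b) iy(a, b, y0))
  p <- clip_edge(p, function(q) q[2] <= y1, function(a, b) iy(a, b, y1))
  p
}

#' Online augmentation of one training sample
#'
#' Geometric transforms (mirrors, rotation, crop) are applied identically
#' to the image and to every instance polygon; boxes and masks are always
#' re-derived from the transformed polygons. Color jitter (brightness,
#' contrast, saturation) touches only the image. Instances removed entirely
#' by a crop are dropped.
#'
#' @param image H x W x 3 array (0-255).
#' @param instances list of instances (`parts`, `bbox`, `mask`).
#' @param config a [train_config()]; draws use the current RNG stream.
#' @return list(image, instances).
#' @export
augment_sample <- function(image, instances, config = train_config()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  aug <- config$augment
  if (isTRUE(aug$mirror_h) && runif(1) < 0.5) {
    image <- flip_image_h(image)
    instances <- transform_sample_polygons(instances, function(p)
      cbind(w - p[, 1], p[, 2]))
  }
  if (isTRUE(aug$mirror_v) && runif(1) < 0.5) {
    image <- flip_image_v(image)
    instances <- transform_sample_polygons(instances, function(p)
      cbind(p[, 1], h - p[, 2]))
  }
  if (isTRUE(aug$rotate) && runif(1) < 0.5) {
    theta <- runif(1, -config$rotation_limit, config$rotation_limit) * pi / 180
    cx <- w / 2; cy <- h / 2
    image <- rotate_image_nn(image, theta, cx, cy)
    ct <- cos(theta); st <- sin(theta)
    instances <- transform_sample_polygons(instances, function(p) {
      px <- cx + (p[, 1] - cx) * ct - (p[, 2] - cy) * st
      py <- cy + (p[, 1] - cx) * st + (p[, 2] - cy) * ct
      cbind(pmin(pmax(px, 0), w), pmin(pmax(py, 0), h))
    })
  }
  if (isTRUE(aug$crop) && runif(1) < 0.5) {
    fr <- runif(1, config$crop_range[1], config$crop_range[2])
    ch <- max(8L, floor(h * fr)); cw <- max(8L, floor(w * fr))
    oy <- sample.int(h - ch + 1L, 1L) - 1L
    ox <- sample.int(w - cw + 1L, 1L) - 1L
    image <- image[oy + seq_len(ch), ox + seq_len(cw), , drop = FALSE]
    instances <- lapply(instances, function(inst) {
      inst$parts <- Filter(function(p) nrow(p) >= 3,
                           lapply(inst$parts, function(p) {
                             q <- clip_polygon_rect(p, ox, oy, ox + cw, oy + ch)
                             if (nrow(q) >= 3) cbind(q[, 1] - ox, q[, 2] - oy)
                             else matrix(numeric(0), 0, 2)
                           }))
      inst
    })
    h <- ch; w <- cw
  }
  if (isTRUE(aug$color)) {
    br <- runif(1, 0.8, 1.2); ct <- runif(1, 0.8, 1.2); st <- runif(1, 0.8, 1.2)
    image <- (image - 128) * ct + 128
    image <- image * br
    luma <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    for (chn in 1:3) image[, , chn] <- luma + (image[, , chn] - luma) * st
    image <- pmin(pmax(image, 0), 255)
  }
  list(image = image, instances = refresh_instances(instances, h, w))
}

#' Multi-scale resize with a long-edge cap
#'
#' Scales isotropically so the short edge equals `short_edge`, unless that
#' would push the long edge past `max_edge`, in which case the long edge is
#' set to `max_edge`. Polygons scale with the image; masks and boxes are
#' re-derived.
#'
#' @param image H x W x 3 array.
#' @param instances instance list (may be empty).
#' @param short_edge target short-edge length (pixels).
#' @param max_edge long-edge cap (default 1443).
#' @return list(image, instances, scale).
#' @export
resize_multiscale <- function(image, instances, short_edge, max_edge = 1443) {
  h <- dim(image)[1]; w <- dim(image)[2]
  s <- short_edge / min(h, w)
  if (max(h, w) * s > max_edge) s <- max_edge / max(h, w)
  nh <- as.integer(round(h * s)); nw <- as.integer(round(w * s))
  out <- array(0, c(nh, nw, dim(image)[3]))
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- cpp_bilinear_resize(image[, , ch], nh, nw)
  instances <- transform_sample_polygons(instances, function(p)
    cbind(p[, 1] * s, p[, 2] * s))
  list(image = out, instances = refresh_instances(instances, nh, nw),
       scale = s)
}

# --- samples -----------------------------------------------------------------

#' Turn a generated scene into a training sample
#' @param scene a `vineseg_scene`.
#' @return list(image, instances) where each instance has `parts`, `bbox`,
#'   `mask`.
#' @export
scene_to_sample <- function(scene) {
  shapes <- scene$shapes
  recs <- merge_group_instances(shapes, nrow(scene$image), ncol(scene$image))
  list(image = scene$image,
       instances = lapply(recs, function(r)
         list(parts = r$parts, bbox = r$bbox, mask = r$mask)))
}

#' Load a COCO dataset directory into training samples
#' @param coco_json COCO annotation path.
#' @param image_dir directory holding the images.
#' @return list of samples plus the image id of each.
#' @export
coco_to_samples <- function(coco_json, image_dir) {
  gt <- read_coco(coco_json)
  anns_by_img <- split(gt$annotations,
                       vapply(gt$annotations, function(a) as.integer(a$image_id), 1L))
  samples <- list()
  for (im in gt$images) {
    img <- png::readPNG(file.path(image_dir, im$file_name)) * 255
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    anns <- anns_by_img[[as.character(as.integer(im$id))]]
    instances <- lapply(anns, function(a) {
      parts <- lapply(a$segmentation, function(p) as_poly_matrix(as.numeric(unlist(p))))
      list(parts = parts, bbox = as.numeric(unlist(a$bbox)),
           mask = rasterize_polygons(parts, im$height, im$width))
    })
    samples[[length(samples) + 1L]] <-
      list(image = img, instances = instances, image_id = as.integer(im$id))
  }
  samples
}

# --- optimizer ----------------------------------------------------------------

sgd_step <- function(params, lr, momentum, weight_decay, grad_scale = 1) {
  for (p in params) {
    if (is.null(p$g)) next
    g <- p$g * grad_scale + weight_decay * p$v
    p$m <- if (is.null(p$m)) g else momentum * p$m + g
    p$v <- p$v - lr * p$m
    p$g <- NULL
  }
}

# --- one forward/backward pass (gradients accumulate into the params) ---------

train_step <- function(model, sample, config) {
  gt_boxes <- do.call(rbind, lapply(sample$instances, function(i)
    box_xywh_to_xyxy(i$bbox)))
  if (is.null(gt_boxes)) gt_boxes <- matrix(numeric(0), 0, 4)
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  img <- normalize_image(sample$image)
  pad <- pad_to_multiple(img, 64L)

  ag_begin()
  on.exit(ag_end(), add = TRUE)
  pyr <- backbone_forward(ag_const(pad$x), model$backbone)
  rpn_out <- rpn_forward(pyr, model)
  rl <- rpn_loss(rpn_out, pyr, model, gt_boxes)
  prop <- proposals_from_outputs(rpn_out, pyr, model, c(h, w), training = TRUE)
  tg <- proposal_targets(prop$boxes, gt_boxes, model$config$box)

  n_roi <- nrow(tg$boxes)
  l_cls <- l_box <- l_mask <- ag_const(0)
  if (n_roi > 0L) {
    bh <- box_head_forward(pyr, tg$boxes, model)
    l_cls <- ag_softmax_ce(bh$cls, tg$labels + 1L)
    pos <- which(tg$labels == 1L)
    if (length(pos) > 0L) {
      targets <- encode_deltas(tg$boxes[pos, , drop = FALSE],
                               gt_boxes[tg$matched[pos], , drop = FALSE],
                               model$config$box$delta_weights)
      # class-1 (grape) delta columns 5:8, column-major flat indices
      idx <- unlist(lapply(pos, function(r) (4:7) * n_roi + r))
      l_box <- ag_smooth_l1(ag_gather(bh$deltas, idx),
                            as.numeric(t(targets)),
                            beta = model$config$box$smooth_l1_beta,
                            divisor = n_roi)
      mpos <- utils::head(pos, model$config$mask$max_train_rois)
      mlogits <- mask_head_forward(pyr, tg$boxes[mpos, , drop = FALSE], model)
      msize <- model$config$mask$size
      terms <- vector("list", length(mpos))
      for (j in seq_along(mpos)) {
        gt_mask <- sample$instances[[tg$matched[mpos[j]]]]$mask
        target <- roi_align(array(gt_mask * 1.0, c(dim(gt_mask), 1L)),
                            tg$boxes[mpos[j], , drop = FALSE],
                            msize, 1, sampling = 2L)[, , 1, 1] >= 0.5
        terms[[j]] <- ag_bce_logits_mean(ag_slice_ch(mlogits[[j]], 2L),
                                         target * 1.0)
      }
      l_mask <- ag_scale_scalar(ag_sum_scalars(terms), 1 / length(terms))
    }
  }
  total <- ag_sum_scalars(list(rl$obj, rl$box, l_cls, l_box, l_mask))
  ag_backward(total)
  list(rpn_cls = rl$obj$v, rpn_box = rl$box$v,
       loss = total_loss(l_cls$v, l_box$v, l_mask$v))
}

# idx targets: ag_gather order must match target layout; see test suite.

#' Train the detector
#'
#' Optimizes the summed detection objective (RPN objectness + RPN box +
#' head classification + head box regression + mask loss) with SGD under
#' the step learning-rate schedule. Fully seeded: identical seeds give
#' identical loss traces.
#'
#' @param samples list of training samples (see [scene_to_sample()] /
#'   [coco_to_samples()]).
#' @param model model from [build_model()]; updated in place (environments).
#' @param config a [train_config()].
#' @param log_file optional path for JSON-lines iteration logs.
#' @param checkpoint_every save a checkpoint every N iterations (0 = only
#'   at the end) when `checkpoint_path` is set.
#' @param checkpoint_path optional .rds path.
#' @return list with `model` and `log` (data.frame of per-iteration terms).
#' @export
train <- function(samples, model, config = train_config(),
                  log_file = NULL, checkpoint_every = 0L,
                  checkpoint_path = NULL) {
  stopifnot(length(samples) >= 1L)
  set.seed(config$seed)
  params <- collect_params(model)
  iters <- if (!is.null(config$iterations)) config$iterations
           else ceiling(config$epochs * length(samples) / config$batch_size)
  log <- vector("list", iters)
  con <- if (!is.null(log_file)) file(log_file, open = "wt")
  if (!is.null(con)) on.exit(close(con), add = TRUE)
  for (it in seq_len(iters)) {
    lr <- lr_schedule(it - 1L, config$initial_lr, config$lr_decay_factor,
                      config$lr_decay_every)
    idx <- sample.int(length(samples), config$batch_size,
                      replace = length(samples) < config$batch_size)
    stats <- vector("list", length(idx))
    for (b in seq_along(idx)) {
      sample_i <- samples[[idx[b]]]
      if (any(unlist(config$augment))) {
        a <- augment_sample(sample_i$image, sample_i$instances, config)
        if (length(a$instances) > 0L) sample_i <- a
      }
      if (isTRUE(config$multiscale)) {
        se <- config$short_edges[sample.int(length(config$short_edges), 1L)]
        r <- resize_multiscale(sample_i$image, sample_i$instances, se,
                               config$max_edge)
        if (length(r$instances) > 0L) sample_i <- r
      }
      stats[[b]] <- train_step(model, sample_i, config)
    }
    sgd_step(params, lr, config$momentum, config$weight_decay,
             grad_scale = 1 / length(idx))
    mean_of <- function(f) mean(vapply(stats, f, 1))
    row <- data.frame(iteration = it, lr = lr,
                      L_cls = mean_of(function(s) s$loss$L_cls),
                      L_box = mean_of(function(s) s$loss$L_box),
                      L_mask = mean_of(function(s) s$loss$L_mask),
                      L_total = mean_of(function(s) s$loss$L_total),
                      rpn_cls = mean_of(function(s) s$rpn_cls),
                      rpn_box = mean_of(function(s) s$rpn_box))
    log[[it]] <- row
    if (!is.null(con))
      writeLines(jsonlite::toJSON(as.list(row), auto_unbox = TRUE,
                                  digits = NA), con)
    if (!is.null(checkpoint_path) && checkpoint_every > 0L &&
        it %% checkpoint_every == 0L)
      save_checkpoint(model, checkpoint_path)
  }
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  list(model = model, log = do.call(rbind, log))
}

#' Evaluate a trained model on a dataset
#'
#' Runs prediction over every sample, assembles COCO-style results (RLE
#' masks) and computes the full metrics report for both the box and the
#' segmentation task.
#'
#' @param model trained model or checkpoint path.
#' @param samples list of samples carrying `image_id`s, or a scene list.
#' @param coco_gt COCO ground truth (path or parsed list) for the same ids.
#' @param score_threshold detection score floor.
#' @return list with `box` and `segm` `vineseg_metrics`, plus `results`.
#' @export
evaluate_cmd <- function(model, samples, coco_gt,
                         score_threshold = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (length(samples) == 0L) stop("evaluate_cmd: empty test set")
  if (is.null(score_threshold))
    score_threshold <- model$config$box$score_threshold
  results <- list()
  for (s in samples) {
    dets <- predict_instances(model, s$image, score_threshold)
    for (d in dets) {
      results[[length(results) + 1L]] <- list(
        image_id = s$image_id, category_id = 1L,
        bbox = d$bbox, score = d$score,
        segmentation = rle_encode(d$mask))
    }
  }
  if (is.character(coco_gt)) coco_gt <- read_coco(coco_gt)
  list(box = evaluate(coco_gt, results, "bbox"),
       segm = evaluate(coco_gt, results, "segm"),
       results = results)
}
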