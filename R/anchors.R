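# Anchor geometry and box parameterization for the region proposal network.
#
# Five anchor base sizes {8, 16, 32, 64, 128} (input pixels) are assigned
# one per pyramid level P2..P6 in increasing order; combined with three
# aspect ratios {0.5, 1, 2} they form the 15 benchmark windows. Aspect
# ratio is height/width; width and height are rounded so that the anchor
# area stays within rounding of scale^2.

#' Build the anchor template set
#'
#' @param scales anchor base sizes in input pixels, one per pyramid level in
#'   increasing order.
#' @param ratios aspect ratios (height/width).
#' @return data.frame with `scale`, `aspect_ratio`, `level` (2..6), `width`,
#'   `height`; scale-major, ratio-minor order.
#' @export
build_anchor_templates <- function(scales = c(8, 16, 32, 64, 128),
                                   ratios = c(0.5, 1, 2)) {
  if (length(scales) == 0L || length(ratios) == 0L)
    stop("build_anchor_templates: empty scale or ratio set")
  if (any(scales <= 0) || any(ratios <= 0))
    stop("build_anchor_templates: scales and ratios must be positive")
  out <- expand.grid(aspect_ratio = ratios, scale = scales,
                     KEEP.OUT.ATTRS = FALSE)[, c("scale", "aspect_ratio")]
  out$level <- 1L + match(out$scale, sort(unique(scales)))
  out$width <- round(out$scale / sqrt(out$aspect_ratio))
  out$height <- round(out$scale * sqrt(out$aspect_ratio))
  rownames(out) <- NULL
  out
}

# All anchors for one pyramid level as an xyxy matrix. Enumeration order
# matches the flat layout of the (H, W, A) objectness array: row index
# fastest, then column, then template.
anchors_for_level <- function(H, W, stride, templates) {
  grid <- expand.grid(h = seq_len(H), w = seq_len(W), a = seq_len(nrow(templates)),
                      KEEP.OUT.ATTRS = FALSE)
  cx <- (grid$w - 0.5) * stride
  cy <- (grid$h - 0.5) * stride
  tw <- templates$width[grid$a]
  th <- templates$height[grid$a]
  cbind(cx - tw / 2, cy - th / 2, cx + tw / 2, cy + th / 2)
}

# --- box delta parameterization (Faster R-CNN convention) -------------------

encode_deltas <- function(anchors_xyxy, gt_xyxy, weights = c(1, 1, 1, 1)) {
  aw <- anchors_xyxy[, 3] - anchors_xyxy[, 1]
  ah <- anchors_xyxy[, 4] - anchors_xyxy[, 2]
  ax <- anchors_xyxy[, 1] + aw / 2
  ay <- anchors_xyxy[, 2] + ah / 2
  gw <- gt_xyxy[, 3] - gt_xyxy[, 1]
  gh <- gt_xyxy[, 4] - gt_xyxy[, 2]
  gx <- gt_xyxy[, 1] + gw / 2
  gy <- gt_xyxy[, 2] + gh / 2
  cbind(weights[1] * (gx - ax) / aw,
        weights[2] * (gy - ay) / ah,
        weights[3] * log(gw / aw),
        weights[4] * log(gh / ah))
}

decode_deltas <- function(anchors_xyxy, deltas, weights = c(1, 1, 1, 1)) {
  aw <- anchors_xyxy[, 3] - anchors_xyxy[, 1]
  ah <- anchors_xyxy[, 4] - anchors_xyxy[, 2]
  ax <- anchors_xyxy[, 1] + aw / 2
  ay <- anchors_xyxy[, 2] + ah / 2
  dx <- deltas[, 1] / weights[1]
  dy <- deltas[, 2] / weights[2]
  dw <- pmin(deltas[, 3] / weights[3], log(1000 / 16))
  dh <- pmin(deltas[, 4] / weights[4], log(1000 / 16))
  cx <- ax + dx * aw
  cy <- ay + dy * ah
  w <- aw * exp(dw)
  h <- ah * exp(dh)
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

# Assign RoIs to pyramid levels by scale (canonical FPN heuristic).
assign_roi_levels <- function(boxes_xyxy, k0 = 4L, canonical = 224,
                              lo = 2L, hi = 5L) {
  area <- pmax((boxes_xyxy[, 3] - boxes_xyxy[, 1]) *
               (boxes_xyxy[, 4] - boxes_xyxy[, 2]), 1e-6)
  k <- floor(k0 + log2(sqrt(area) / canonical))
  pmin(pmax(k, lo), hi)
}
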