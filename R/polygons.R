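# Polygon / mask geometry.
#
# Conventions (fixed across the package):
#  * 0-based continuous pixel coordinates: pixel (row r, col c), 0-based,
#    covers x in [c, c+1), y in [r, r+1); its center is (c + 0.5, r + 0.5).
#  * Rasterization: even-odd fill sampled at pixel centers.
#  * Boxes are COCO style (x, y, w, h) unless a function says otherwise.

#' Tightest axis-aligned box around one or more polygons
#'
#' Computes the outer rectangular box from polygon contours, the same way a
#' box is derived automatically from an instance's traced outline instead of
#' being annotated by hand.
#'
#' @param parts a single n x 2 matrix of (x, y) vertices, or a list of such
#'   matrices (e.g. the visible parts of one occlusion-split cluster).
#' @return numeric (x, y, w, h) with `w, h > 0`.
#' @export
polygon_to_bbox <- function(parts) {
  if (is.matrix(parts)) parts <- list(parts)
  stopifnot(length(parts) >= 1L)
  pts <- do.call(rbind, lapply(parts, as_poly_matrix))
  x0 <- min(pts[, 1]); x1 <- max(pts[, 1])
  y0 <- min(pts[, 2]); y1 <- max(pts[, 2])
  if (x1 - x0 <= 0 || y1 - y0 <= 0)
    stop("polygon_to_bbox: degenerate polygon with zero extent")
  c(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
}

# Accepts an n x 2 matrix, a list of (x, y) pairs (LabelMe "points"), or a
# flat x1,y1,x2,y2,... vector (COCO "segmentation" entry).
as_poly_matrix <- function(p) {
  if (is.matrix(p)) {
    m <- cbind(as.numeric(p[, 1]), as.numeric(p[, 2]))
  } else if (is.list(p)) {
    m <- do.call(rbind, lapply(p, function(q) as.numeric(unlist(q))[1:2]))
  } else {
    m <- matrix(as.numeric(p), ncol = 2, byrow = TRUE)
  }
  if (nrow(m) < 3L) stop("polygon must have at least 3 points")
  if (any(!is.finite(m))) stop("polygon coordinates must be finite")
  m
}

#' Rasterize polygons to a binary mask
#'
#' Union (logical OR) of even-odd fills of each polygon, sampled at pixel
#' centers. Polygons extending beyond the canvas are clipped, not an error.
#'
#' @param parts n x 2 matrix or list of matrices of (x, y) vertices.
#' @param height,width canvas size in pixels.
#' @return logical `height` x `width` matrix.
#' @export
rasterize_polygons <- function(parts, height, width) {
  stopifnot(height >= 1, width >= 1)
  if (is.matrix(parts)) parts <- list(parts)
  m <- matrix(FALSE, height, width)
  for (p in parts) {
    pm <- as_poly_matrix(p)
    m <- m | (cpp_fill_polygon(pm, as.integer(height), as.integer(width)) > 0)
  }
  m
}

#' Rasterize an instance record to its binary mask
#'
#' @param record an instance record (see [merge_group_instances()]).
#' @param height,width image size in pixels.
#' @return logical mask; its `sum()` is the instance area.
#' @export
rasterize_instance <- function(record, height, width) {
  rasterize_polygons(record$parts, height, width)
}

# Trace the boundary loops of a binary mask as pixel-corner polygons.
# Rasterizing the result with rasterize_polygons() reproduces the mask
# pixel-for-pixel provided the mask has no holes (fill holes first).
trace_mask_polygons <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  cpp_trace_boundaries(m)
}

# 4-connected component labels of a binary mask
label_components <- function(mask) {
  cpp_label4(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

# fill enclosed background holes (4-connectivity)
fill_mask_holes <- function(mask) {
  cpp_fill_holes4(matrix(as.integer(mask), nrow(mask), ncol(mask))) > 0
}

# --- COCO run-length encoding (uncompressed counts, column-major) ----------

#' Encode a binary mask as uncompressed COCO run-length counts
#'
#' Column-major order, counts alternating (zeros first), as in the COCO
#' `{"size": [h, w], "counts": [...]}` uncompressed RLE form.
#' @param mask logical matrix.
#' @return list with `size` and integer `counts`.
#' @export
rle_encode <- function(mask) {
  v <- as.integer(mask)
  r <- rle(v)
  counts <- r$lengths
  if (length(v) == 0L) counts <- integer(0)
  else if (r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' Decode uncompressed COCO run-length counts to a binary mask
#' @param rle list with `size = c(h, w)` and `counts`.
#' @return logical matrix.
#' @export
rle_decode <- function(rle) {
  h <- rle$size[1]; w <- rle$size[2]
  counts <- as.integer(rle$counts)
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  if (length(vals) != h * w) stop("rle_decode: counts do not sum to h*w")
  matrix(as.logical(vals), h, w)
}

# --- box utilities (xywh <-> xyxy, IoU, clipping, NMS) ----------------------

box_xywh_to_xyxy <- function(b) {
  b <- matrix(b, ncol = 4)
  cbind(b[, 1], b[, 2], b[, 1] + b[, 3], b[, 2] + b[, 4])
}

box_xyxy_to_xywh <- function(b) {
  b <- matrix(b, ncol = 4)
  cbind(b[, 1], b[, 2], b[, 3] - b[, 1], b[, 4] - b[, 2])
}

# IoU matrix between two sets of xywh boxes
box_iou_matrix <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(0, na, nb))
  ax1 <- a[, 1]; ay1 <- a[, 2]; ax2 <- a[, 1] + a[, 3]; ay2 <- a[, 2] + a[, 4]
  bx1 <- b[, 1]; by1 <- b[, 2]; bx2 <- b[, 1] + b[, 3]; by2 <- b[, 2] + b[, 4]
  ix <- pmax(outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax), 0)
  iy <- pmax(outer(ay2, by2, pmin) - outer(ay1, by1, pmax), 0)
  inter <- ix * iy
  ua <- outer(a[, 3] * a[, 4], b[, 3] * b[, 4], "+") - inter
  out <- inter / ua
  out[ua <= 0] <- 0
  out
}

mask_iou_pair <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

clip_boxes_xyxy <- function(b, height, width) {
  b[, 1] <- pmin(pmax(b[, 1], 0), width)
  b[, 3] <- pmin(pmax(b[, 3], 0), width)
  b[, 2] <- pmin(pmax(b[, 2], 0), height)
  b[, 4] <- pmin(pmax(b[, 4], 0), height)
  b
}

# greedy non-maximum suppression on xyxy boxes; returns kept indices
nms_boxes <- function(boxes, scores, iou_threshold) {
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  ord <- order(-scores)
  keep <- integer(0)
  xywh <- box_xyxy_to_xywh(boxes)
  while (length(ord) > 0L) {
    i <- ord[1L]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1L]
    iou <- box_iou_matrix(xywh[i, , drop = FALSE], xywh[rest, , drop = FALSE])
    ord <- rest[iou[1, ] <= iou_threshold]
  }
  keep
}
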