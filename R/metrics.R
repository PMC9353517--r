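# COCO-style evaluation: AP / AP@0.5 / AP@0.75 and AR@{1,10,100} for box
# and mask tasks, following the reference COCO evaluation algorithm
# (greedy best-IoU matching per threshold, 101-point precision
# interpolation, per-image detection caps). A prediction matches a ground
# truth at IoU >= threshold (the reference convention).

COCO_IOU_THRS <- seq(0.5, 0.95, by = 0.05)
COCO_REC_THRS <- seq(0, 1, by = 0.01)

#' Intersection-over-union of boxes or masks
#'
#' @param a,b boxes as (x, y, w, h) vectors / n x 4 matrices, or masks as
#'   logical matrices / lists of logical matrices. Both arguments must be
#'   the same kind.
#' @return scalar IoU for single inputs, otherwise an IoU matrix. An empty
#'   union has IoU 0 by convention.
#' @export
pairwise_iou <- function(a, b) {
  is_box <- function(x) is.numeric(x) && (is.matrix(x) || length(x) == 4L)
  is_mask <- function(x) is.matrix(x) && is.logical(x) ||
    (is.list(x) && all(vapply(x, is.matrix, TRUE)))
  if (is_box(a) && is_box(b)) {
    single <- !is.matrix(a) && !is.matrix(b)
    m <- box_iou_matrix(matrix(a, ncol = 4), matrix(b, ncol = 4))
    return(if (single) m[1, 1] else m)
  }
  if (is_mask(a) && is_mask(b)) {
    la <- if (is.list(a)) a else list(a)
    lb <- if (is.list(b)) b else list(b)
    m <- matrix(0, length(la), length(lb))
    for (i in seq_along(la)) for (j in seq_along(lb))
      m[i, j] <- mask_iou_pair(la[[i]], lb[[j]])
    return(if (!is.list(a) && !is.list(b)) m[1, 1] else m)
  }
  stop("pairwise_iou: mixed or unsupported geometry kinds")
}

#' Greedy one-to-one matching of predictions to ground truths
#'
#' Predictions are visited in descending score order; each is matched to
#' the unmatched ground truth with the highest IoU at or above the
#' threshold. Unmatched predictions are false positives, unmatched ground
#' truths false negatives.
#'
#' @param gts ground truths: n x 4 xywh box matrix or list of logical masks.
#' @param preds list with `boxes` (or `masks`) and `scores`.
#' @param iou_threshold matching threshold.
#' @return list with `counts` (TP, FP, FN), `precision`, `recall`, and
#'   per-prediction logical `tp_flags` (in score order).
#' @export
match_predictions <- function(gts, preds, iou_threshold) {
  masks <- !is.null(preds$masks)
  dt <- if (masks) preds$masks else matrix(preds$boxes, ncol = 4)
  nd <- if (masks) length(dt) else nrow(dt)
  ng <- if (is.list(gts)) length(gts) else nrow(matrix(gts, ncol = 4))
  ord <- order(-preds$scores)
  iou <- if (nd > 0 && ng > 0) pairwise_iou(dt, gts) else matrix(0, nd, ng)
  iou <- matrix(iou, nd, ng)
  gt_used <- rep(FALSE, ng)
  tp <- rep(FALSE, nd)
  for (d in ord) {
    best <- iou_threshold - 1e-10
    m <- 0L
    for (g in seq_len(ng)) {
      if (gt_used[g] || iou[d, g] < best) next
      best <- iou[d, g]; m <- g
    }
    if (m > 0L) { gt_used[m] <- TRUE; tp[d] <- TRUE }
  }
  TP <- sum(tp)
  counts <- list(TP = TP, FP = nd - TP, FN = ng - TP)
  list(counts = counts,
       precision = if (nd > 0) TP / nd else NA_real_,
       recall = if (ng > 0) TP / ng else NA_real_,
       tp_flags = tp[ord])
}

# --- evaluator core ---------------------------------------------------------
# gts, dts: per-image lists. gts[[i]]: list(boxes = n x 4 xywh, masks = list)
# dts[[i]]: list(boxes, scores, masks). kind: "bbox" or "segm".

coco_eval_core <- function(gts, dts, kind = "bbox",
                           iou_thrs = COCO_IOU_THRS,
                           max_dets = c(1L, 10L, 100L)) {
  stopifnot(length(gts) == length(dts), length(iou_thrs) >= 1L)
  n_img <- length(gts)
  cap <- max(max_dets)
  T <- length(iou_thrs)
  per_img <- vector("list", n_img)
  n_gt_total <- 0L
  for (i in seq_len(n_img)) {
    g <- gts[[i]]; d <- dts[[i]]
    ng <- if (kind == "segm") length(g$masks) else
      (if (is.null(g$boxes)) 0L else nrow(g$boxes))
    nd_all <- length(d$scores)
    ord <- utils::head(order(-d$scores), cap)
    nd <- length(ord)
    n_gt_total <- n_gt_total + ng
    iou <- if (nd > 0 && ng > 0) {
      if (kind == "segm") pairwise_iou(d$masks[ord], g$masks)
      else pairwise_iou(d$boxes[ord, , drop = FALSE], g$boxes)
    } else matrix(0, nd, ng)
    iou <- matrix(iou, nd, ng)
    dtm <- matrix(0L, T, nd)
    for (t in seq_len(T)) {
      thr <- min(iou_thrs[t], 1 - 1e-10)
      gt_used <- rep(FALSE, ng)
      for (dd in seq_len(nd)) {
        best <- thr - 1e-10
        m <- 0L
        for (gg in seq_len(ng)) {
          if (gt_used[gg] || iou[dd, gg] < best) next
          best <- iou[dd, gg]; m <- gg
        }
        if (m > 0L) { gt_used[m] <- TRUE; dtm[t, dd] <- m }
      }
    }
    per_img[[i]] <- list(scores = d$scores[ord], dtm = dtm, n_gt = ng)
  }

  if (n_gt_total == 0L) {
    return(list(AP = rep(-1, T), AR = setNames(rep(-1, length(max_dets)),
                                               paste0("AR", max_dets)),
                iou_thrs = iou_thrs, n_gt = 0L))
  }

  ap_per_thr <- numeric(T)
  ar_per_k <- numeric(length(max_dets))
  for (ki in seq_along(max_dets)) {
    k <- max_dets[ki]
    scores <- unlist(lapply(per_img, function(p) utils::head(p$scores, k)))
    recalls_k <- numeric(T)
    aps_k <- numeric(T)
    for (t in seq_len(T)) {
      matched <- unlist(lapply(per_img, function(p)
        utils::head(p$dtm[t, ], k))) > 0
      if (length(scores) == 0L) {
        aps_k[t] <- 0; recalls_k[t] <- 0
        next
      }
      ord <- order(-scores)
      tps <- cumsum(matched[ord])
      fps <- cumsum(!matched[ord])
      rc <- tps / n_gt_total
      pr <- tps / (tps + fps)
      recalls_k[t] <- rc[length(rc)]
      # monotone envelope then 101-point interpolation
      pr <- rev(cummax(rev(pr)))
      idx <- findInterval(COCO_REC_THRS, rc, left.open = TRUE) + 1L
      q <- ifelse(idx <= length(pr), pr[pmin(idx, length(pr))], 0)
      aps_k[t] <- mean(q)
    }
    ar_per_k[ki] <- mean(recalls_k)
    if (k == max(max_dets)) ap_per_thr <- aps_k
  }
  list(AP = ap_per_thr,
       AR = setNames(ar_per_k, paste0("AR", max_dets)),
       iou_thrs = iou_thrs, n_gt = n_gt_total)
}

#' Average precision over a set of IoU thresholds
#'
#' 101-point interpolated AP per threshold, averaged over the threshold
#' set (the primary metric uses the 10 thresholds 0.50:0.05:0.95).
#'
#' @param gts,preds per-image lists: `gts[[i]]` has `boxes` (xywh) and/or
#'   `masks`; `preds[[i]]` additionally has `scores`.
#' @param iou_thresholds numeric vector of thresholds.
#' @param kind "bbox" or "segm".
#' @return mean AP (fraction); per-threshold values in attribute
#'   `per_threshold`. Returns -1 (sentinel) when there are no ground truths.
#' @export
average_precision <- function(gts, preds, iou_thresholds = COCO_IOU_THRS,
                              kind = "bbox") {
  r <- coco_eval_core(gts, preds, kind, iou_thresholds)
  structure(mean(r$AP), per_threshold = r$AP)
}

#' Average recall at a detection cap
#'
#' Maximum recall with at most `max_detections` highest-scoring detections
#' per image, averaged over the 10 IoU thresholds.
#'
#' @inheritParams average_precision
#' @param max_detections per-image cap (1, 10 or 100).
#' @return AR (fraction); -1 when there are no ground truths.
#' @export
average_recall <- function(gts, preds, max_detections = 100L,
                           kind = "bbox") {
  r <- coco_eval_core(gts, preds, kind, COCO_IOU_THRS,
                      max_dets = as.integer(max_detections))
  as.numeric(r$AR[1])
}

# --- COCO container adapters -------------------------------------------------

coco_gt_to_core <- function(gt, task) {
  imgs <- gt$images
  ids <- vapply(imgs, function(im) as.integer(im$id), 1L)
  o <- order(ids)
  imgs <- imgs[o]; ids <- ids[o]
  hw <- lapply(imgs, function(im) c(as.integer(im$height), as.integer(im$width)))
  per <- setNames(vector("list", length(ids)), as.character(ids))
  for (i in seq_along(per)) per[[i]] <- list(boxes = NULL, masks = list())
  for (a in gt$annotations) {
    key <- as.character(as.integer(a$image_id))
    if (is.null(per[[key]]))
      stop("evaluate: annotation references unknown image id ", a$image_id)
    b <- as.numeric(unlist(a$bbox))
    per[[key]]$boxes <- rbind(per[[key]]$boxes, b)
    if (task == "segm") {
      d <- hw[[match(key, as.character(ids))]]
      per[[key]]$masks <- c(per[[key]]$masks,
                            list(decode_segmentation(a$segmentation, d[1], d[2])))
    }
  }
  list(per = per, ids = ids, hw = hw)
}

decode_segmentation <- function(seg, height, width) {
  if (!is.null(seg$counts)) return(rle_decode(list(size = as.integer(unlist(seg$size)),
                                                   counts = as.integer(unlist(seg$counts)))))
  rasterize_polygons(lapply(seg, function(p) as.numeric(unlist(p))), height, width)
}

#' Evaluate COCO-format results against COCO ground truth
#'
#' @param coco_gt ground truth: path to a COCO JSON or the parsed list.
#' @param coco_results detections: path to a COCO results JSON or a list of
#'   detections (`image_id`, `category_id`, `bbox`, `score`, and for the
#'   segmentation task a polygon or RLE `segmentation`).
#' @param task `"bbox"` or `"segm"`.
#' @return `vineseg_metrics` list: `task`, `AP`, `AP50`, `AP75`, `AR1`,
#'   `AR10`, `AR100` as fractions (and `percent`, the same on the 0-100
#'   scale the tables print). -1 marks the no-ground-truth sentinel.
#' @export
evaluate <- function(coco_gt, coco_results, task = c("bbox", "segm")) {
  task <- match.arg(task)
  if (is.character(coco_gt)) coco_gt <- read_coco(coco_gt)
  if (is.character(coco_results)) coco_results <- read_coco(coco_results)
  core_gt <- coco_gt_to_core(coco_gt, task)
  ids <- core_gt$ids
  dts <- setNames(vector("list", length(ids)), as.character(ids))
  for (i in seq_along(dts)) dts[[i]] <- list(boxes = NULL, scores = numeric(0),
                                             masks = list())
  orphans <- c()
  for (d in coco_results) {
    key <- as.character(as.integer(d$image_id))
    if (is.null(dts[[key]])) { orphans <- c(orphans, key); next }
    dts[[key]]$boxes <- rbind(dts[[key]]$boxes, as.numeric(unlist(d$bbox)))
    dts[[key]]$scores <- c(dts[[key]]$scores, as.numeric(d$score))
    if (task == "segm") {
      hw <- core_gt$hw[[match(key, as.character(ids))]]
      dts[[key]]$masks <- c(dts[[key]]$masks,
                            list(decode_segmentation(d$segmentation, hw[1], hw[2])))
    }
  }
  if (length(orphans))
    stop("evaluate: results reference unknown image ids: ",
         paste(unique(orphans), collapse = ", "))
  r <- coco_eval_core(core_gt$per, dts, kind = task)
  sentinel <- r$n_gt == 0L
  rep_at <- function(thr) if (sentinel) -1 else r$AP[match(thr, r$iou_thrs)]
  out <- list(task = task,
              AP = if (sentinel) -1 else mean(r$AP),
              AP50 = rep_at(0.5),
              AP75 = rep_at(0.75),
              AR1 = as.numeric(r$AR["AR1"]),
              AR10 = as.numeric(r$AR["AR10"]),
              AR100 = as.numeric(r$AR["AR100"]))
  out$percent <- lapply(out[c("AP", "AP50", "AP75", "AR1", "AR10", "AR100")],
                        function(v) if (v < 0) -1 else 100 * v)
  structure(out, class = "vineseg_metrics")
}

#' @export
print.vineseg_metrics <- function(x, ...) {
  cat(metrics_report_text(x), sep = "\n")
  invisible(x)
}

#' Plain-text metrics table (fractions and percentages)
#'
#' One row per metric in the standard COCO report order.
#' @param ... one or more `vineseg_metrics` reports (e.g. box and segm).
#' @return character vector of lines.
#' @export
metrics_report_text <- function(...) {
  reports <- list(...)
  rows <- c("AP", "AP50", "AP75", "AR1", "AR10", "AR100")
  labels <- c("AP", "AP IoU=0.5", "AP IoU=0.75",
              "AR max=1", "AR max=10", "AR max=100")
  cols <- vapply(reports, function(r) r$task, "")
  lines <- sprintf("%-14s %s", "Metric",
                   paste(sprintf("%12s", cols), collapse = ""))
  for (i in seq_along(rows)) {
    vals <- vapply(reports, function(r) {
      v <- r[[rows[i]]]
      if (v < 0) "   --" else sprintf("%6.2f (%.4f)", 100 * v, v)
    }, "")
    lines <- c(lines, sprintf("%-14s %s", labels[i],
                              paste(sprintf("%12s", vals), collapse = "")))
  }
  lines
}
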