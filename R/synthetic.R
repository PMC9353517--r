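# Synthetic vineyard scenes.
#
# The generator's contract is annotation structure, not photorealism:
# clusters are unions of berry discs scattered around an elliptical
# envelope, occluders are full-height bars (trunks / wires) drawn after the
# clusters, and every instance's polygons are re-derived from its visible
# pixels by boundary tracing - mirroring how an annotator traces the visible
# parts of an occluded cluster and ties them together with one group id.

#' Configuration for a synthetic vineyard scene
#'
#' The two scale regimes emulate the two acquisition distances of the field
#' protocol: `near` (camera 50-100 cm from the canopy: larger clusters,
#' fewer per image) and `far` (100-150 cm: smaller clusters, more of them).
#' Brightness / contrast / saturation jitter emulates down-light vs
#' back-light capture.
#'
#' @param image_height,image_width canvas size in pixels.
#' @param scale_regime `"near"` or `"far"`; sets regime defaults for any of
#'   `n_clusters_range`, `berries_per_cluster_range`, `berry_radius_range`
#'   not supplied explicitly.
#' @param n_clusters_range integer interval, clusters per image.
#' @param berries_per_cluster_range integer interval.
#' @param berry_radius_range pixel interval.
#' @param occluder_probability chance, per cluster, that a bar occluder is
#'   drawn through it.
#' @param occluder_width_range pixel interval for bar width.
#' @param photometric_jitter list of `brightness`, `contrast`, `saturation`
#'   multiplier ranges.
#' @param seed integer; identical (config, seed) pairs produce bit-identical
#'   scenes.
#' @return a `vineseg_scene_config` list.
#' @export
scene_config <- function(image_height = 256L, image_width = 256L,
                         scale_regime = c("near", "far"),
                         n_clusters_range = NULL,
                         berries_per_cluster_range = NULL,
                         berry_radius_range = NULL,
                         occluder_probability = 0.3,
                         occluder_width_range = c(6L, 14L),
                         photometric_jitter = list(
                           brightness = c(0.7, 1.3),
                           contrast = c(0.8, 1.2),
                           saturation = c(0.8, 1.2)),
                         seed = 1L) {
  scale_regime <- match.arg(scale_regime)
  if (is.null(n_clusters_range))
    n_clusters_range <- if (scale_regime == "near") c(1L, 6L) else c(5L, 16L)
  if (is.null(berries_per_cluster_range))
    berries_per_cluster_range <- c(10L, 30L)
  if (is.null(berry_radius_range))
    berry_radius_range <- if (scale_regime == "near") c(7L, 14L) else c(3L, 7L)
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              scale_regime = scale_regime,
              n_clusters_range = as.integer(n_clusters_range),
              berries_per_cluster_range = as.integer(berries_per_cluster_range),
              berry_radius_range = as.numeric(berry_radius_range),
              occluder_probability = occluder_probability,
              occluder_width_range = as.numeric(occluder_width_range),
              photometric_jitter = photometric_jitter,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "vineseg_scene_config")
}

#' Tiny scene preset for CPU tests and the overfit smoke run
#'
#' 128 x 128 canvas with at most 3 clusters.
#' @param ... overrides passed to [scene_config()].
#' @export
scene_config_tiny <- function(...) {
  args <- list(image_height = 128L, image_width = 128L,
               scale_regime = "near",
               n_clusters_range = c(1L, 3L),
               berries_per_cluster_range = c(8L, 18L),
               berry_radius_range = c(7L, 12L),
               occluder_probability = 0.25,
               occluder_width_range = c(4L, 8L))
  do.call(scene_config, modifyList(args, list(...)))
}

validate_scene_config <- function(cfg) {
  chk_range <- function(r, name, min_lo = 0) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < min_lo)
      stop("scene_config: invalid ", name)
  }
  if (cfg$image_height < 8L || cfg$image_width < 8L)
    stop("scene_config: degenerate image size")
  chk_range(cfg$n_clusters_range, "n_clusters_range")
  chk_range(cfg$berries_per_cluster_range, "berries_per_cluster_range", 1)
  chk_range(cfg$berry_radius_range, "berry_radius_range", 1)
  chk_range(cfg$occluder_width_range, "occluder_width_range", 1)
  if (cfg$occluder_probability < 0 || cfg$occluder_probability > 1)
    stop("scene_config: occluder_probability must be in [0, 1]")
  invisible(cfg)
}

sample_int_range <- function(r) if (r[1] >= r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)

# draw a filled disc into (H,W) channels; returns updated list(img, mask)
draw_disc <- function(img, mask, cx, cy, rad, col) {
  h <- nrow(mask); w <- ncol(mask)
  r0 <- max(1L, floor(cy - rad) + 1L); r1 <- min(h, ceiling(cy + rad) + 1L)
  c0 <- max(1L, floor(cx - rad) + 1L); c1 <- min(w, ceiling(cx + rad) + 1L)
  if (r0 > r1 || c0 > c1) return(list(img = img, mask = mask))
  ys <- (r0:r1) - 0.5; xs <- (c0:c1) - 0.5
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  inside <- d2 <= rad^2
  if (!any(inside)) return(list(img = img, mask = mask))
  # cheap radial shading so berries look rounded
  shade <- 1 - 0.35 * sqrt(pmin(d2, rad^2)) / rad
  for (ch in 1:3) {
    patch <- img[r0:r1, c0:c1, ch]
    patch[inside] <- col[ch] * shade[inside]
    img[r0:r1, c0:c1, ch] <- patch
  }
  m <- mask[r0:r1, c0:c1]
  m[inside] <- TRUE
  mask[r0:r1, c0:c1] <- m
  list(img = img, mask = mask)
}

#' Generate one labelled synthetic vineyard scene
#'
#' Clusters crossed by an occluder (or hidden by a nearer cluster) are
#' emitted as several polygons sharing one integer `group_id`; unsplit
#' clusters are single polygons with no group id. Rasterizing a scene's
#' polygons, grouped by id, reproduces its ground-truth masks
#' pixel-for-pixel.
#'
#' @param config a [scene_config()].
#' @return a `vineseg_scene`: list with integer `image` (H x W x 3, 0-255),
#'   `shapes` (label / points / group_id), and `masks` (one logical matrix
#'   per instance, aligned with unique instances in `shapes`).
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  h <- config$image_height; w <- config$image_width
  # leafy background with coarse structure
  base <- c(58, 92, 48)
  img <- array(0, c(h, w, 3))
  gh <- max(2L, h %/% 16L); gw <- max(2L, w %/% 16L)
  for (ch in 1:3) {
    coarse <- matrix(rnorm(gh * gw, base[ch], 18), gh, gw)
    img[, , ch] <- cpp_bilinear_resize(coarse, h, w)
  }

  n_clusters <- sample_int_range(config$n_clusters_range)
  cluster_masks <- list()
  if (n_clusters > 0) {
    for (k in seq_len(n_clusters)) {
      cx <- runif(1, 0.1 * w, 0.9 * w)
      cy <- runif(1, 0.1 * h, 0.9 * h)
      nb <- sample_int_range(config$berries_per_cluster_range)
      rad_mid <- mean(config$berry_radius_range)
      a <- runif(1, 1.2, 2.2) * rad_mid          # envelope semi-axes
      b <- runif(1, 1.6, 3.0) * rad_mid          # clusters hang: taller than wide
      base_col <- c(95, 62, 128) + rnorm(3, 0, 10)
      mask <- matrix(FALSE, h, w)
      for (i in seq_len(nb)) {
        bx <- cx + rnorm(1, 0, a / 1.8)
        by <- cy + rnorm(1, 0, b / 1.8)
        br <- runif(1, config$berry_radius_range[1], config$berry_radius_range[2])
        col <- pmax(pmin(base_col + rnorm(3, 0, 12), 255), 0)
        res <- draw_disc(img, mask, bx, by, br, col)
        img <- res$img; mask <- res$mask
      }
      mask <- fill_mask_holes(mask)
      # a physical cluster is one connected blob: stray outlier berries stay
      # in the image as unlabeled distractors but leave the annotation
      lab <- label_components(mask)
      if (max(lab) > 1L) mask <- lab == which.max(tabulate(lab))
      cluster_masks[[k]] <- mask
    }
    # Overlapping clusters keep their full annotated extent (an annotator
    # labels each cluster whole even where a nearer one partly covers it);
    # only bar occluders cut pixels out of the ground truth and split
    # instances. A cluster more than half hidden by nearer (later-drawn)
    # clusters is imperceptible and goes unannotated, as hidden clusters
    # do in field datasets.
    if (n_clusters > 1) {
      hidden <- rep(FALSE, n_clusters)
      for (k in seq_len(n_clusters - 1L)) {
        vis <- cluster_masks[[k]]
        for (j in seq.int(k + 1L, n_clusters)) vis <- vis & !cluster_masks[[j]]
        hidden[k] <- sum(vis) < 0.5 * sum(cluster_masks[[k]])
      }
      cluster_masks <- cluster_masks[!hidden]
      n_clusters <- length(cluster_masks)
    }
    # bar occluders (trunks / wires), drawn after the clusters
    for (k in seq_len(n_clusters)) {
      if (runif(1) >= config$occluder_probability) next
      if (!any(cluster_masks[[k]])) next
      idx <- which(cluster_masks[[k]], arr.ind = TRUE)
      cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
      theta <- runif(1, -pi / 9, pi / 9)          # near-vertical bar
      bw <- runif(1, config$occluder_width_range[1], config$occluder_width_range[2])
      dvec <- c(sin(theta), cos(theta))
      nvec <- c(dvec[2], -dvec[1])
      L <- h + w
      p0 <- c(cx, cy) - L * dvec; p1 <- c(cx, cy) + L * dvec
      corners <- rbind(p0 + bw / 2 * nvec, p1 + bw / 2 * nvec,
                       p1 - bw / 2 * nvec, p0 - bw / 2 * nvec)
      bar <- cpp_fill_polygon(corners, h, w) > 0
      col <- c(92, 66, 44) + rnorm(3, 0, 6)
      for (ch in 1:3) {
        patch <- img[, , ch]
        patch[bar] <- col[ch] + rnorm(sum(bar), 0, 5)
        img[, , ch] <- patch
      }
      for (j in seq_len(n_clusters))
        cluster_masks[[j]] <- cluster_masks[[j]] & !bar
    }
  }

  # derive polygons from visible pixels (what an annotator would trace)
  shapes <- list()
  masks <- list()
  inst <- 0L
  for (k in seq_along(cluster_masks)) {
    vis <- cluster_masks[[k]]
    if (!any(vis)) next
    lab <- label_components(vis)
    polys <- list()
    gt <- matrix(FALSE, h, w)
    for (cc in seq_len(max(lab))) {
      comp <- lab == cc
      if (sum(comp) < 4L) next
      comp <- fill_mask_holes(comp)
      gt <- gt | comp
      polys <- c(polys, trace_mask_polygons(comp))
    }
    if (length(polys) == 0L) next
    inst <- inst + 1L
    gid <- if (length(polys) > 1L) inst else NA_integer_
    for (p in polys)
      shapes[[length(shapes) + 1L]] <-
        list(label = "grape", points = p, group_id = gid)
    masks[[inst]] <- gt
  }

  # photometric jitter (brightness / contrast / saturation)
  pj <- config$photometric_jitter
  br <- runif(1, pj$brightness[1], pj$brightness[2])
  ct <- runif(1, pj$contrast[1], pj$contrast[2])
  st <- runif(1, pj$saturation[1], pj$saturation[2])
  img <- (img - 128) * ct + 128
  img <- img * br
  luma <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  for (ch in 1:3) img[, , ch] <- luma + (img[, , ch] - luma) * st
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"

  structure(list(image = img, shapes = shapes, masks = masks, config = config),
            class = "vineseg_scene")
}

#' Generate a synthetic dataset on disk
#'
#' Writes one PNG image plus one LabelMe-style JSON per scene and a
#' `manifest.json` listing files and per-image instance counts. Scene `i`
#' uses seed `config$seed + i - 1`.
#'
#' @param config a [scene_config()].
#' @param n_images number of scenes (>= 0).
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(config, n_images, out_dir) {
  stopifnot(n_images >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("generate_dataset: cannot create ", out_dir)
  entries <- list()
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    scene <- generate_scene(cfg)
    stem <- sprintf("scene_%04d", i)
    img_file <- paste0(stem, ".png")
    json_file <- paste0(stem, ".json")
    png::writePNG(scene$image / 255, file.path(out_dir, img_file))
    write_labelme(scene, img_file, file.path(out_dir, json_file))
    entries[[i]] <- list(image = img_file, annotation = json_file,
                         n_instances = length(scene$masks),
                         n_polygons = length(scene$shapes))
  }
  manifest <- list(n_images = n_images, seed = config$seed,
                   scale_regime = config$scale_regime, images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_labelme <- function(scene, image_path, json_path) {
  shapes <- lapply(scene$shapes, function(s) {
    pts <- lapply(seq_len(nrow(s$points)), function(i) as.numeric(s$points[i, ]))
    list(label = jsonlite::unbox(s$label),
         points = pts,
         group_id = if (is.na(s$group_id)) NULL else jsonlite::unbox(as.integer(s$group_id)),
         shape_type = jsonlite::unbox("polygon"),
         flags = structure(list(), names = character(0)))
  })
  doc <- list(version = jsonlite::unbox("5.0.1"),
              flags = structure(list(), names = character(0)),
              shapes = shapes,
              imagePath = jsonlite::unbox(image_path),
              imageData = NULL,
              imageHeight = jsonlite::unbox(nrow(scene$image)),
              imageWidth = jsonlite::unbox(ncol(scene$image)))
  json <- jsonlite::toJSON(doc, null = "null", digits = NA, pretty = TRUE)
  writeLines(json, json_path)
}
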