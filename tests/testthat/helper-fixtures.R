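# Shared fixtures: tiny scenes, in-memory COCO containers, perturbed
# predictions, the external evaluator oracle, numeric gradients.

make_tiny_samples <- function(n = 4, seed = 100, ...) {
  scenes <- lapply(seq_len(n), function(i)
    generate_scene(scene_config_tiny(seed = seed + i, ...)))
  samples <- lapply(scenes, scene_to_sample)
  for (i in seq_len(n)) samples[[i]]$image_id <- i
  samples
}

gt_from_samples <- function(samples) {
  images <- lapply(seq_along(samples), function(i)
    list(id = i, file_name = sprintf("s%d.png", i),
         height = dim(samples[[i]]$image)[1],
         width = dim(samples[[i]]$image)[2]))
  anns <- list()
  for (i in seq_along(samples)) {
    for (inst in samples[[i]]$instances) {
      anns[[length(anns) + 1L]] <- list(
        id = length(anns) + 1L, image_id = i, category_id = 1L,
        bbox = as.numeric(inst$bbox), area = sum(inst$mask), iscrowd = 0L,
        segmentation = rle_encode(inst$mask))
    }
  }
  list(images = images, annotations = anns,
       categories = list(list(id = 1L, name = "grape")))
}

shift_mask <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- (1:h) + dy; cs <- (1:w) + dx
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[rs[ok_r], cs[ok_c]] <- m[which(ok_r), which(ok_c)]
  out
}

# jittered copies of the ground truth plus false positives, random scores
perturb_predictions <- function(gt, seed = 1, keep_prob = 0.85, n_fp = 8) {
  set.seed(seed)
  results <- list()
  img_by_id <- setNames(gt$images,
                        vapply(gt$images, function(i) as.character(i$id), ""))
  for (a in gt$annotations) {
    if (runif(1) >= keep_prob) next
    img <- img_by_id[[as.character(a$image_id)]]
    m <- vineseg:::decode_segmentation(a$segmentation, img$height, img$width)
    m2 <- shift_mask(m, sample(-4:4, 1), sample(-4:4, 1))
    bb <- as.numeric(unlist(a$bbox)) + rnorm(4, 0, 2)
    bb[3:4] <- pmax(bb[3:4], 2)
    results[[length(results) + 1L]] <- list(
      image_id = a$image_id, category_id = 1L, bbox = bb,
      score = runif(1), segmentation = rle_encode(m2))
  }
  for (k in seq_len(n_fp)) {
    img <- gt$images[[sample(length(gt$images), 1)]]
    x <- runif(1, 0, img$width - 20); y <- runif(1, 0, img$height - 20)
    bw <- runif(1, 10, 40); bh <- runif(1, 10, 40)
    m <- matrix(FALSE, img$height, img$width)
    rr <- max(1, round(y)):min(img$height, round(y + bh))
    cc <- max(1, round(x)):min(img$width, round(x + bw))
    m[rr, cc] <- TRUE
    results[[length(results) + 1L]] <- list(
      image_id = img$id, category_id = 1L, bbox = c(x, y, bw, bh),
      score = runif(1), segmentation = rle_encode(m))
  }
  results
}

write_gt_json <- function(gt, path) {
  ub <- jsonlite::unbox
  gt$images <- lapply(gt$images, function(i) lapply(i, ub))
  gt$annotations <- lapply(gt$annotations, function(a) {
    a$id <- ub(a$id); a$image_id <- ub(a$image_id)
    a$category_id <- ub(a$category_id); a$area <- ub(a$area)
    a$iscrowd <- ub(a$iscrowd)
    a
  })
  gt$categories <- lapply(gt$categories, function(c) lapply(c, ub))
  writeLines(jsonlite::toJSON(gt, digits = NA, null = "null"), path)
  path
}

write_results_json <- function(results, path) {
  out <- lapply(results, function(r) {
    r$image_id <- jsonlite::unbox(r$image_id)
    r$category_id <- jsonlite::unbox(r$category_id)
    r$score <- jsonlite::unbox(r$score)
    r
  })
  writeLines(jsonlite::toJSON(out, digits = NA, null = "null"), path)
  path
}

run_eval_oracle <- function(gt_json, res_json, task) {
  script <- system.file("oracle", "coco_eval_oracle.py", package = "vineseg")
  out <- system2("python", c(script, gt_json, res_json, task), stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
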