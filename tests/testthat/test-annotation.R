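# Annotation pipeline: group-id merging, outer boxes, rasterization,
# COCO conversion, dataset splitting.

tri <- function(x0, y0, s = 1) matrix(c(x0, y0, x0 + s, y0, x0, y0 + s),
                                      ncol = 2, byrow = TRUE)
shp <- function(pts, gid = NA_integer_, label = "grape")
  list(label = label, points = pts, group_id = as.integer(gid))

test_that("shapes sharing a group id collapse into one multi-part instance", {
  shapes <- list(shp(tri(0, 0), 1), shp(tri(5, 5), 1), shp(tri(10, 0)))
  recs <- merge_group_instances(shapes)
  expect_length(recs, 2)
  expect_identical(recs[[1]]$n_parts, 2L)
  expect_identical(recs[[2]]$n_parts, 1L)
  # output order is by first appearance
  expect_identical(recs[[1]]$instance_id, 1L)
})

test_that("ungrouped shapes each become single-part instances", {
  shapes <- list(shp(tri(0, 0)), shp(tri(4, 0)), shp(tri(8, 0)))
  recs <- merge_group_instances(shapes)
  expect_length(recs, 3)
  expect_true(all(vapply(recs, function(r) r$n_parts, 1L) == 1L))
})

test_that("conflicting labels under one group id are a validation error", {
  shapes <- list(shp(tri(0, 0), 1), shp(tri(5, 5), 1, label = "leaf"))
  expect_error(merge_group_instances(shapes), "conflicting labels")
})

test_that("merged bbox is the min/max over all member vertices", {
  set.seed(4)
  for (rep in 1:10) {
    parts <- lapply(1:3, function(i)
      matrix(runif(8, 0, 50), ncol = 2))
    shapes <- lapply(parts, function(p) shp(p, 7))
    rec <- merge_group_instances(shapes)[[1]]
    all_pts <- do.call(rbind, parts)
    expect_equal(unname(rec$bbox),
                 c(min(all_pts[, 1]), min(all_pts[, 2]),
                   max(all_pts[, 1]) - min(all_pts[, 1]),
                   max(all_pts[, 2]) - min(all_pts[, 2])))
  }
})

test_that("polygon_to_bbox matches worked examples and is order-invariant", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(unname(polygon_to_bbox(sq)), c(0, 0, 1, 1))
  t1 <- matrix(c(2, 3, 4, 3, 3, 5), ncol = 2, byrow = TRUE)
  t2 <- matrix(c(8, 6, 10, 8, 9, 6), ncol = 2, byrow = TRUE)
  expect_equal(unname(polygon_to_bbox(list(t1, t2))), c(2, 3, 8, 5))
  expect_equal(unname(polygon_to_bbox(list(t2, t1))), c(2, 3, 8, 5))
  expect_equal(unname(polygon_to_bbox(t1[c(3, 1, 2), ])),
               unname(polygon_to_bbox(t1)))
  expect_error(polygon_to_bbox(matrix(c(0, 0, 0, 5, 0, 9), ncol = 2,
                                      byrow = TRUE)), "zero extent|degenerate")
})

test_that("rasterization follows the even-odd pixel-center fill rule", {
  sq10 <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10), ncol = 2, byrow = TRUE)
  m <- rasterize_polygons(sq10, 20, 20)
  expect_identical(sum(m), 100L)
  # brute-force even-odd point-in-polygon at pixel centers
  pip <- function(px, py, poly) {
    n <- nrow(poly); cross <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- poly[i, 2]; y2 <- poly[j, 2]
      if ((y1 <= py) != (y2 <= py)) {
        xi <- poly[i, 1] + (py - y1) * (poly[j, 1] - poly[i, 1]) / (y2 - y1)
        if (px < xi) cross <- cross + 1
      }
    }
    cross %% 2 == 1
  }
  set.seed(8)
  poly <- matrix(c(2.3, 1.1, 14.8, 3.2, 11.5, 13.7, 4.1, 9.9), ncol = 2,
                 byrow = TRUE)
  m2 <- rasterize_polygons(poly, 16, 16)
  ref <- outer(1:16, 1:16, Vectorize(function(r, c)
    pip(c - 0.5, r - 0.5, poly)))
  expect_identical(unname(m2), unname(ref))
})

test_that("disjoint parts rasterize to the sum of their areas", {
  a <- matrix(c(0, 0, 4, 0, 4, 4, 0, 4), ncol = 2, byrow = TRUE)
  b <- matrix(c(10, 10, 14, 10, 14, 14, 10, 14), ncol = 2, byrow = TRUE)
  m <- rasterize_polygons(list(a, b), 20, 20)
  expect_identical(sum(m), sum(rasterize_polygons(a, 20, 20)) +
                             sum(rasterize_polygons(b, 20, 20)))
})

test_that("polygons fully outside the canvas clip to an empty mask", {
  far <- matrix(c(100, 100, 110, 100, 110, 110, 100, 110), ncol = 2,
                byrow = TRUE)
  expect_identical(sum(rasterize_polygons(far, 20, 20)), 0L)
})

test_that("merging then rasterizing equals OR of per-part rasterization", {
  s <- generate_scene(scene_config_tiny(seed = 31, occluder_probability = 1))
  recs <- merge_group_instances(s$shapes, 128, 128)
  for (r in recs) {
    ors <- Reduce(`|`, lapply(r$parts, function(p)
      rasterize_polygons(p, 128, 128)))
    expect_identical(r$mask, ors)
  }
})

test_that("COCO conversion counts images/annotations and keeps split instances whole", {
  dir <- withr::local_tempdir()
  # seeds chosen to include occluder-split clusters
  n_img <- 6
  generate_dataset(scene_config_tiny(seed = 300, occluder_probability = 0.9),
                   n_img, dir)
  out <- file.path(withr::local_tempdir(), "coco.json")
  summary <- labelme_to_coco(dir, out)
  gt <- read_coco(out)
  expect_length(gt$images, n_img)
  expect_length(gt$categories, 1)
  expect_identical(gt$categories[[1]]$name, "grape")
  # one annotation per merged instance
  n_expected <- 0L
  multi <- 0L
  for (i in seq_len(n_img)) {
    lm <- read_labelme(file.path(dir, sprintf("scene_%04d.json", i)))
    recs <- merge_group_instances(lm$shapes)
    n_expected <- n_expected + length(recs)
    multi <- multi + sum(vapply(recs, function(r) r$n_parts, 1L) > 1L)
  }
  expect_identical(length(gt$annotations), n_expected)
  expect_gt(multi, 0)  # the fixture really contains split clusters
  n_multi_coco <- sum(vapply(gt$annotations,
                             function(a) length(a$segmentation) > 1L, TRUE))
  expect_identical(n_multi_coco, multi)
  expect_true(all(vapply(gt$annotations, function(a) a$iscrowd == 0, TRUE)))
})

test_that("stored COCO areas equal areas recomputed from decoded masks", {
  dir <- withr::local_tempdir()
  generate_dataset(scene_config_tiny(seed = 41, occluder_probability = 0.8),
                   3, dir)
  out <- file.path(dir, "coco.json")
  labelme_to_coco(dir, out)
  gt <- read_coco(out)
  for (a in gt$annotations) {
    img <- gt$images[[as.integer(a$image_id)]]
    m <- vineseg:::decode_segmentation(a$segmentation, img$height, img$width)
    expect_identical(sum(m), as.integer(a$area))
    # bbox covers the mask support
    bb <- as.numeric(unlist(a$bbox))
    idx <- which(m, arr.ind = TRUE)
    expect_true(min(idx[, 2]) - 1 >= floor(bb[1]))
    expect_true(max(idx[, 2]) <= ceiling(bb[1] + bb[3]))
  }
})

test_that("independent COCO tooling reproduces the converter's areas", {
  dir <- withr::local_tempdir()
  generate_dataset(scene_config_tiny(seed = 55, occluder_probability = 0.8),
                   3, dir)
  out <- file.path(dir, "coco.json")
  labelme_to_coco(dir, out)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    sprintf("sys.path.insert(0, %s)",
            deparse(dirname(system.file("oracle", "coco_eval_oracle.py",
                                        package = "vineseg")))),
    "import coco_eval_oracle as oc",
    sprintf("gt = json.load(open(%s))", deparse(out)),
    "hw = {im['id']: (im['height'], im['width']) for im in gt['images']}",
    "areas = [int(oc.decode_segmentation(a['segmentation'], *hw[a['image_id']]).sum())",
    "         for a in gt['annotations']]",
    "print(json.dumps(areas))"), script)
  py_areas <- jsonlite::fromJSON(paste(system2("python", script, stdout = TRUE),
                                       collapse = ""))
  gt <- read_coco(out)
  r_areas <- vapply(gt$annotations, function(a) as.numeric(a$area), 1)
  expect_equal(as.numeric(py_areas), r_areas)
})

test_that("8:2 split reproduces the published per-source partition", {
  sp <- split_dataset(seq_len(10), 0.8, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  # 218 images -> 174 train / 44 test
  sp2 <- split_dataset(sprintf("img%03d", 1:218), 0.8, seed = 7)
  expect_length(sp2$train, 174)
  expect_length(sp2$test, 44)
  # per-source independence
  sp3 <- split_dataset(list(A = 1:218, B = 1:464), 0.8, seed = 3)
  expect_length(sp3$train$A, 174)
  expect_length(sp3$test$A, 44)
})

test_that("splits are reproducible, disjoint and exhaustive", {
  for (seed in 1:5) {
    n <- sample(5:200, 1)
    v <- sample(letters, n, replace = TRUE)
    v <- paste0(v, seq_len(n))  # unique ids
    s1 <- split_dataset(v, 0.8, seed = seed)
    s2 <- split_dataset(v, 0.8, seed = seed)
    expect_identical(s1, s2)
    expect_length(intersect(s1$train, s1$test), 0)
    expect_setequal(c(s1$train, s1$test), v)
  }
})
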