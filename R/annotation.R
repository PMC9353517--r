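# LabelMe-style polygon annotations: reading, group-id merging of
# occlusion-split clusters, COCO conversion, dataset splitting.
#
# Group ids are file-local: they tie together the visible parts of one
# physical cluster within a single image and are never merged across images.

#' Read a LabelMe-style polygon annotation file
#'
#' @param path JSON file with `imagePath`, `imageHeight`, `imageWidth` and
#'   `shapes[{label, points, group_id}]`.
#' @return list with `shapes` (each `label`, `points` matrix, `group_id`
#'   integer or `NA`), `height`, `width`, `image_path`.
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("imagePath", "imageHeight", "imageWidth", "shapes")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("read_labelme: ", basename(path), " missing fields: ",
         paste(miss, collapse = ", "))
  shapes <- lapply(doc$shapes, function(s) {
    if (is.null(s$label) || is.null(s$points))
      stop("read_labelme: ", basename(path), ": shape missing label/points")
    pts <- as_poly_matrix(s$points)
    if (any(pts < 0)) stop("read_labelme: negative coordinates in ",
                           basename(path))
    gid <- s$group_id
    gid <- if (is.null(gid) || length(gid) == 0L || is.na(gid)) NA_integer_
           else as.integer(gid)
    list(label = as.character(s$label), points = pts, group_id = gid)
  })
  list(shapes = shapes,
       height = as.integer(doc$imageHeight),
       width = as.integer(doc$imageWidth),
       image_path = as.character(doc$imagePath))
}

#' Merge occlusion-split polygons into instances by group id
#'
#' Shapes sharing a non-empty `group_id` (and label) collapse into one
#' instance whose `parts` are all member polygons; shapes without a group id
#' each become a single-part instance. Output order is by first appearance.
#'
#' @param shapes list of shapes as returned by [read_labelme()].
#' @param height,width optional image size; when given, each record also
#'   carries its rasterized `mask` and pixel `area`.
#' @return list of instance records: `instance_id`, `category`, `parts`,
#'   `bbox` (x, y, w, h over all member vertices), and optionally `mask`,
#'   `area`.
#' @export
merge_group_instances <- function(shapes, height = NULL, width = NULL) {
  keys <- character(length(shapes))
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    keys[i] <- if (is.na(s$group_id)) paste0(".solo.", i)
               else paste0("g", s$group_id)
  }
  # same group id with different labels is an annotation error
  gids <- vapply(shapes, function(s) s$group_id, 1L)
  for (g in unique(gids[!is.na(gids)])) {
    labs <- unique(vapply(shapes[which(gids == g)], `[[`, "", "label"))
    if (length(labs) > 1L)
      stop("merge_group_instances: group id ", g,
           " used with conflicting labels: ", paste(labs, collapse = ", "))
  }
  order_keys <- unique(keys)
  out <- vector("list", length(order_keys))
  for (j in seq_along(order_keys)) {
    members <- shapes[keys == order_keys[j]]
    parts <- lapply(members, `[[`, "points")
    rec <- list(instance_id = j,
                category = members[[1L]]$label,
                parts = parts,
                bbox = polygon_to_bbox(parts),
                n_parts = length(parts))
    if (!is.null(height) && !is.null(width)) {
      rec$mask <- rasterize_polygons(parts, height, width)
      rec$area <- sum(rec$mask)
    }
    out[[j]] <- rec
  }
  out
}

#' Convert a directory of LabelMe annotations to one COCO JSON file
#'
#' One COCO annotation per merged instance; an occlusion-split cluster keeps
#' its multi-polygon segmentation. Areas are pixel counts of the rasterized
#' masks; boxes are the tight boxes over polygon vertices; `iscrowd` is
#' always 0; the single category is `grape`.
#'
#' @param input_dir directory of paired image + LabelMe JSON files.
#' @param out_json output path for the COCO JSON.
#' @return summary list (`n_images`, `n_annotations`, `out_json`), invisibly.
#' @export
labelme_to_coco <- function(input_dir, out_json) {
  files <- sort(list.files(input_dir, pattern = "\\.json$", full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  if (length(files) == 0L) stop("labelme_to_coco: no annotation JSON in ", input_dir)
  images <- list()
  annotations <- list()
  ann_id <- 0L
  for (i in seq_along(files)) {
    lm <- tryCatch(read_labelme(files[i]),
                   error = function(e) stop("labelme_to_coco: ", basename(files[i]),
                                            ": ", conditionMessage(e)))
    if (!file.exists(file.path(input_dir, lm$image_path)))
      stop("labelme_to_coco: image ", lm$image_path, " referenced by ",
           basename(files[i]), " not found")
    images[[i]] <- list(id = jsonlite::unbox(i),
                        file_name = jsonlite::unbox(lm$image_path),
                        height = jsonlite::unbox(lm$height),
                        width = jsonlite::unbox(lm$width))
    recs <- merge_group_instances(lm$shapes, lm$height, lm$width)
    for (r in recs) {
      ann_id <- ann_id + 1L
      seg <- lapply(r$parts, function(p) as.numeric(t(p)))
      annotations[[ann_id]] <- list(
        id = jsonlite::unbox(ann_id),
        image_id = jsonlite::unbox(i),
        category_id = jsonlite::unbox(1L),
        segmentation = seg,
        area = jsonlite::unbox(r$area),
        bbox = as.numeric(r$bbox),
        iscrowd = jsonlite::unbox(0L))
    }
  }
  doc <- list(
    info = list(description = jsonlite::unbox("vineseg grape cluster dataset")),
    images = images,
    annotations = annotations,
    categories = list(list(id = jsonlite::unbox(1L),
                           name = jsonlite::unbox("grape"),
                           supercategory = jsonlite::unbox("fruit"))))
  writeLines(jsonlite::toJSON(doc, digits = NA, null = "null"), out_json)
  invisible(list(n_images = length(images), n_annotations = ann_id,
                 out_json = out_json))
}

#' Read a COCO annotation or results JSON
#'
#' @param path COCO JSON file.
#' @return for ground truth: list with `images`, `annotations`, `categories`;
#'   a results file (a bare array) is returned as a list of detections.
#' @export
read_coco <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Split image lists 8:2 into train and test sets, per source
#'
#' The split is performed independently for each source dataset (e.g. the
#' near- and far-distance acquisitions), with a deterministic shuffle and a
#' round-half-up test count: 218 images yield 174 train / 44 test.
#'
#' @param records character/integer vector of image identifiers, or a named
#'   list of such vectors (one per source).
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed integer seed for the shuffle.
#' @return list with `train` and `test`; each mirrors the input structure.
#' @export
split_dataset <- function(records, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  single <- !is.list(records)
  if (single) records <- list(records)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  train <- list(); test <- list()
  for (k in seq_along(records)) {
    v <- records[[k]]
    n <- length(v)
    n_test <- floor(n * (1 - train_fraction) + 0.5)
    perm <- if (n > 0) sample.int(n) else integer(0)
    test_idx <- perm[seq_len(n_test)]
    train[[k]] <- v[sort(perm[setdiff(seq_len(n), seq_len(n_test))])]
    test[[k]] <- v[sort(test_idx)]
  }
  names(train) <- names(records); names(test) <- names(records)
  if (single) list(train = train[[1L]], test = test[[1L]])
  else list(train = train, test = test)
}
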