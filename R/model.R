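# Model assembly: configuration, parameter construction, checkpoints.

#' Model configuration
#'
#' @param preset `"full"` (published geometry) or `"test"` (CPU-sized model
#'   preserving the full ED topology: reduced widths and block counts,
#'   smaller proposal budgets).
#' @param scales,ratios anchor template sets; defaults are the published
#'   five base sizes and three aspect ratios.
#' @param ... named overrides merged into the config (e.g.
#'   `rpn = list(nms_threshold = 0.8)` or `mask = list(size = 56L)`;
#'   names must match config entries exactly).
#' @return nested configuration list.
#' @export
model_config <- function(preset = c("full", "test"),
                         scales = c(8, 16, 32, 64, 128),
                         ratios = c(0.5, 1, 2), ...) {
  preset <- match.arg(preset)
  tiny <- preset == "test"
  cfg <- list(
    preset = preset,
    backbone = backbone_config(preset),
    scales = scales, ratios = ratios,
    n_classes = 2L,  # background + grape
    rpn = list(
      pre_nms_train = if (tiny) 600L else 2000L,
      post_nms_train = if (tiny) 200L else 1000L,
      pre_nms_test = if (tiny) 300L else 1000L,
      post_nms_test = if (tiny) 100L else 300L,
      nms_threshold = 0.7,
      pos_iou = 0.7, neg_iou = 0.3,
      batch = if (tiny) 64L else 256L, pos_fraction = 0.5,
      smooth_l1_beta = 1 / 9,
      delta_weights = c(1, 1, 1, 1)),
    box = list(
      pool = 7L,
      fc_dim = if (tiny) 128L else 1024L,
      pos_iou = 0.5,
      batch = if (tiny) 32L else 64L, pos_fraction = 0.25,
      score_threshold = 0.05,
      nms_threshold = 0.5,
      max_detections = 100L,
      smooth_l1_beta = 1,
      delta_weights = c(10, 10, 5, 5)),
    mask = list(
      pool = 14L,
      size = 28L,
      n_convs = if (tiny) 2L else 4L,
      channels = if (tiny) 64L else 256L,
      max_train_rois = if (tiny) 8L else 16L))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("model_config: unknown config entries: ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  cfg
}

he_linear <- function(ci, co, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / ci)
  vs_param(matrix(rnorm(ci * co, 0, sd), ci, co))
}

#' Build a full model (backbone + RPN + box and mask heads)
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return model: nested list of parameter environments plus the config and
#'   the anchor template table.
#' @export
build_model <- function(config = model_config("test"), seed = 1L) {
  set.seed(seed)
  m <- list(config = config)
  m$backbone <- build_backbone_at_current_seed(config$backbone)
  fw <- config$backbone$fpn_width
  A <- length(config$ratios)
  m$rpn <- list(conv = he_conv(3, 3, fw, fw), conv_b = vs_param(numeric(fw)),
                obj = he_conv(1, 1, fw, A), obj_b = vs_param(numeric(A)),
                box = he_conv(1, 1, fw, 4L * A), box_b = vs_param(numeric(4L * A)))
  d <- config$box$pool^2 * fw
  fc <- config$box$fc_dim
  m$box_head <- list(
    fc1 = he_linear(d, fc), fc1_b = vs_param(numeric(fc)),
    fc2 = he_linear(fc, fc), fc2_b = vs_param(numeric(fc)),
    cls = he_linear(fc, config$n_classes, sd = 0.01),
    cls_b = vs_param(numeric(config$n_classes)),
    box = he_linear(fc, 4L * config$n_classes, sd = 0.001),
    box_b = vs_param(numeric(4L * config$n_classes)))
  mc <- config$mask$channels
  convs <- list()
  cin <- fw
  for (i in seq_len(config$mask$n_convs)) {
    convs[[i]] <- list(w = he_conv(3, 3, cin, mc), b = vs_param(numeric(mc)))
    cin <- mc
  }
  m$mask_head <- list(
    convs = convs,
    deconv = list(w = he_conv(1, 1, mc, 4L * mc), b = vs_param(numeric(4L * mc))),
    pred = list(w = he_conv(1, 1, mc, config$n_classes),
                b = vs_param(numeric(config$n_classes))))
  m$templates <- build_anchor_templates(config$scales, config$ratios)
  class(m) <- "vineseg_model"
  m
}

# build_backbone without re-seeding (build_model already seeded the stream)
build_backbone_at_current_seed <- function(config) {
  seed_now <- sample.int(.Machine$integer.max, 1L)
  bb <- build_backbone(config, seed = seed_now)
  bb
}

# flat list of every parameter environment in the model
collect_params <- function(x, prefix = "") {
  if (is.environment(x)) return(setNames(list(x), prefix))
  if (!is.list(x)) return(list())
  nms <- names(x)
  if (is.null(nms)) nms <- rep("", length(x))
  out <- list()
  for (i in seq_along(x)) {
    nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
    if (nm %in% c("config", "templates", "stride", "preset")) next
    out <- c(out, collect_params(x[[i]],
                                 if (prefix == "") nm else paste0(prefix, ".", nm)))
  }
  out
}

params_values <- function(model) lapply(collect_params(model), function(p) p$v)

#' Save a model checkpoint
#'
#' Stores the configuration, every weight tensor by name, and the RNG state
#' so training can resume deterministically.
#' @param model a model from [build_model()].
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  saveRDS(list(config = model$config, values = params_values(model),
               rng_state = rng), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @param restore_rng restore the stored RNG state (default FALSE).
#' @return the reconstructed model.
#' @export
load_checkpoint <- function(path, restore_rng = FALSE) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = 1L)
  ps <- collect_params(model)
  missing <- setdiff(names(ps), names(ck$values))
  if (length(missing)) stop("load_checkpoint: missing tensors: ",
                            paste(head(missing, 5), collapse = ", "))
  for (nm in names(ps)) ps[[nm]]$v <- ck$values[[nm]]
  if (restore_rng && !is.null(ck$rng_state))
    assign(".Random.seed", ck$rng_state, globalenv())
  model
}

#' Import weights by name intersection
#'
#' Copies every tensor whose name and shape match from a named list of
#' arrays (e.g. converted pretrained weights) and reports what was skipped.
#' Training from scratch is the tested path; this is a convenience hook.
#'
#' @param model target model.
#' @param values named list of arrays.
#' @return list with `loaded` and `skipped` tensor names.
#' @export
import_partial_weights <- function(model, values) {
  ps <- collect_params(model)
  loaded <- character(0); skipped <- character(0)
  for (nm in names(ps)) {
    v <- values[[nm]]
    if (!is.null(v) && identical(dim(v), dim(ps[[nm]]$v)) &&
        length(v) == length(ps[[nm]]$v)) {
      ps[[nm]]$v <- v
      loaded <- c(loaded, nm)
    } else skipped <- c(skipped, nm)
  }
  list(loaded = loaded, skipped = skipped)
}
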