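#' Pipeline configuration
#'
#' Collects everything a processing run needs: the two panel rectangles
#' inside the composite, the four-point calibration quads (or a cached
#' homography), the colour-bar parameters, and the thresholds. Normally
#' read from YAML via [load_config()].
#'
#' @param rgb_roi,thermal_roi Panel rectangles, `[x, y, w, h]` or [rect()].
#' @param src_quad,dst_quad 4x2 point matrices (RGB -> thermal); may be
#'   omitted when `homography` is given.
#' @param scalebar An [scale_bar()] or a named list of its fields.
#' @param homography Optional precomputed [homography()].
#' @param conf_threshold Detection confidence cut (default 0.5).
#' @param iou_threshold IoU threshold for evaluation (default 0.5).
#' @param mask_threshold Grayscale cutoff for mask refinement (default 128).
#' @param stride Frame stride (default 1).
#' @return An object of class `lt_config`.
#' @export
pipeline_config <- function(rgb_roi, thermal_roi, src_quad = NULL,
                            dst_quad = NULL, scalebar = NULL,
                            homography = NULL, conf_threshold = 0.5,
                            iou_threshold = 0.5, mask_threshold = 128L,
                            stride = 1L) {
  missing_keys <- character()
  if (missing(rgb_roi) || is.null(rgb_roi)) missing_keys <- c(missing_keys, "rgb_roi")
  if (missing(thermal_roi) || is.null(thermal_roi)) {
    missing_keys <- c(missing_keys, "thermal_roi")
  }
  if (is.null(homography) && (is.null(src_quad) || is.null(dst_quad))) {
    missing_keys <- c(missing_keys, "src_quad/dst_quad (or homography)")
  }
  if (is.null(scalebar)) missing_keys <- c(missing_keys, "scalebar")
  if (length(missing_keys) > 0L) {
    lt_config_error(paste("missing config keys:",
                          paste(missing_keys, collapse = ", ")))
  }
  if (!inherits(scalebar, "lt_scale_bar")) {
    scalebar <- do.call(scale_bar, scalebar[c("t_min", "t_max", "y_min",
                                              "y_max", "x_med", "bar_width")])
  }
  if (is.null(homography)) {
    homography <- fit_homography(quad_correspondence(
      quad_from_config(src_quad), quad_from_config(dst_quad)))
  }
  structure(list(rgb_roi = as_rect(unlist(rgb_roi)),
                 thermal_roi = as_rect(unlist(thermal_roi)),
                 homography = homography, scalebar = scalebar,
                 conf_threshold = conf_threshold,
                 iou_threshold = iou_threshold,
                 mask_threshold = as.integer(mask_threshold),
                 stride = as.integer(stride)),
            class = "lt_config")
}

quad_from_config <- function(q) {
  if (is.matrix(q)) return(q)
  do.call(rbind, lapply(q, function(p) as.numeric(unlist(p))))
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys: `rgb_roi`, `thermal_roi`, `src_quad`, `dst_quad`,
#' `scalebar` (mapping with `t_min`, `t_max`, `y_min`, `y_max`, `x_med`,
#' `bar_width`), `homography` (9 numbers, row-major), `conf_threshold`,
#' `iou_threshold`, `mask_threshold`, `stride`. Missing mandatory keys are
#' reported together in one config error.
#'
#' @param path YAML file path.
#' @return An `lt_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) lt_input_error(paste("no such config file:", path))
  y <- yaml::read_yaml(path)
  hom <- if (!is.null(y$homography)) {
    homography(matrix(as.numeric(unlist(y$homography)), 3L, 3L, byrow = TRUE))
  }
  if (is.null(y$scalebar$bar_width)) y$scalebar$bar_width <- 10L
  pipeline_config(
    rgb_roi = y$rgb_roi, thermal_roi = y$thermal_roi,
    src_quad = y$src_quad, dst_quad = y$dst_quad,
    scalebar = y$scalebar, homography = hom,
    conf_threshold = y$conf_threshold %||% 0.5,
    iou_threshold = y$iou_threshold %||% 0.5,
    mask_threshold = y$mask_threshold %||% 128L,
    stride = y$stride %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration matching a synthetic scene's ground truth
#'
#' @param scene An [make_scene()] scene.
#' @param ... Threshold overrides passed to [pipeline_config()].
#' @return An `lt_config` whose calibration equals the scene's ground truth.
#' @export
scene_config <- function(scene, ...) {
  pipeline_config(rgb_roi = scene$rgb_rect, thermal_roi = scene$thermal_rect,
                  src_quad = scene$src_quad, dst_quad = scene$dst_quad,
                  scalebar = scene$gt_scalebar, ...)
}
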