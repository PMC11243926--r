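#' The seven detection classes
#'
#' The detector contract recognises a whole-lizard class plus six body
#' parts: snout, head, dorsum, tail, left hind leg and left hind palm.
#'
#' @return Character vector of the seven legal class names, in label-index
#'   order (index 0 = "Lizard") as used in YOLO-format label files.
#' @export
lizard_classes <- function() {
  c("Lizard", "Snout", "Head", "Dorsum", "Tail", "Leg_L", "Palm_L")
}

check_class_labels <- function(labels) {
  bad <- setdiff(unique(labels), lizard_classes())
  if (length(bad) > 0L) {
    lt_value_error(paste("unknown class label(s):",
                         paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Build a detection table
#'
#' Detections are stored as a data frame with one row per bounding box:
#' columns `label`, `x`, `y`, `width`, `height` (RGB-panel pixel
#' coordinates, 0-based) and `confidence` in \[0, 1\].
#'
#' @param label Character vector of class names (see [lizard_classes()]).
#' @param x,y,width,height Box coordinates, vectorised.
#' @param confidence Scores in \[0, 1\].
#' @return A `data.frame` of class `lt_detections`.
#' @export
detections <- function(label = character(), x = integer(), y = integer(),
                       width = integer(), height = integer(),
                       confidence = numeric()) {
  check_class_labels(label)
  n <- length(label)
  if (any(lengths(list(x, y, width, height, confidence)) != n)) {
    lt_value_error("all detection columns must have the same length")
  }
  if (n > 0L) {
    if (any(confidence < 0 | confidence > 1)) {
      lt_value_error("confidence must lie in [0, 1]")
    }
    if (any(width <= 0L | height <= 0L)) {
      lt_value_error("detection boxes must have positive width and height")
    }
    if (any(x < 0L | y < 0L)) lt_value_error("detection boxes must have x, y >= 0")
  }
  structure(
    data.frame(label = as.character(label), x = as.integer(x),
               y = as.integer(y), width = as.integer(width),
               height = as.integer(height),
               confidence = as.numeric(confidence),
               stringsAsFactors = FALSE),
    class = c("lt_detections", "data.frame"))
}

det_box <- function(dets, i) {
  rect(dets$x[i], dets$y[i], dets$width[i], dets$height[i])
}

#' Discard low-confidence detections
#'
#' Keeps exactly the detections whose confidence is greater than or equal to
#' the threshold (ties at the threshold are kept), preserving input order.
#' The default threshold of 0.50 discards predictions the model scores below
#' 50%.
#'
#' @param dets An [detections()] table.
#' @param conf_threshold Minimum confidence in \[0, 1\] (default 0.5).
#' @return The filtered detection table.
#' @export
filter_detections <- function(dets, conf_threshold = 0.5) {
  if (!is.numeric(conf_threshold) || length(conf_threshold) != 1L ||
      is.na(conf_threshold) || conf_threshold < 0 || conf_threshold > 1) {
    lt_value_error("conf_threshold must be a single value in [0, 1]")
  }
  dets[dets$confidence >= conf_threshold, , drop = FALSE]
}

#' Run a detector backend on an RGB panel
#'
#' The detector is a contract: any function taking an image and returning an
#' [detections()] table. Detection is only ever run on the RGB panel — a
#' model trained on RGB imagery produces erroneous boxes on false-colour
#' thermal frames. Returned boxes are clamped to the frame; boxes left empty
#' by clamping are dropped.
#'
#' @param frame The RGB panel image.
#' @param detector A function `image -> lt_detections`.
#' @return A clamped detection table.
#' @export
detect <- function(frame, detector) {
  dets <- tryCatch(detector(frame), error = function(e) {
    backend <- attr(detector, "backend")
    lt_detector_error(sprintf("detector backend '%s' failed: %s",
                              if (is.null(backend)) "anonymous" else backend,
                              conditionMessage(e)))
  })
  if (!is.data.frame(dets)) lt_detector_error("detector must return a detection table")
  clamp_detections(dets, dim(frame)[2], dim(frame)[1])
}

# intersect boxes with the frame rectangle; drop boxes clamped to nothing
clamp_detections <- function(dets, frame_width, frame_height) {
  if (nrow(dets) == 0L) return(dets)
  x1 <- pmax(dets$x, 0L)
  y1 <- pmax(dets$y, 0L)
  x2 <- pmin(dets$x + dets$width, frame_width)
  y2 <- pmin(dets$y + dets$height, frame_height)
  keep <- x2 - x1 >= 1L & y2 - y1 >= 1L
  dets <- dets[keep, , drop = FALSE]
  dets$x <- as.integer(x1[keep]); dets$y <- as.integer(y1[keep])
  dets$width <- as.integer(x2[keep] - x1[keep])
  dets$height <- as.integer(y2[keep] - y1[keep])
  dets
}

#' Fixture detector replaying scripted boxes
#'
#' Stands in for a trained model so the downstream pipeline is testable:
#' returns the same scripted detection table for every frame (or per-frame
#' tables keyed by frame index when given a list).
#'
#' @param scripted An [detections()] table, or a list of tables indexed by
#'   frame number (1-based list position = frame 0, 1, ...).
#' @return A detector function for [detect()].
#' @export
fixture_detector <- function(scripted) {
  calls <- 0L
  f <- function(frame) {
    if (is.data.frame(scripted)) return(scripted)
    calls <<- calls + 1L
    if (calls > length(scripted)) {
      detections()
    } else {
      scripted[[calls]]
    }
  }
  attr(f, "backend") <- "fixture"
  f
}

#' Detector built from a synthetic scene's ground truth
#'
#' Returns the scene's ground-truth boxes, optionally perturbed by uniform
#' integer jitter on every coordinate, with a fixed confidence score. With
#' `jitter = 0` the detections equal the ground truth exactly.
#'
#' @param scene A scene from [make_scene()].
#' @param jitter Maximum absolute perturbation in pixels (default 0).
#' @param confidence Confidence assigned to every box (default 0.9).
#' @param seed RNG seed for the jitter.
#' @return A detector function for [detect()].
#' @export
gt_detector <- function(scene, jitter = 0L, confidence = 0.9, seed = 1L) {
  gt <- scene$gt_boxes
  f <- function(frame) {
    d <- detections(gt$label, gt$x, gt$y, gt$width, gt$height,
                    rep(confidence, nrow(gt)))
    if (jitter > 0L) {
      with_seed(seed, {
        n <- nrow(d)
        d$x <- pmax(0L, d$x + sample.int(2L * jitter + 1L, n, TRUE) - jitter - 1L)
        d$y <- pmax(0L, d$y + sample.int(2L * jitter + 1L, n, TRUE) - jitter - 1L)
        d$width <- pmax(1L, d$width + sample.int(2L * jitter + 1L, n, TRUE) - jitter - 1L)
        d$height <- pmax(1L, d$height + sample.int(2L * jitter + 1L, n, TRUE) - jitter - 1L)
      })
    }
    d
  }
  attr(f, "backend") <- "synthetic-ground-truth"
  f
}

#' Read YOLO-format label files
#'
#' Each line is `class_index cx cy w h [confidence]` with coordinates
#' normalised to the image dimensions. Boxes are converted to absolute
#' pixel rectangles by rounding half-up; widths/heights are clamped to at
#' least 1 pixel.
#'
#' @param path Label file path.
#' @param image_width,image_height Pixel dimensions of the labelled image.
#' @param class_names Mapping from class index (0-based) to name.
#' @return An [detections()] table (confidence 1 when absent in the file).
#' @export
read_yolo_labels <- function(path, image_width, image_height,
                             class_names = lizard_classes()) {
  if (!file.exists(path)) lt_input_error(paste("no such label file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(detections())
  fields <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  nf <- lengths(fields)
  if (any(nf < 5L | nf > 6L)) {
    lt_input_error(paste("malformed YOLO label line in", path))
  }
  m <- t(vapply(fields, function(f) c(f, NA)[1:6], numeric(6)))
  cls_idx <- as.integer(m[, 1])
  if (any(cls_idx < 0L | cls_idx >= length(class_names))) {
    lt_input_error("class index out of range in YOLO labels")
  }
  w <- pmax(1L, as.integer(round_half_up(m[, 4] * image_width)))
  h <- pmax(1L, as.integer(round_half_up(m[, 5] * image_height)))
  x <- as.integer(round_half_up((m[, 2] - m[, 4] / 2) * image_width))
  y <- as.integer(round_half_up((m[, 3] - m[, 5] / 2) * image_height))
  conf <- ifelse(is.na(m[, 6]), 1, m[, 6])
  detections(class_names[cls_idx + 1L], pmax(0L, x), pmax(0L, y), w, h, conf)
}

#' Write a detection table as a YOLO-format label file
#'
#' @param dets An [detections()] table.
#' @param path Output path.
#' @param image_width,image_height Pixel dimensions used for normalisation.
#' @param with_confidence Append the confidence as a sixth field.
#' @param class_names Class index mapping (0-based).
#' @export
write_yolo_labels <- function(dets, path, image_width, image_height,
                              with_confidence = FALSE,
                              class_names = lizard_classes()) {
  idx <- match(dets$label, class_names) - 1L
  cx <- (dets$x + dets$width / 2) / image_width
  cy <- (dets$y + dets$height / 2) / image_height
  w <- dets$width / image_width
  h <- dets$height / image_height
  lines <- if (with_confidence) {
    sprintf("%d %.6f %.6f %.6f %.6f %.4f", idx, cx, cy, w, h, dets$confidence)
  } else {
    sprintf("%d %.6f %.6f %.6f %.6f", idx, cx, cy, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}
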