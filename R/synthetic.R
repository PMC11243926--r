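# Synthetic paired scenes: a dark elliptical "lizard" (body plus six parts)
# on a light background in the RGB panel, and a known temperature field
# rendered through a known injective colourmap in the thermal panel, with a
# colour bar and a known homography between panels. Every downstream stage
# can be validated against the stored ground truth.

#' Injective colour ramp for rendering temperature fields
#'
#' Samples `n_steps` colours at equal arc length along a fixed polyline
#' through RGB space running dark blue -> magenta -> orange -> yellow ->
#' near-white (the familiar "ironbow" look of thermal cameras). Consecutive
#' colours are guaranteed at least 4 apart in Euclidean RGB distance and all
#' colours are pairwise distinct, so nearest-colour lookup inverts the ramp
#' unambiguously.
#'
#' @param n_steps Number of colours (>= 2).
#' @return An `n_steps x 3` integer matrix of RGB triples (0..255).
#' @export
make_colourmap <- function(n_steps) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2L) {
    lt_value_error("n_steps must be an integer >= 2")
  }
  n_steps <- as.integer(n_steps)
  verts <- rbind(c(10, 10, 80), c(60, 20, 200), c(200, 40, 220),
                 c(255, 120, 60), c(255, 220, 40), c(255, 255, 230))
  seg <- sqrt(rowSums(diff(verts)^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[length(cum)], length.out = n_steps)
  cmap <- t(vapply(s, function(si) {
    j <- max(which(cum <= si + 1e-12))
    if (j >= length(cum)) return(verts[nrow(verts), ])
    f <- (si - cum[j]) / seg[j]
    verts[j, ] * (1 - f) + verts[j + 1, ] * f
  }, numeric(3)))
  cmap <- round_half_up(cmap)
  storage.mode(cmap) <- "integer"
  dmin <- min(sqrt(rowSums(diff(cmap)^2)))
  if (dmin < 4 || anyDuplicated(cmap) > 0L) {
    lt_value_error(paste0(
      "n_steps = ", n_steps, " is too fine for the guaranteed 4-unit ",
      "separation between consecutive colours"))
  }
  cmap
}

# filled ellipse mask on a 0-based pixel grid
ellipse_mask <- function(xx, yy, cx, cy, rx, ry) {
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}

mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  rect(min(cols) - 1L, min(rows) - 1L,
       max(cols) - min(cols) + 1L, max(rows) - min(rows) + 1L)
}

#' Generate a paired RGB/thermal composite scene with ground truth
#'
#' Builds one side-by-side composite: the left panel shows a dark lizard
#' silhouette (body ellipse plus snout, head, dorsum, tail, left leg and
#' left palm) on a light background; the right panel renders a known
#' temperature field (ambient everywhere, `lizard_temp` on the mapped
#' lizard footprint) through [make_colourmap()], with a vertical colour bar
#' on its right edge. The panels are related by a known rectangle-to-
#' rectangle homography. Layout is mildly jittered by the seed; the same
#' seed is bit-reproducible.
#'
#' With `curl_tail = TRUE` the tail is drawn as an open ring whose bounding
#' box centre falls on background, exercising the nearest-white-pixel
#' fallback of the representative-pixel selection.
#'
#' @param t_min,t_max Colour-scale endpoint temperatures in degrees Celsius
#'   (defaults 29.3 and 50.5, a typical heat-lamp enclosure frame).
#' @param lizard_temp,ambient_temp Scene temperatures in degrees C, both
#'   within `[t_min, t_max]` (defaults 33 and 30.5).
#' @param panel_size `c(width, height)` of each panel in pixels
#'   (default `c(160, 120)`).
#' @param seed Integer seed controlling layout jitter.
#' @param curl_tail Draw the curled-tail configuration (default FALSE).
#' @return An object of class `lt_scene`; see Details for fields.
#' @details Fields: `composite`, `rgb_rect`, `thermal_rect`, `rgb_panel`,
#'   `thermal_panel`, `gt_boxes` (label + box per part), `gt_homography`,
#'   `src_quad`, `dst_quad`, `gt_scalebar`, `gt_temperature` (degrees C per
#'   thermal-panel pixel, full precision), `colourmap`, `seed`, `params`.
#' @export
make_scene <- function(t_min = 29.3, t_max = 50.5, lizard_temp = 33,
                       ambient_temp = 30.5, panel_size = c(160L, 120L),
                       seed = 1L, curl_tail = FALSE) {
  if (t_max <= t_min) lt_value_error("t_max must exceed t_min")
  if (ambient_temp < t_min || ambient_temp > t_max ||
      lizard_temp < t_min || lizard_temp > t_max) {
    lt_value_error("scene temperatures must lie within [t_min, t_max]")
  }
  w <- as.integer(panel_size[1]); h <- as.integer(panel_size[2])
  if (w < 120L || h < 90L) {
    lt_value_error("panel_size must be at least 120 x 90 pixels")
  }

  with_seed(seed, {
    cx <- w * 0.5 + stats::runif(1, -3, 3)
    cy <- h * 0.5 + stats::runif(1, -3, 3)
    sc <- stats::runif(1, 0.95, 1.05)

    xx <- matrix(rep(0:(w - 1L), each = h), nrow = h)
    yy <- matrix(rep(0:(h - 1L), times = w), nrow = h)

    dorsum <- ellipse_mask(xx, yy, cx, cy, 0.19 * w * sc, 0.12 * h * sc)
    head <- ellipse_mask(xx, yy, cx - 0.24 * w, cy, 0.075 * w * sc, 0.075 * h * sc)
    snout <- ellipse_mask(xx, yy, cx - 0.31 * w, cy, 0.032 * w, 0.033 * h)
    leg <- ellipse_mask(xx, yy, cx + 0.09 * w, cy + 0.17 * h, 0.04 * w, 0.075 * h)
    palm <- ellipse_mask(xx, yy, cx + 0.09 * w, cy + 0.27 * h, 0.03 * w, 0.033 * h)
    tail <- if (curl_tail) {
      tcx <- cx + 0.30 * w; tcy <- cy - 0.04 * h
      r <- 0.09 * w
      dist <- sqrt((xx - tcx)^2 + (yy - tcy)^2)
      ang <- atan2(yy - tcy, xx - tcx) * 180 / pi   # -180..180, 0 = +x
      abs(dist - r) <= 2.5 & abs(ang) >= 50
    } else {
      ellipse_mask(xx, yy, cx + 0.31 * w, cy, 0.14 * w * sc, 0.042 * h)
    }

    parts <- list(Snout = snout, Head = head, Dorsum = dorsum,
                  Tail = tail, Leg_L = leg, Palm_L = palm)
    union <- Reduce(`|`, parts)

    # RGB panel: light background, dark parts with slight per-part shading
    shades <- c(Snout = 55L, Head = 62L, Dorsum = 60L, Tail = 65L,
                Leg_L = 58L, Palm_L = 52L)
    rgb_gray <- matrix(225L, h, w)
    for (nm in names(parts)) rgb_gray[parts[[nm]]] <- shades[[nm]]
    rgb_panel <- array(rep(rgb_gray, 3L), dim = c(h, w, 3L))
    storage.mode(rgb_panel) <- "integer"

    boxes <- c(list(Lizard = mask_bbox(union)),
               lapply(parts, mask_bbox))
    gt_boxes <- data.frame(
      label = names(boxes),
      x = vapply(boxes, `[[`, integer(1), "x"),
      y = vapply(boxes, `[[`, integer(1), "y"),
      width = vapply(boxes, `[[`, integer(1), "width"),
      height = vapply(boxes, `[[`, integer(1), "height"),
      stringsAsFactors = FALSE, row.names = NULL)

    # panels related by a rectangle-to-rectangle perspective map; the
    # thermal content sits left of the colour bar
    src_quad <- rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1), c(0, h - 1))
    dst_quad <- rbind(c(6, 6), c(6 + 0.7 * (w - 1), 6),
                      c(6 + 0.7 * (w - 1), 6 + 0.7 * (h - 1)),
                      c(6, 6 + 0.7 * (h - 1)))
    gt_h <- fit_homography(quad_correspondence(src_quad, dst_quad))
    h_inv <- invert_homography(gt_h)

    # bar length capped at 140 rows: the colourmap guarantees its 4-unit
    # separation only up to that resolution
    n_rows <- min(h - 21L, 140L)
    bar <- scale_bar(t_min, t_max, y_min = 10L, y_max = 10L + n_rows - 1L,
                     x_med = w - 14L, bar_width = 10L)
    cmap <- make_colourmap(n_rows)

    # temperature field on the thermal panel via the inverse map
    txx <- matrix(rep(0:(w - 1L), each = h), nrow = h)
    tyy <- matrix(rep(0:(h - 1L), times = w), nrow = h)
    src_pts <- h_inv$m %*% rbind(as.vector(txx), as.vector(tyy), 1)
    sx <- round_half_up(src_pts[1, ] / src_pts[3, ])
    sy <- round_half_up(src_pts[2, ] / src_pts[3, ])
    inside <- sx >= 0 & sx < w & sy >= 0 & sy < h
    on_lizard <- logical(length(sx))
    on_lizard[inside] <- union[cbind(sy[inside] + 1L, sx[inside] + 1L)]
    temp_field <- matrix(ambient_temp, h, w)
    temp_field[matrix(on_lizard, h, w)] <- lizard_temp

    # colour bar overlay; its rows carry their own interpolated temperature
    bar_cols <- bar_columns(bar)
    bar_rows <- bar$y_min:bar$y_max
    temp_field[bar_rows + 1L, bar_cols + 1L] <-
      row_to_temperature(bar, bar_rows)

    # render: temperature -> bar row -> colourmap entry
    rowf <- bar$y_max - (temp_field - t_min) / (t_max - t_min) *
      (bar$y_max - bar$y_min)
    ri <- pmin(pmax(round_half_up(rowf), bar$y_min), bar$y_max)
    idx <- as.vector(ri) - bar$y_min + 1L
    thermal_panel <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) thermal_panel[, , ch] <- matrix(cmap[idx, ch], h, w)

    composite <- array(0L, dim = c(h, 2L * w, 3L))
    composite[, 1:w, ] <- rgb_panel
    composite[, (w + 1L):(2L * w), ] <- thermal_panel

    structure(list(
      composite = composite,
      rgb_rect = rect(0, 0, w, h),
      thermal_rect = rect(w, 0, w, h),
      rgb_panel = rgb_panel,
      thermal_panel = thermal_panel,
      gt_boxes = gt_boxes,
      gt_homography = gt_h,
      src_quad = src_quad,
      dst_quad = dst_quad,
      gt_scalebar = bar,
      gt_temperature = temp_field,
      colourmap = cmap,
      seed = as.integer(seed),
      params = list(t_min = t_min, t_max = t_max,
                    lizard_temp = lizard_temp, ambient_temp = ambient_temp,
                    panel_size = c(w, h), curl_tail = curl_tail)
    ), class = "lt_scene")
  })
}

#' Write a synthetic scene to disk
#'
#' Emits the composite as PNG, the ground-truth boxes as a YOLO-format
#' label file, and a YAML sidecar with the homography, scale bar, quads and
#' scene temperatures.
#'
#' @param scene An [make_scene()] scene.
#' @param dir Output directory (created if needed).
#' @param stem Base file name (default "scene").
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(scene$composite, file.path(dir, paste0(stem, ".png")))
  gt <- scene$gt_boxes
  dets <- detections(gt$label, gt$x, gt$y, gt$width, gt$height,
                     rep(1, nrow(gt)))
  write_yolo_labels(dets, file.path(dir, paste0(stem, ".txt")),
                    scene$rgb_rect$width, scene$rgb_rect$height)
  side <- list(
    seed = scene$seed,
    panel_size = scene$params$panel_size,
    curl_tail = scene$params$curl_tail,
    temperatures = list(t_min = scene$params$t_min,
                        t_max = scene$params$t_max,
                        lizard = scene$params$lizard_temp,
                        ambient = scene$params$ambient_temp),
    rgb_roi = unlist(scene$rgb_rect, use.names = FALSE),
    thermal_roi = unlist(scene$thermal_rect, use.names = FALSE),
    src_quad = apply(scene$src_quad, 1, as.list),
    dst_quad = apply(scene$dst_quad, 1, as.list),
    homography = as.vector(t(scene$gt_homography$m)),
    scalebar = unclass(scene$gt_scalebar))
  yaml::write_yaml(side, file.path(dir, paste0(stem, ".yaml")))
  invisible(dir)
}
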