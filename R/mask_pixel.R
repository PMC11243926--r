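# Bounding boxes generally contain both the detected body part and
# background. The refinement here separates the two inside each box so a
# single representative pixel guaranteed to lie on the animal can be picked.

# 8-bit luma (0.299 R + 0.587 G + 0.114 B), rounded half-up
gray_luma <- function(image) {
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  m <- round_half_up(g)
  storage.mode(m) <- "integer"
  m
}

#' Refine a bounding box to a binary foreground mask
#'
#' Five sequential steps applied to one detection: (1) a black mask the size
#' of the panel; (2) the box region set to white; (3) the panel masked to the
#' box (bitwise AND); (4) grayscale conversion; (5) inverse-binary
#' thresholding, so dark pixels (the lizard) become white/foreground and
#' light background pixels become black. The threshold is a user choice that
#' depends on the footage.
#'
#' @param roi The RGB panel image.
#' @param box An [rect()] inside the panel.
#' @param gray_threshold Grayscale cutoff 0..255 (default 128): luma <=
#'   threshold -> 255 (foreground), luma > threshold -> 0.
#' @return An integer `h x w` matrix over the whole panel with values in
#'   \{0, 255\}; all pixels outside `box` are 0.
#' @export
refine_box_mask <- function(roi, box, gray_threshold = 128L) {
  box <- as_rect(box)
  check_rect_inside(box, roi, "box")
  if (!is.numeric(gray_threshold) || length(gray_threshold) != 1L ||
      gray_threshold < 0 || gray_threshold > 255) {
    lt_value_error("gray_threshold must be a single value in 0..255")
  }
  mask <- matrix(0L, nrow = dim(roi)[1], ncol = dim(roi)[2])
  rows <- (box$y + 1L):(box$y + box$height)
  cols <- (box$x + 1L):(box$x + box$width)
  sub <- roi[rows, cols, , drop = FALSE]
  g <- gray_luma(sub)
  mask[rows, cols] <- ifelse(g <= gray_threshold, 255L, 0L)
  mask
}

#' Nearest white pixel to a starting point
#'
#' Scans the white (255) pixels of `mask` restricted to `box` and returns
#' the one minimising Euclidean distance to `start`. Ties are broken by
#' row-major scan order: smallest `y`, then smallest `x`, making the result
#' deterministic.
#'
#' @param mask A \{0, 255\} matrix (panel extent).
#' @param start An [pixel_coord()].
#' @param box Search region; defaults to the full mask extent.
#' @return The chosen [pixel_coord()].
#' @export
nearest_white_pixel <- function(mask, start,
                                box = rect(0, 0, ncol(mask), nrow(mask))) {
  box <- as_rect(box)
  check_rect_inside(box, mask, "box")
  sub <- mask[(box$y + 1L):(box$y + box$height),
              (box$x + 1L):(box$x + box$width), drop = FALSE]
  # t() gives row-major enumeration: y ascending, then x — the tie-break order
  idx0 <- which(t(sub) == 255L) - 1L
  if (length(idx0) == 0L) {
    lt_no_foreground_error("no white pixel inside the box")
  }
  xs <- idx0 %% box$width + box$x
  ys <- idx0 %/% box$width + box$y
  d2 <- (xs - start$x)^2 + (ys - start$y)^2
  i <- which.min(d2)   # first minimum in row-major order
  pixel_coord(xs[i], ys[i])
}

#' Representative pixel of a bounding box
#'
#' The pixel whose temperature stands for the whole detection. The box
#' centre `(x + width %/% 2, y + height %/% 2)` is used when it is
#' foreground (white in the refined mask); otherwise the nearest white pixel
#' to the centre, searched within the box only. The returned pixel is always
#' white.
#'
#' @param mask A refined mask from [refine_box_mask()].
#' @param box The detection's [rect()].
#' @return An [pixel_coord()]; raises a no-foreground error when the box
#'   contains no white pixel (the measurement is then skipped and logged).
#' @export
representative_pixel <- function(mask, box) {
  box <- as_rect(box)
  check_rect_inside(box, mask, "box")
  cx <- box$x + box$width %/% 2L
  cy <- box$y + box$height %/% 2L
  if (mask[cy + 1L, cx + 1L] == 255L) {
    return(pixel_coord(cx, cy))
  }
  nearest_white_pixel(mask, pixel_coord(cx, cy), box)
}

#' Dump a mask as a PNG for visual debugging
#'
#' @param mask A \{0, 255\} matrix.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}
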