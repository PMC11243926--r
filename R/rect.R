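#' Axis-aligned pixel rectangle
#'
#' Rectangles define both panel regions of interest and detector bounding
#' boxes. Coordinates are 0-based with `x` the column of the top-left corner,
#' `y` the row (y increases downward), and the covered pixel set is the
#' half-open block `[y, y + height) x [x, x + width)`.
#'
#' @param x,y Integer pixel coordinates of the top-left corner (0-based,
#'   both >= 0).
#' @param width,height Extent in pixels; both must be > 0.
#' @return An object of class `lt_rect` (a named list).
#' @examples
#' rect(0, 0, 10, 10)
#' @export
rect <- function(x, y, width, height) {
  for (v in list(x = x, y = y, width = width, height = height)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != as.integer(v)) {
      lt_value_error("rect fields must be single integer values")
    }
  }
  x <- as.integer(x); y <- as.integer(y)
  width <- as.integer(width); height <- as.integer(height)
  if (width <= 0L) lt_value_error("rect width must be > 0")
  if (height <= 0L) lt_value_error("rect height must be > 0")
  if (x < 0L) lt_value_error("rect x must be >= 0")
  if (y < 0L) lt_value_error("rect y must be >= 0")
  structure(list(x = x, y = y, width = width, height = height),
            class = "lt_rect")
}

#' @export
print.lt_rect <- function(x, ...) {
  cat(sprintf("<rect x=%d y=%d w=%d h=%d>\n", x$x, x$y, x$width, x$height))
  invisible(x)
}

as_rect <- function(v) {
  if (inherits(v, "lt_rect")) return(v)
  if (is.numeric(v) && length(v) == 4L) return(rect(v[1], v[2], v[3], v[4]))
  lt_value_error("cannot interpret value as a rect; expected [x, y, w, h]")
}

rect_area <- function(r) as.numeric(r$width) * as.numeric(r$height)

# check rect against an image (h x w x 3 array) or mask (h x w matrix);
# names the offending edge in the error.
check_rect_inside <- function(r, image, what = "rect") {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (r$x + r$width > w) {
    lt_bounds_error(sprintf(
      "%s right edge %d exceeds image width %d", what, r$x + r$width, w))
  }
  if (r$y + r$height > h) {
    lt_bounds_error(sprintf(
      "%s bottom edge %d exceeds image height %d", what, r$y + r$height, h))
  }
  invisible(TRUE)
}

#' Pixel coordinate
#'
#' A single 0-based pixel position, `x` = column, `y` = row.
#'
#' @param x,y Integer column and row (0-based).
#' @return An object of class `lt_pixel`.
#' @export
pixel_coord <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      is.na(x) || is.na(y)) {
    lt_value_error("pixel coordinates must be single numbers")
  }
  structure(list(x = as.integer(x), y = as.integer(y)), class = "lt_pixel")
}

#' @export
print.lt_pixel <- function(x, ...) {
  cat(sprintf("<pixel x=%d y=%d>\n", x$x, x$y))
  invisible(x)
}
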