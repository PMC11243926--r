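# The thermal panel is a false-colour render, not radiometric data; the
# only quantitative handle on temperature is the vertical colour scale bar
# embedded in the frame, whose ends are annotated with the frame's minimum
# and maximum temperatures. Temperatures are recovered by matching a
# pixel's colour against the bar and linearly interpolating between the
# annotated endpoints.

#' Colour scale bar calibration
#'
#' Describes the vertical colour bar of a thermal frame: its temperature
#' endpoints and pixel footprint. The bar top (`y_min`) is the hot end
#' (`t_max`), the bottom (`y_max`) the cold end (`t_min`). All pixel values
#' are 0-based thermal-panel coordinates.
#'
#' @param t_min,t_max Temperatures in degrees Celsius at the bottom and top
#'   of the bar; `t_max > t_min`.
#' @param y_min,y_max Rows of the bar top and bottom; `y_max > y_min`.
#' @param x_med Column of the bar centre.
#' @param bar_width Width of the bar in pixels (default 10).
#' @return An object of class `lt_scale_bar`.
#' @export
scale_bar <- function(t_min, t_max, y_min, y_max, x_med, bar_width = 10L) {
  if (!is.numeric(t_min) || !is.numeric(t_max) || t_max <= t_min) {
    lt_value_error("scale bar requires t_max > t_min")
  }
  if (y_max <= y_min) lt_value_error("scale bar requires y_max > y_min")
  if (bar_width < 1L) lt_value_error("bar_width must be >= 1")
  structure(list(t_min = t_min, t_max = t_max,
                 y_min = as.integer(y_min), y_max = as.integer(y_max),
                 x_med = as.integer(x_med), bar_width = as.integer(bar_width)),
            class = "lt_scale_bar")
}

#' Temperature at a scale-bar row
#'
#' Linear interpolation between the bar's endpoints:
#' `T = t_min + (y_max - final) / (y_max - y_min) * (t_max - t_min)`,
#' where `final` is the row index. Exact real arithmetic; logs report the
#' value to 0.1 degrees C. Strictly decreasing in `final` (hotter is higher
#' on the bar).
#'
#' @param bar An [scale_bar()].
#' @param final Row index (vectorised) in `[y_min, y_max]`.
#' @return Temperature(s) in degrees Celsius.
#' @export
row_to_temperature <- function(bar, final) {
  if (any(final < bar$y_min | final > bar$y_max)) {
    lt_range_error(sprintf("row index outside the bar range [%d, %d]",
                           bar$y_min, bar$y_max))
  }
  bar$t_min + (bar$y_max - final) / (bar$y_max - bar$y_min) *
    (bar$t_max - bar$t_min)
}

# bar footprint columns, 0-based: bar_width columns centred on x_med
bar_columns <- function(bar) {
  x0 <- bar$x_med - bar$bar_width %/% 2L
  x0:(x0 + bar$bar_width - 1L)
}

#' Sample the colour bar from a thermal panel
#'
#' Reads one colour per bar row, averaging across the bar's width (the mean
#' suppresses compression artefacts from screen-recorded video) and rounding
#' each channel half-up to 8 bits.
#'
#' @param thermal The thermal panel image.
#' @param bar An [scale_bar()] whose footprint lies inside the panel.
#' @return An object of class `lt_bar_sample`: `rows` (integer vector
#'   `y_min..y_max`) and `colours` (n x 3 integer matrix).
#' @export
sample_bar <- function(thermal, bar) {
  cols <- bar_columns(bar)
  d <- dim(thermal)
  if (cols[1] < 0L || cols[length(cols)] >= d[2]) {
    lt_bounds_error("scale bar columns fall outside the thermal panel")
  }
  if (bar$y_min < 0L || bar$y_max >= d[1]) {
    lt_bounds_error("scale bar rows fall outside the thermal panel")
  }
  rows <- bar$y_min:bar$y_max
  strip <- thermal[rows + 1L, cols + 1L, , drop = FALSE]
  colours <- apply(strip, c(1, 3), mean)
  colours <- round_half_up(colours)
  storage.mode(colours) <- "integer"
  structure(list(rows = rows, colours = colours), class = "lt_bar_sample")
}

#' Temperature of a thermal-panel pixel via the colour bar
#'
#' Matches the pixel's RGB colour against the sampled bar by Euclidean
#' distance and returns the matched row's interpolated temperature. Ties are
#' broken toward the smaller row index (the hotter row). The result always
#' lies in `[t_min, t_max]`.
#'
#' @param thermal The thermal panel image.
#' @param bar An [scale_bar()].
#' @param p An [pixel_coord()] inside the panel.
#' @return Temperature in degrees Celsius.
#' @export
colour_to_temperature <- function(thermal, bar, p) {
  d <- dim(thermal)
  if (p$x < 0L || p$y < 0L || p$x >= d[2] || p$y >= d[1]) {
    lt_bounds_error(sprintf("pixel (%d, %d) outside the %dx%d thermal panel",
                            p$x, p$y, d[2], d[1]))
  }
  s <- sample_bar(thermal, bar)
  colour <- as.numeric(thermal[p$y + 1L, p$x + 1L, ])
  d2 <- (s$colours[, 1] - colour[1])^2 +
        (s$colours[, 2] - colour[2])^2 +
        (s$colours[, 3] - colour[3])^2
  i <- which.min(d2)   # rows ascend from the hot end, so first min = hotter
  row_to_temperature(bar, s$rows[i])
}
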