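# The RGB and thermal cameras view the same planar scene from slightly
# different positions; a 3x3 perspective transform fitted from four point
# correspondences maps RGB-panel pixels to thermal-panel pixels.

#' Four-point correspondence between the RGB and thermal panels
#'
#' Points follow the fixed corner order top-left, top-right, bottom-right,
#' bottom-left, i.e. `[x_min, y_min], [x_max, y_min], [x_max, y_max],
#' [x_min, y_max]` for an axis-aligned calibration rectangle. General
#' (non-rectangular) quads are accepted as long as no three points are
#' collinear.
#'
#' @param src 4x2 numeric matrix of RGB-panel points (x, y per row).
#' @param dst 4x2 numeric matrix of the corresponding thermal-panel points.
#' @return An object of class `lt_quad_correspondence`.
#' @export
quad_correspondence <- function(src, dst) {
  src <- as_quad(src, "src")
  dst <- as_quad(dst, "dst")
  check_no_collinear(src, "src")
  check_no_collinear(dst, "dst")
  structure(list(src = src, dst = dst), class = "lt_quad_correspondence")
}

as_quad <- function(q, what) {
  q <- as.matrix(q)
  if (!is.numeric(q) || !identical(dim(q), c(4L, 2L))) {
    lt_value_error(paste(what, "quad must be a 4x2 numeric matrix"))
  }
  unname(q)
}

check_no_collinear <- function(q, what) {
  combs <- utils::combn(4L, 3L)
  for (j in seq_len(ncol(combs))) {
    p <- q[combs[, j], , drop = FALSE]
    cross <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])
    if (abs(cross) < 1e-9) {
      lt_singularity_error(paste("three", what, "quad points are collinear"))
    }
  }
  invisible(TRUE)
}

#' A 3x3 planar homography
#'
#' @param m 3x3 numeric matrix; it is normalised so `m[3, 3] == 1` and must
#'   be invertible.
#' @return An object of class `lt_homography`.
#' @export
homography <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L))) {
    lt_value_error("homography must be a 3x3 numeric matrix")
  }
  if (abs(m[3, 3]) < 1e-12) {
    lt_singularity_error("homography has m[3,3] ~ 0; cannot normalise")
  }
  m <- m / m[3, 3]
  if (abs(det(m)) <= 1e-12) {
    lt_singularity_error("homography matrix is singular")
  }
  structure(list(m = unname(m)), class = "lt_homography")
}

#' @export
print.lt_homography <- function(x, ...) {
  cat("<homography>\n")
  print(x$m)
  invisible(x)
}

#' Fit the perspective transform from four point pairs
#'
#' Solves the standard 8-unknown linear system for the projective matrix
#' taking each `src` point to its `dst` point; with the ninth entry fixed at
#' 1, four correspondences determine the transform exactly. Each of the four
#' corners reproduces its destination to within 1e-6 after homogeneous
#' normalisation.
#'
#' @param corr An [quad_correspondence()] (or a list with `src` and `dst`
#'   4x2 matrices).
#' @return An [homography()].
#' @export
fit_homography <- function(corr) {
  if (!inherits(corr, "lt_quad_correspondence")) {
    corr <- quad_correspondence(corr$src, corr$dst)
  }
  s <- corr$src; d <- corr$dst
  A <- matrix(0, 8L, 8L)
  b <- numeric(8L)
  for (i in 1:4) {
    x <- s[i, 1]; y <- s[i, 2]; X <- d[i, 1]; Y <- d[i, 2]
    A[2L * i - 1L, ] <- c(x, y, 1, 0, 0, 0, -x * X, -y * X)
    A[2L * i, ]      <- c(0, 0, 0, x, y, 1, -x * Y, -y * Y)
    b[2L * i - 1L] <- X
    b[2L * i]      <- Y
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    lt_singularity_error(paste("degenerate correspondence:",
                               conditionMessage(e)))
  })
  homography(matrix(c(h, 1), 3L, 3L, byrow = TRUE))
}

#' Invert a homography
#'
#' @param h An [homography()].
#' @return The inverse transform as an [homography()].
#' @export
invert_homography <- function(h) {
  homography(solve(h$m))
}

#' Map a pixel through a homography
#'
#' Computes `(x', y', w) = m %*% (x, y, 1)`, normalises by `w`, and rounds
#' each coordinate with `floor(v + 0.5)`. A zero homogeneous coordinate
#' raises a mapping error. Negative normalised coordinates, or (when
#' `panel` is supplied) rounded coordinates outside the panel, raise an
#' out-of-panel error carrying the raw coordinates — such measurements are
#' skipped rather than clamped, because clamping would silently read a wrong
#' temperature.
#'
#' @param h An [homography()].
#' @param p An [pixel_coord()] in source-panel coordinates.
#' @param panel Optional destination image (or its `dim()`) used for the
#'   bounds check.
#' @return The mapped [pixel_coord()] in destination-panel coordinates.
#' @export
map_point <- function(h, p, panel = NULL) {
  v <- h$m %*% c(p$x, p$y, 1)
  if (abs(v[3]) < 1e-12) {
    lt_mapping_error(sprintf("pixel (%d, %d) maps to the line at infinity",
                             p$x, p$y))
  }
  xn <- v[1] / v[3]
  yn <- v[2] / v[3]
  if (xn < 0 || yn < 0) {
    lt_out_of_panel_error(
      sprintf("mapped point (%.3f, %.3f) has a negative coordinate", xn, yn),
      raw = c(x = xn, y = yn))
  }
  xi <- as.integer(round_half_up(xn))
  yi <- as.integer(round_half_up(yn))
  if (!is.null(panel)) {
    d <- if (is.numeric(panel) && length(panel) <= 3L) panel else dim(panel)
    if (xi >= d[2] || yi >= d[1]) {
      lt_out_of_panel_error(
        sprintf("mapped point (%.3f, %.3f) falls outside the %dx%d panel",
                xn, yn, d[2], d[1]),
        raw = c(x = xn, y = yn))
    }
  }
  pixel_coord(xi, yi)
}

#' Write / read a homography as a 9-number text file
#'
#' Row-major, one number per line, full precision. Used to cache a fitted
#' calibration between runs.
#'
#' @param h An [homography()].
#' @param path File path.
#' @export
write_homography <- function(h, path) {
  writeLines(formatC(as.vector(t(h$m)), format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname write_homography
#' @export
read_homography <- function(path) {
  if (!file.exists(path)) lt_input_error(paste("no such file:", path))
  v <- as.numeric(readLines(path, warn = FALSE))
  if (length(v) != 9L || anyNA(v)) {
    lt_input_error("homography file must contain exactly 9 numbers")
  }
  homography(matrix(v, 3L, 3L, byrow = TRUE))
}
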