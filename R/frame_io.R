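#' Images as 8-bit integer arrays
#'
#' Throughout the package a colour image is an integer array of dimension
#' `height x width x 3` with values in 0..255, indexed `[row, column, channel]`
#' internally but addressed by the 0-based `(x, y)` convention in every
#' user-facing coordinate.
#'
#' @param path Path to a PNG, JPEG or TIFF file.
#' @return An integer `h x w x 3` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) lt_input_error(paste("no such file:", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      lt_input_error(paste("unsupported image format:", ext))
    ),
    error = function(e) {
      if (inherits(e, "lizardtherm_error")) stop(e)
      lt_input_error(paste("cannot decode", path, ":", conditionMessage(e)))
    })
  as_image8(img)
}

# normalise whatever a reader returned ([0,1] doubles, grayscale matrix,
# RGBA) to an integer h x w x 3 array in 0..255
as_image8 <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L) lt_input_error("image must be 2-D or 3-D")
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  if (is.double(img) && max(img) <= 1 + 1e-9) img <- img * 255
  storage.mode(img) <- "integer"
  img[img < 0L] <- 0L
  img[img > 255L] <- 255L
  img
}

#' Write an image array to PNG
#'
#' @param image An integer `h x w x 3` array (0..255).
#' @param path Output path (`.png`).
#' @export
write_image <- function(image, path) {
  png::writePNG(array(image / 255, dim = dim(image)), path)
  invisible(path)
}

#' Extract a rectangular region of interest
#'
#' Carves `rect` out of `image`: output pixel `(r, c)` equals input pixel
#' `(rect$y + r, rect$x + c)` (0-based, half-open intervals). This is how the
#' RGB and thermal panels are isolated from a side-by-side composite frame.
#'
#' @param image Integer `h x w x 3` image array.
#' @param rect An [rect()] lying fully inside the image.
#' @return The `rect$height x rect$width x 3` sub-image.
#' @examples
#' img <- array(0L, dim = c(10, 20, 3))
#' left <- extract_roi(img, rect(0, 0, 10, 10))
#' @export
extract_roi <- function(image, rect) {
  rect <- as_rect(rect)
  check_rect_inside(rect, image)
  image[(rect$y + 1L):(rect$y + rect$height),
        (rect$x + 1L):(rect$x + rect$width), , drop = FALSE]
}

#' Paired RGB and thermal panels of one composite frame
#'
#' @param rgb_panel,thermal_panel Integer image arrays.
#' @param frame_index Integer >= 0.
#' @param timestamp A `POSIXct` time for the frame.
#' @return An object of class `lt_frame_pair`.
#' @export
frame_pair <- function(rgb_panel, thermal_panel, frame_index = 0L,
                       timestamp = Sys.time()) {
  if (length(rgb_panel) == 0L || length(thermal_panel) == 0L) {
    lt_value_error("frame panels must be non-empty")
  }
  if (frame_index < 0L) lt_value_error("frame_index must be >= 0")
  structure(list(rgb_panel = rgb_panel, thermal_panel = thermal_panel,
                 frame_index = as.integer(frame_index), timestamp = timestamp),
            class = "lt_frame_pair")
}

#' Split a side-by-side composite into its RGB and thermal panels
#'
#' The composite frames captured by screen-recording the two cameras place
#' the RGB view on the left and the false-colour thermal view (with its
#' colour scale bar) on the right; the two panel rectangles are supplied by
#' the user because the split line depends on the recording setup.
#'
#' @param image The composite frame.
#' @param rgb_rect,thermal_rect Panel rectangles (may overlap).
#' @inheritParams frame_pair
#' @return An `lt_frame_pair`.
#' @export
split_side_by_side <- function(image, rgb_rect, thermal_rect,
                               frame_index = 0L, timestamp = Sys.time()) {
  frame_pair(extract_roi(image, as_rect(rgb_rect)),
             extract_roi(image, as_rect(thermal_rect)),
             frame_index, timestamp)
}

#' Iterate frames from an image, frame directory, or TIFF stack
#'
#' Yields every `stride`-th frame. A single PNG/JPEG yields one frame; a
#' multi-page TIFF or a directory of image files (sorted by name) acts as a
#' frame sequence. Timestamps derive from the source file's mtime plus the
#' frame offset at `fps`. MP4/AVI containers are not decoded; extract frames
#' to a directory first.
#'
#' @param source Path to an image, a multi-page TIFF, or a directory.
#' @param stride Keep every `stride`-th frame (default 1 = every frame).
#' @param fps Nominal frame rate used to derive timestamps (default 25).
#' @return A list of `list(frame_index, timestamp, image)` in frame order.
#' @export
iter_frames <- function(source, stride = 1L, fps = 25) {
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1L) {
    lt_value_error("stride must be an integer >= 1")
  }
  stride <- as.integer(stride)
  if (!file.exists(source)) lt_input_error(paste("no such source:", source))
  base_time <- file.mtime(source)

  frames <- if (dir.exists(source)) {
    paths <- sort(list.files(source, pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(paths) == 0L) {
      lt_input_error(paste("no image frames found in directory:", source))
    }
    lapply(paths, read_image)
  } else {
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("mp4", "avi", "mov", "mkv")) {
      lt_input_error(paste0(
        "video containers are not decoded; extract '", source,
        "' to a directory of frames and pass that directory"))
    }
    if (ext %in% c("tif", "tiff")) {
      pages <- tryCatch(tiff::readTIFF(source, all = TRUE),
                        error = function(e) lt_input_error(
                          paste("cannot decode", source)))
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, as_image8)
    } else {
      list(read_image(source))
    }
  }

  idx <- seq(0L, length(frames) - 1L, by = stride)
  lapply(idx, function(i) {
    list(frame_index = i,
         timestamp = base_time + i / fps,
         image = frames[[i + 1L]])
  })
}

#' Stride preset for a fixed-interval measurement cadence
#'
#' Manual thermography protocols often log one reading every 20 s; this
#' converts that cadence to a frame stride for [iter_frames()].
#'
#' @param fps Frame rate of the recording.
#' @param seconds Interval between measurements (default 20).
#' @return Integer stride (>= 1).
#' @export
cadence_stride <- function(fps, seconds = 20) {
  max(1L, as.integer(round_half_up(seconds * fps)))
}
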