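# End-to-end orchestration: composite frame -> detections -> refined masks
# -> representative pixels -> perspective mapping -> colour-bar temperature
# -> timestamped log lines. A detection that cannot produce a temperature
# (no foreground in its box, or its pixel maps off-panel) is recorded with
# a status instead of being dropped, so log lines always account for every
# detection that survived the confidence filter.

#' Process one frame pair into measurements
#'
#' For each detection at or above the confidence threshold: refine the box
#' to a binary mask, select the representative pixel, map it into the
#' thermal panel, and read its temperature off the colour bar. One
#' measurement row per kept detection, in input order; failures carry
#' status `no_foreground` or `out_of_panel` with no temperature.
#'
#' @param pair An [frame_pair()].
#' @param detector A detector function (see [detect()]).
#' @param cfg An [pipeline_config()].
#' @param clock A zero-argument function returning the measurement time as
#'   `POSIXct`; injectable so tests are reproducible (default [Sys.time]).
#' @return A data frame with columns `date`, `time`, `label`, `rgb_x`,
#'   `rgb_y`, `thermal_x`, `thermal_y`, `temperature_c`, `status`.
#' @export
process_frame <- function(pair, detector, cfg, clock = Sys.time) {
  if (!inherits(cfg, "lt_config")) {
    lt_config_error("cfg must be an lt_config (see pipeline_config())")
  }
  dets <- detect(pair$rgb_panel, detector)
  kept <- filter_detections(dets, cfg$conf_threshold)
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    box <- det_box(kept, i)
    ts <- clock()
    base <- list(date = format(ts, "%Y-%m-%d"),
                 time = format(ts, "%H:%M:%S"),
                 label = kept$label[i],
                 rgb_x = NA_integer_, rgb_y = NA_integer_,
                 thermal_x = NA_integer_, thermal_y = NA_integer_,
                 temperature_c = NA_real_, status = "ok")
    tryCatch({
      mask <- refine_box_mask(pair$rgb_panel, box, cfg$mask_threshold)
      rp <- representative_pixel(mask, box)
      base$rgb_x <- rp$x; base$rgb_y <- rp$y
      tp <- map_point(cfg$homography, rp, panel = pair$thermal_panel)
      base$thermal_x <- tp$x; base$thermal_y <- tp$y
      base$temperature_c <- colour_to_temperature(pair$thermal_panel,
                                                  cfg$scalebar, tp)
      base
    },
    lizardtherm_no_foreground_error = function(e) {
      base$status <- "no_foreground"; base
    },
    lizardtherm_out_of_panel_error = function(e) {
      base$status <- "out_of_panel"; base
    })
  })
  if (length(rows) == 0L) {
    return(data.frame(date = character(), time = character(),
                      label = character(), rgb_x = integer(),
                      rgb_y = integer(), thermal_x = integer(),
                      thermal_y = integer(), temperature_c = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

#' Append measurements to a tab-separated log
#'
#' One line per measurement: `YYYY-MM-DD<TAB>HH:MM:SS<TAB>label<TAB>value`,
#' where the value is the temperature printed with one decimal (matching
#' the precision of the scale-bar labels) or, for failed measurements, the
#' status string. Lines are appended, so repeated runs accumulate like a
#' lab notebook; an empty measurement set leaves the file untouched (but
#' creates it).
#'
#' @param measurements A data frame from [process_frame()].
#' @param path Log file path.
#' @export
write_log <- function(measurements, path) {
  con <- tryCatch(file(path, open = "a"),
                  error = function(e) lt_io_error(paste("cannot open log:", path)))
  on.exit(close(con))
  if (nrow(measurements) > 0L) {
    value <- ifelse(measurements$status == "ok",
                    sprintf("%.1f", measurements$temperature_c),
                    measurements$status)
    writeLines(paste(measurements$date, measurements$time,
                     measurements$label, value, sep = "\t"), con)
  }
  invisible(path)
}

#' Parse a measurement log back into a data frame
#'
#' @param path Log file written by [write_log()].
#' @return A data frame with columns `date`, `time`, `label`,
#'   `temperature_c` (NA for failed measurements) and `status`.
#' @export
read_measurement_log <- function(path) {
  if (!file.exists(path)) lt_input_error(paste("no such log:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(date = character(), time = character(),
                      label = character(), temperature_c = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    lt_input_error("malformed log line: expected 4 tab-separated fields")
  }
  m <- do.call(rbind, parts)
  temp <- suppressWarnings(as.numeric(m[, 4]))
  data.frame(date = m[, 1], time = m[, 2], label = m[, 3],
             temperature_c = temp,
             status = ifelse(is.na(temp), m[, 4], "ok"),
             stringsAsFactors = FALSE)
}

#' Process a source end to end and append to a log
#'
#' Iterates frames from `input` (image, TIFF stack or frame directory),
#' splits each composite into its panels, processes every frame and appends
#' all measurements to `log_path`.
#'
#' @param input Source path for [iter_frames()].
#' @param cfg An [pipeline_config()] (its `stride` is used).
#' @param detector A detector function.
#' @param log_path Output log (appended); `NULL` to skip writing.
#' @param clock Injectable clock, as in [process_frame()].
#' @return All measurements, invisibly.
#' @export
process_source <- function(input, cfg, detector, log_path = NULL,
                           clock = Sys.time) {
  frames <- iter_frames(input, stride = cfg$stride)
  out <- lapply(frames, function(fr) {
    pair <- split_side_by_side(fr$image, cfg$rgb_roi, cfg$thermal_roi,
                               fr$frame_index, fr$timestamp)
    process_frame(pair, detector, cfg, clock = clock)
  })
  measurements <- do.call(rbind, out)
  if (!is.null(log_path)) write_log(measurements, log_path)
  invisible(measurements)
}
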