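# Classed conditions used across the package. Every recoverable pipeline
# failure (no foreground pixel, mapped point off-panel, ...) has its own
# class so process_frame() can turn it into a Measurement status instead of
# aborting the frame.

lt_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "lizardtherm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

lt_bounds_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_bounds_error", ...)
}

lt_value_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_value_error", ...)
}

lt_input_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_input_error", ...)
}

lt_no_foreground_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_no_foreground_error", ...)
}

lt_mapping_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_mapping_error", ...)
}

lt_out_of_panel_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_out_of_panel_error", ...)
}

lt_singularity_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_singularity_error", ...)
}

lt_range_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_range_error", ...)
}

lt_config_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_config_error", ...)
}

lt_detector_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_detector_error", ...)
}

lt_io_error <- function(message, ...) {
  lt_abort(message, "lizardtherm_io_error", ...)
}

# round-half-up on non-negative (and general) values; base round() is
# round-half-even which does not match the int(v + 0.5) convention used
# throughout the pixel arithmetic here.
round_half_up <- function(v) floor(v + 0.5)

# run code with the global RNG seeded, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
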