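# Typed error conditions. Every error raised by the package inherits
# "csvd_error" plus a specific class, so callers (and the CLI's exit
# codes) can dispatch without parsing messages.

csvd_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "csvd_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

abort_format     <- function(msg, ...) csvd_abort("csvd_format_error", msg, ...)
abort_unsupported <- function(msg, ...) csvd_abort("csvd_unsupported_input_error", msg, ...)
abort_label_decode <- function(msg, ...) csvd_abort("csvd_label_decode_error", msg, ...)
abort_shape      <- function(msg, ...) csvd_abort("csvd_shape_error", msg, ...)
abort_config     <- function(msg, ...) csvd_abort("csvd_config_error", msg, ...)
abort_degenerate_image <- function(msg, ...) csvd_abort("csvd_degenerate_image_error", msg, ...)
abort_empty_mask <- function(msg, ...) csvd_abort("csvd_empty_mask_error", msg, ...)
abort_no_brain   <- function(msg, ...) csvd_abort("csvd_no_brain_error", msg, ...)
abort_degenerate_data <- function(msg, ...) csvd_abort("csvd_degenerate_data_error", msg, ...)
abort_count      <- function(msg, ...) csvd_abort("csvd_count_error", msg, ...)
abort_undefined_metric <- function(msg, ...) csvd_abort("csvd_undefined_metric_error", msg, ...)
abort_placement  <- function(msg, ...) csvd_abort("csvd_placement_error", msg, ...)
abort_io         <- function(msg, ...) csvd_abort("csvd_io_error", msg, ...)
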