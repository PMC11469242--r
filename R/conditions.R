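#' @keywords internal
faz_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "faz_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

no_foreground_error   <- function(msg) faz_abort("faz_no_foreground_error", msg)
invalid_polygon_error <- function(msg) faz_abort("faz_invalid_polygon_error", msg)
parameter_error       <- function(msg) faz_abort("faz_parameter_error", msg)
centroid_outside_error<- function(msg) faz_abort("faz_centroid_outside_error", msg)
fit_failed_error      <- function(msg) faz_abort("faz_fit_failed_error", msg)
config_error          <- function(msg) faz_abort("faz_config_error", msg)
data_error            <- function(msg) faz_abort("faz_data_error", msg)
spec_error            <- function(msg) faz_abort("faz_spec_error", msg)
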