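# Classed conditions so callers (and the CLI) can categorize failures.
# Classes: trabsep_io_error, trabsep_format_error, trabsep_dim_error,
# trabsep_grid_error, trabsep_param_error, trabsep_config_error,
# trabsep_consistency_error.

ts_stop <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(class, "trabsep_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_io          <- function(...) ts_stop("trabsep_io_error", ...)
stop_format      <- function(...) ts_stop("trabsep_format_error", ...)
stop_dim         <- function(...) ts_stop("trabsep_dim_error", ...)
stop_grid        <- function(...) ts_stop("trabsep_grid_error", ...)
stop_param       <- function(...) ts_stop("trabsep_param_error", ...)
stop_config      <- function(...) ts_stop("trabsep_config_error", ...)
stop_consistency <- function(...) ts_stop("trabsep_consistency_error", ...)

# Error category label for run logs.
error_category <- function(cond) {
  cl <- class(cond)
  if ("trabsep_io_error" %in% cl) return("I/O")
  if ("trabsep_format_error" %in% cl || "trabsep_dim_error" %in% cl) return("format")
  if ("trabsep_grid_error" %in% cl) return("grid")
  if ("trabsep_param_error" %in% cl || "trabsep_config_error" %in% cl) return("config")
  if ("trabsep_consistency_error" %in% cl) return("consistency")
  "internal"
}
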