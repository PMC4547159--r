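# Classed conditions so callers (and the CLI) can map failures to exit codes:
# usage errors -> 1, data/integrity/lookup/format/parse errors -> 2.

pc_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "pc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

pc_usage_error     <- function(fmt, ...) pc_stop("pc_usage_error", fmt, ...)
pc_integrity_error <- function(fmt, ...) pc_stop("pc_integrity_error", fmt, ...)
pc_lookup_error    <- function(fmt, ...) pc_stop("pc_lookup_error", fmt, ...)
pc_format_error    <- function(fmt, ...) pc_stop("pc_format_error", fmt, ...)
pc_parse_error     <- function(fmt, ...) pc_stop("pc_parse_error", fmt, ...)
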