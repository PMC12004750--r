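#' Classify a port option token as input or output
#'
#' Port direction is a pure function of the option token: tokens starting
#' with \code{-out} or \code{--out} name output ports, every other token
#' names an input port. Tokens are case-sensitive.
#'
#' @param option_token A single option token beginning with \code{"-"},
#'   e.g. \code{"-inf"}, \code{"-outf"}, \code{"--out-summary"}.
#' @return \code{"output"} or \code{"input"}.
#' @examples
#' classify_port("-outf")         # output
#' classify_port("-inf")          # input
#' classify_port("--out-summary") # output
#' @export
classify_port <- function(option_token) {
  if (!is_string(option_token) || !startsWith(option_token, "-")) {
    fbp_error("fbp_malformed_option",
              sprintf("malformed option token %s: must start with '-'",
                      deparse(option_token)))
  }
  if (startsWith(option_token, "--out") || startsWith(option_token, "-out")) {
    "output"
  } else {
    "input"
  }
}

#' Sentinel returned when an option token is absent
#'
#' \code{read_opt_value} returns this distinguished value (rather than
#' raising an error) when the requested token is not present, so callers
#' can branch on optional options.
#'
#' @return An object of class \code{"fbp_not_found"}.
#' @seealso \code{\link{read_opt_value}}
#' @export
opt_not_found <- function() {
  structure(list(), class = "fbp_not_found")
}

#' @rdname opt_not_found
#' @param x Object to test.
#' @export
is_not_found <- function(x) inherits(x, "fbp_not_found")

#' Read the value following an option token in an argument list
#'
#' Scans an ordered option/value argument vector for \code{option_token}
#' and returns the element that follows its first occurrence (duplicate
#' tokens resolve to the first, shell-like precedence).
#'
#' @param args Character vector of alternating option tokens and values.
#' @param option_token Token to look up.
#' @return The value following the token, or \code{opt_not_found()} when
#'   the token is absent. A token in final position (no value after it)
#'   is an error.
#' @examples
#' read_opt_value(c("-inf", "/p/x", "-outf", "/p/y"), "-inf")  # "/p/x"
#' is_not_found(read_opt_value(c("-inf", "/p/x"), "-n"))       # TRUE
#' @export
read_opt_value <- function(args, option_token) {
  stopifnot(is.character(args) || length(args) == 0L)
  idx <- which(args == option_token)
  if (length(idx) == 0L) return(opt_not_found())
  i <- idx[1L]
  if (i == length(args)) {
    fbp_error("fbp_malformed_args",
              sprintf("option %s present but no value follows it", option_token))
  }
  args[[i + 1L]]
}

#' Declare a process port
#'
#' A port is a named option of a process; its direction follows from the
#' token prefix rule (see \code{\link{classify_port}}). The payload states
#' what travels through the port: a \code{"stream"} of newline-delimited
#' records over a FIFO, a \code{"path"} to a regular file, or a plain
#' \code{"value"}.
#'
#' @param option_token Option token, e.g. \code{"-inf"}.
#' @param payload One of \code{"stream"}, \code{"path"}, \code{"value"}.
#' @param required Logical; must the port be bound for the program to run?
#' @param doc Short description used in help rendering.
#' @param value_kind One of \code{"string"}, \code{"int"}, \code{"path"}.
#' @return A \code{port_spec} object.
#' @export
port_spec <- function(option_token,
                      payload = c("stream", "path", "value"),
                      required = TRUE,
                      doc = "",
                      value_kind = c("string", "int", "path")) {
  payload <- match.arg(payload)
  value_kind <- match.arg(value_kind)
  direction <- classify_port(option_token)
  structure(list(
    option_token = option_token,
    direction = direction,
    payload = payload,
    required = isTRUE(required),
    doc = doc,
    value_kind = value_kind
  ), class = "fbp_port")
}

# Derive the short port name used in FIFO basenames: lowercase the token,
# strip leading dashes, then a leading "in"/"out" prefix plus a following
# separator. When stripping would leave nothing (tokens "-in"/"-out"), the
# dash-stripped token itself is the name, matching conventional FIFO names
# such as counter_out and stream_echo_in.
port_short_name <- function(option_token) {
  s <- tolower(sub("^-+", "", option_token))
  stripped <- sub("^(out|in)[-_]?", "", s)
  if (nzchar(stripped)) stripped else s
}

fifo_basename_for <- function(process, option_token) {
  paste0(process, "_", port_short_name(option_token))
}

#' @export
print.fbp_port <- function(x, ...) {
  cat(sprintf("<port %s %s %s%s>\n", x$option_token, x$direction, x$payload,
              if (x$required) "" else " optional"))
  invisible(x)
}
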