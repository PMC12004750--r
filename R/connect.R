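# Connection directives: the vocabulary a process's connection rule uses to
# state where each of its options comes from (or goes to). A connection rule
# (eager `connect` or generator `generate`) produces an ordered list of
# these; resolving a program drains every rule and turns the directives into
# channels and per-process option lists.

directive <- function(kind, token, ...) {
  structure(list(kind = kind, token = token, ...), class = "fbp_directive")
}

#' Connection directives
#'
#' Constructors for the directives a connection rule may emit:
#' \describe{
#'   \item{\code{opt_cmdline(token, default)}}{bind the option to the value
#'     supplied on the program command line (a \code{value} channel). When
#'     the token is absent and a default is given, the default binds;
#'     absent with no default on a required port is an unbound-input
#'     error.}
#'   \item{\code{opt_from_proc_out(token, producer, producer_token)}}{bind
#'     this input option to an output option of another process. The
#'     channel medium is \code{stream} (a FIFO) when the producer port's
#'     payload is a stream, else \code{file}.}
#'   \item{\code{opt_fifo(token, basename)}}{create a FIFO whose other
#'     endpoint is external (exposed to the user under
#'     \code{__fifos__/}); the default basename is
#'     \code{<process>_<portname>}.}
#'   \item{\code{opt_file(token, filename)}}{bind an output path option to
#'     a regular file under the producing process's output directory.
#'     \code{filename} may contain \code{{task}}, replaced by the 1-based
#'     task index.}
#'   \item{\code{opt_value(token, value)}}{bind a literal value.}
#' }
#'
#' @param token Option token of the process being connected.
#' @param default Default value for an absent command-line option.
#' @param producer,producer_token The producing process and its output
#'   option token.
#' @param basename FIFO basename override.
#' @param filename File name under the process output directory.
#' @param value Literal value.
#' @return A directive object, consumed by \code{\link{resolve}}.
#' @name directives
NULL

#' @rdname directives
#' @export
opt_cmdline <- function(token, default = NULL) {
  directive("cmdline", token, default = default)
}

#' @rdname directives
#' @export
opt_from_proc_out <- function(token, producer, producer_token) {
  directive("proc_out", token, producer = producer,
            producer_token = producer_token)
}

#' @rdname directives
#' @export
opt_fifo <- function(token, basename = NULL) {
  directive("fifo", token, basename = basename)
}

#' @rdname directives
#' @export
opt_file <- function(token, filename = NULL) {
  directive("file", token, filename = filename)
}

#' @rdname directives
#' @export
opt_value <- function(token, value) {
  directive("value", token, value = as.character(value))
}

# Drain a connection rule into a list of directive lists, one per task.
# Eager rules yield one list shared by every task; generator rules are
# called once per task index.
drain_connect_rule <- function(spec) {
  n <- spec$task_count
  if (!is.null(spec$generate)) {
    lapply(seq_len(n), function(t) {
      ds <- spec$generate(t)
      check_directives(spec, ds)
      ds
    })
  } else {
    ds <- if (is.function(spec$connect)) spec$connect() else spec$connect
    check_directives(spec, ds)
    rep(list(ds), n)
  }
}

check_directives <- function(spec, ds) {
  if (!is.list(ds) || (length(ds) && !all(vapply(ds, inherits, TRUE, "fbp_directive")))) {
    fbp_error("fbp_invalid_connect",
              sprintf("connection rule of process %s must return a list of directives",
                      spec$name))
  }
  for (d in ds) {
    if (is.null(process_port(spec, d$token))) {
      fbp_error("fbp_unknown_port",
                sprintf("process %s has no port %s referenced by its connection rule",
                        spec$name, d$token))
    }
  }
  invisible(ds)
}
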