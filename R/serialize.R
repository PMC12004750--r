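# Program definition files: a versioned plain-text (JSON) schema so the
# CLI can load programs from disk. Only declarative connection rules
# (directive lists) serialize; function-style rules and native_callable
# bodies are in-memory constructs and are rejected with a clear error.

PROGRAM_SCHEMA <- "fbpr-program/1"

directive_to_list <- function(d) {
  out <- list(kind = d$kind, token = d$token)
  extra <- switch(d$kind,
    cmdline = list(default = d$default),
    proc_out = list(producer = d$producer, producer_token = d$producer_token),
    fifo = list(basename = d$basename),
    file = list(filename = d$filename),
    value = list(value = d$value))
  for (nm in names(extra)) if (!is.null(extra[[nm]])) out[[nm]] <- extra[[nm]]
  out
}

directive_from_list <- function(x) {
  switch(x$kind,
    cmdline = opt_cmdline(x$token, default = x$default),
    proc_out = opt_from_proc_out(x$token, x$producer, x$producer_token),
    fifo = opt_fifo(x$token, basename = x$basename),
    file = opt_file(x$token, filename = x$filename),
    value = opt_value(x$token, x$value),
    fbp_error("fbp_bad_program_file", sprintf("unknown directive kind %s", x$kind)))
}

#' Serialize a program definition to a file
#'
#' Writes a versioned JSON document that \code{\link{read_program}}
#' loads back; serializing and reloading round-trips byte-identically.
#' Only declarative connection rules and text bodies serialize.
#'
#' @param program A \code{\link{program_spec}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_program <- function(program, path) {
  stopifnot(inherits(program, "fbp_program"))
  procs <- lapply(program$processes, function(s) {
    if (is.function(s$connect) || !is.null(s$generate)) {
      fbp_error("fbp_not_serializable",
                sprintf("process %s uses a function-style connection rule; only declarative directive lists serialize",
                        s$name))
    }
    if (s$body$form == "native_callable") {
      fbp_error("fbp_not_serializable",
                sprintf("process %s has a native_callable body", s$name))
    }
    list(
      name = s$name,
      exec_class = s$exec_class,
      task_count = s$task_count,
      resources = s$resources,
      body = list(form = s$body$form, text = s$body$text,
                  interpreter = s$body$interpreter),
      ports = lapply(s$ports, function(p) {
        list(option_token = p$option_token, payload = p$payload,
             required = p$required, doc = p$doc, value_kind = p$value_kind)
      }),
      connect = lapply(s$connect, directive_to_list)
    )
  })
  doc <- list(schema = PROGRAM_SCHEMA,
              module_name = program$module_name,
              processes = procs,
              option_docs = program$option_docs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a program definition from a file
#'
#' @param path A file written by \code{\link{write_program}}.
#' @return A \code{\link{program_spec}}.
#' @export
read_program <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, PROGRAM_SCHEMA)) {
    fbp_error("fbp_bad_program_file",
              sprintf("unsupported program schema %s (expected %s)",
                      doc$schema %||% "(none)", PROGRAM_SCHEMA))
  }
  prog <- program_spec(doc$module_name)
  for (p in doc$processes) {
    spec <- process_spec(
      name = p$name,
      body = body_spec(text = p$body$text, form = p$body$form,
                       interpreter = p$body$interpreter %||% ""),
      ports = lapply(p$ports, function(q) {
        port_spec(q$option_token, payload = q$payload,
                  required = isTRUE(q$required), doc = q$doc %||% "",
                  value_kind = q$value_kind %||% "string")
      }),
      connect = lapply(p$connect, directive_from_list),
      resources = p$resources,
      task_count = p$task_count %||% 1L,
      exec_class = p$exec_class
    )
    prog <- register_process(prog, spec)
  }
  for (proc in names(doc$option_docs)) {
    for (tok in names(doc$option_docs[[proc]])) {
      d <- doc$option_docs[[proc]][[tok]]
      prog <- document_option(prog, proc, tok, d$value_kind,
                              d$description %||% "", isTRUE(d$required))
    }
  }
  prog
}
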