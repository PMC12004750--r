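#' Declare a process body
#'
#' A body is what a process executes once its options are bound. Three
#' forms exist: \code{"command_text"} (a command line; bound options are
#' appended as arguments), \code{"inline_script"} (script source run via a
#' declared interpreter, passed byte-exact with no escaping), and
#' \code{"native_callable"} (an R function; only usable through
#' \code{\link{invoke_inline}} and dynamic computations, never spawned as
#' a network process).
#'
#' @param text Command line or script source.
#' @param form One of \code{"command_text"}, \code{"inline_script"},
#'   \code{"native_callable"}.
#' @param interpreter Interpreter command for inline scripts (e.g.
#'   \code{"sh"}, \code{"python"}, \code{"Rscript"}). Required for
#'   \code{inline_script}.
#' @param fun R function for \code{native_callable} bodies; receives the
#'   bound argument vector.
#' @return A \code{body_spec} object.
#' @export
body_spec <- function(text = "",
                      form = c("inline_script", "command_text", "native_callable"),
                      interpreter = "",
                      fun = NULL) {
  form <- match.arg(form)
  if (form == "inline_script" && !nzchar(interpreter)) {
    fbp_error("fbp_invalid_body",
              "inline_script bodies require a non-empty interpreter")
  }
  if (form == "native_callable" && !is.function(fun)) {
    fbp_error("fbp_invalid_body", "native_callable bodies require `fun`")
  }
  structure(list(form = form, text = text, interpreter = interpreter, fun = fun),
            class = "fbp_body")
}

# Convenience: an inline POSIX-shell body.
sh_body <- function(text) body_spec(text = text, form = "inline_script", interpreter = "sh")

#' Declare a process template
#'
#' A process has a name, an execution class, a body, a set of ports, a
#' resource declaration, a task count (array size, job steps only) and a
#' connection rule. Exactly one connection style must be given:
#' \code{connect} (the eager style: a directive list, or a zero-argument
#' function returning one) or \code{generate} (the generator style: a
#' function of the 1-based task index returning a directive list, enabling
#' per-task option lists for arrays).
#'
#' @param name Process identifier, matching
#'   \code{[A-Za-z_][A-Za-z0-9_]*} (it is embedded in file and FIFO names).
#' @param body A \code{\link{body_spec}}.
#' @param ports List of \code{\link{port_spec}} objects; tokens must be
#'   unique within the process.
#' @param connect Eager connection rule (directive list or function()).
#' @param generate Generator connection rule (function(task_index)).
#' @param resources Named list with \code{cpus}, \code{mem_mb},
#'   \code{time_min}.
#' @param task_count Array size; defaults to 1. Rejected for FBP
#'   processes (arrays apply to job steps only).
#' @param exec_class \code{"fbp_process"}, \code{"job_step"}, or
#'   \code{NULL} to infer at resolve time (any stream port forces
#'   \code{fbp_process}; all-file/value ports default to
#'   \code{job_step}).
#' @return A \code{process_spec} object.
#' @export
process_spec <- function(name, body, ports = list(),
                         connect = NULL, generate = NULL,
                         resources = list(cpus = 1, mem_mb = 256, time_min = 60),
                         task_count = 1L,
                         exec_class = NULL) {
  if (!is_identifier(name)) {
    fbp_error("fbp_invalid_name",
              sprintf("invalid process name %s: must match [A-Za-z_][A-Za-z0-9_]*",
                      deparse(name)))
  }
  stopifnot(inherits(body, "fbp_body"))
  toks <- vapply(ports, function(p) p$option_token, "")
  if (anyDuplicated(toks)) {
    fbp_error("fbp_duplicate_port",
              sprintf("duplicate port token(s) in process %s: %s", name,
                      paste(unique(toks[duplicated(toks)]), collapse = ", ")))
  }
  if (is.null(connect) && is.null(generate)) connect <- list()
  if (!is.null(connect) && !is.null(generate)) {
    fbp_error("fbp_invalid_process",
              sprintf("process %s: exactly one of connect/generate may be set", name))
  }
  if (!is_count(task_count)) {
    fbp_error("fbp_invalid_process",
              sprintf("process %s: task_count must be a positive integer", name))
  }
  if (!is.null(exec_class)) {
    exec_class <- match.arg(exec_class, c("fbp_process", "job_step"))
    if (exec_class == "fbp_process" && task_count > 1L) {
      fbp_error("fbp_invalid_process",
                sprintf("process %s: task arrays apply to job steps only", name))
    }
  }
  res <- utils::modifyList(list(cpus = 1, mem_mb = 256, time_min = 60),
                           as.list(resources))
  structure(list(
    name = name, body = body, ports = ports,
    connect = connect, generate = generate,
    resources = res, task_count = as.integer(task_count),
    exec_class = exec_class
  ), class = "fbp_process_spec")
}

process_port <- function(spec, token) {
  for (p in spec$ports) if (p$option_token == token) return(p)
  NULL
}

#' Create an empty program (module)
#'
#' A program is an ordered collection of process templates plus option
#' documentation, built up with \code{\link{register_process}},
#' \code{\link{include_module}} and \code{\link{document_option}}.
#' Declaration order is recorded and used as the deterministic tie-break
#' everywhere ordering matters.
#'
#' @param module_name Identifier of the module owning the program.
#' @return A \code{program_spec} object.
#' @export
program_spec <- function(module_name) {
  if (!is_identifier(module_name)) {
    fbp_error("fbp_invalid_name",
              sprintf("invalid module name %s", deparse(module_name)))
  }
  structure(list(
    module_name = module_name,
    processes = list(),
    option_docs = list(),     # process -> token -> list(value_kind, description, required)
    included_modules = character(),
    process_module = character()  # process name -> defining module
  ), class = "fbp_program")
}

#' Add a process template to a program
#'
#' @param program A \code{\link{program_spec}}.
#' @param spec A \code{\link{process_spec}}.
#' @return The updated program; declaration order is preserved.
#' @export
register_process <- function(program, spec) {
  stopifnot(inherits(program, "fbp_program"), inherits(spec, "fbp_process_spec"))
  if (spec$name %in% names(program$process_module)) {
    fbp_error("fbp_duplicate_process",
              sprintf("process %s is already registered", spec$name))
  }
  program$processes[[length(program$processes) + 1L]] <- spec
  program$process_module[[spec$name]] <- program$module_name
  program
}

#' Include another module's program
#'
#' Merges the processes and option documentation of \code{other} into
#' \code{program}. Inclusion is idempotent: including the same module
#' twice is the same as including it once.
#'
#' @param program,other \code{\link{program_spec}} objects.
#' @return The merged program.
#' @export
include_module <- function(program, other) {
  stopifnot(inherits(program, "fbp_program"), inherits(other, "fbp_program"))
  if (other$module_name %in% program$included_modules ||
      other$module_name == program$module_name) {
    return(program)
  }
  clash <- intersect(names(program$process_module), names(other$process_module))
  if (length(clash)) {
    owners <- unique(program$process_module[clash])
    fbp_error("fbp_module_clash",
              sprintf("process name clash between modules %s and %s: %s",
                      paste(owners, collapse = "/"), other$module_name,
                      paste(clash, collapse = ", ")))
  }
  for (p in other$processes) {
    program$processes[[length(program$processes) + 1L]] <- p
  }
  program$process_module <- c(program$process_module, other$process_module)
  for (proc in names(other$option_docs)) {
    for (tok in names(other$option_docs[[proc]])) {
      program <- document_option(program, proc, tok,
                                 other$option_docs[[proc]][[tok]]$value_kind,
                                 other$option_docs[[proc]][[tok]]$description,
                                 other$option_docs[[proc]][[tok]]$required)
    }
  }
  program$included_modules <- c(program$included_modules, other$module_name,
                                other$included_modules)
  program
}

#' Document a command-line option of a process
#'
#' Registers help metadata for an option the user supplies on the command
#' line: its value kind and a description. Rendered by
#' \code{\link{render_help}}.
#'
#' @param program A \code{\link{program_spec}}.
#' @param process Name of a registered process.
#' @param option_token The option token.
#' @param value_kind One of \code{"string"}, \code{"int"}, \code{"path"}.
#' @param description Free-text description (empty is accepted and
#'   flagged as undocumented in the help output).
#' @param required Logical.
#' @return The updated program.
#' @export
document_option <- function(program, process, option_token,
                            value_kind = c("string", "int", "path"),
                            description = "", required = TRUE) {
  stopifnot(inherits(program, "fbp_program"))
  value_kind <- match.arg(value_kind)
  if (!process %in% names(program$process_module)) {
    fbp_error("fbp_unknown_process",
              sprintf("cannot document option for unregistered process %s", process))
  }
  if (!is.null(program$option_docs[[process]][[option_token]])) {
    fbp_error("fbp_duplicate_doc",
              sprintf("option %s of process %s is already documented",
                      option_token, process))
  }
  if (is.null(program$option_docs[[process]])) {
    program$option_docs[[process]] <- list()
  }
  program$option_docs[[process]][[option_token]] <-
    list(value_kind = value_kind, description = description,
         required = isTRUE(required))
  program
}

#' Render program help text
#'
#' One stable, line-oriented help listing: every documented option appears
#' exactly once under its process.
#'
#' @param program A \code{\link{program_spec}}.
#' @return Character vector of help lines.
#' @export
render_help <- function(program) {
  lines <- c(sprintf("Program: %s", program$module_name), "Options:")
  for (spec in program$processes) {
    docs <- program$option_docs[[spec$name]]
    if (is.null(docs) || length(docs) == 0L) next
    lines <- c(lines, sprintf("  %s:", spec$name))
    for (tok in names(docs)) {
      d <- docs[[tok]]
      desc <- if (nzchar(d$description)) d$description else "(undocumented)"
      lines <- c(lines, sprintf("    %s <%s>%s  %s", tok, d$value_kind,
                                if (d$required) "" else " [optional]", desc))
    }
  }
  lines
}

process_names <- function(program) {
  vapply(program$processes, function(p) p$name, "")
}

#' @export
print.fbp_program <- function(x, ...) {
  cat(sprintf("<fbp program %s: %d process(es)>\n", x$module_name,
              length(x$processes)))
  for (p in x$processes) {
    cat(sprintf("  %-14s %s tasks=%d ports: %s\n", p$name,
                p$exec_class %||% "(inferred)", p$task_count,
                paste(vapply(p$ports, function(q) q$option_token, ""),
                      collapse = " ")))
  }
  invisible(x)
}
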