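# Network resolution: compile a program into a resolved network by draining
# every process's connection rule, creating channels, and classifying the
# result (cyclic or not, plus the job-step dependency graph).
#
# Performance note: binding lists are accumulated per process in local
# variables and written to the shared state once, so resolving arrays of
# tens of thousands of tasks stays linear. File channels between arrayed
# processes are recorded once per port pair (the per-task paths live in
# the bindings), keeping the channel list small.

endpoint_process <- function(process, token) {
  list(kind = "process_port", process = process, option_token = token,
       external_name = "")
}

endpoint_external <- function(name) {
  list(kind = "external", process = "", option_token = "", external_name = name)
}

new_resolver_state <- function() {
  e <- new.env(parent = emptyenv())
  e$channels <- list()
  e$fifo_basenames <- character()
  e$bindings <- list()          # process -> list(task) -> ordered entries
  e$consumed_out <- character() # "proc\ttoken" of stream outputs already consumed
  e$bound_in <- character()     # "proc\ttoken" of bound input ports
  e$bound_out <- character()    # "proc\ttoken" of value-carrying output ports
  e$cmdline_used <- character()
  e$dep_edges <- character()    # "producer\tconsumer", unique
  e
}

add_channel <- function(st, chan) {
  chan$id <- length(st$channels) + 1L
  st$channels[[chan$id]] <- chan
  chan$id
}

claim_fifo_basename <- function(st, basename) {
  if (basename %in% st$fifo_basenames) {
    fbp_error("fbp_fifo_collision",
              sprintf("FIFO basename collision: %s", basename))
  }
  st$fifo_basenames <- c(st$fifo_basenames, basename)
  basename
}

mark_input_bound <- function(st, process, token) {
  key <- paste(process, token, sep = "\t")
  if (key %in% st$bound_in) {
    fbp_error("fbp_port_already_bound",
              sprintf("input port %s of process %s is already bound (single-producer rule)",
                      token, process))
  }
  st$bound_in <- c(st$bound_in, key)
}

claim_stream_output <- function(st, process, token) {
  key <- paste(process, token, sep = "\t")
  if (key %in% st$consumed_out) {
    fbp_error("fbp_port_already_bound",
              sprintf("output port %s of %s already consumed", token, process))
  }
  st$consumed_out <- c(st$consumed_out, key)
  st$bound_out <- c(st$bound_out, key)
}

default_output_filename <- function(spec, token, task) {
  base <- port_short_name(token)
  if (spec$task_count > 1L) sprintf("%s_%04d.out", base, task) else paste0(base, ".out")
}

#' Resolve a program into an executable network
#'
#' Drains every process's connection rule (eager rules exactly once,
#' generator rules once per task), binds command-line values, creates the
#' stream/file/value channels, classifies cyclicity, and derives the
#' job-step dependency graph. Execution classes left unspecified are
#' inferred here: any stream port forces \code{fbp_process}; all
#' file/value ports default to \code{job_step}.
#'
#' @param program A \code{\link{program_spec}}.
#' @param cmdline Character vector of option/value pairs supplied by the
#'   user (e.g. \code{c("-f", "input.txt")}). Unknown tokens are a
#'   fail-fast error; every token must be consumed by some
#'   \code{opt_cmdline} directive.
#' @return An object of class \code{fbp_network}.
#' @export
resolve <- function(program, cmdline = character()) {
  stopifnot(inherits(program, "fbp_program"))
  specs <- program$processes
  pnames <- process_names(program)
  if (anyDuplicated(pnames)) {
    fbp_error("fbp_duplicate_process", "duplicate process names in program")
  }
  names(specs) <- pnames

  # Infer execution classes.
  specs <- lapply(specs, function(s) {
    payloads <- vapply(s$ports, function(p) p$payload, "")
    inferred <- if (any(payloads == "stream")) "fbp_process" else "job_step"
    if (is.null(s$exec_class)) s$exec_class <- inferred
    if (s$exec_class == "fbp_process" && s$task_count > 1L) {
      fbp_error("fbp_invalid_process",
                sprintf("process %s: task arrays apply to job steps only", s$name))
    }
    if (s$exec_class == "job_step" && any(payloads == "stream")) {
      fbp_error("fbp_invalid_process",
                sprintf("job step %s may not declare stream ports", s$name))
    }
    s
  })

  # Validate command line shape and index its tokens.
  cmd_tokens <- character()
  i <- 1L
  while (i <= length(cmdline)) {
    tok <- cmdline[[i]]
    if (!startsWith(tok, "-")) {
      fbp_error("fbp_malformed_args",
                sprintf("expected an option token at position %d, got %s", i,
                        deparse(tok)))
    }
    if (i == length(cmdline)) {
      fbp_error("fbp_malformed_args",
                sprintf("option %s present but no value follows it", tok))
    }
    cmd_tokens <- c(cmd_tokens, tok)
    i <- i + 2L
  }

  st <- new_resolver_state()
  directives <- lapply(specs, drain_connect_rule)
  unbound <- character()

  # Phase A: directives that only involve the process itself; cross-process
  # connections become placeholders filled in phase B.
  for (nm in pnames) {
    spec <- specs[[nm]]
    btasks <- vector("list", spec$task_count)
    for (t in seq_len(spec$task_count)) {
      entries <- list()
      for (d in directives[[nm]][[t]]) {
        port <- process_port(spec, d$token)
        entry <- switch(d$kind,
          cmdline = {
            v <- read_opt_value(cmdline, d$token)
            if (t == 1L) st$cmdline_used <- union(st$cmdline_used, d$token)
            if (is_not_found(v)) v <- d$default
            if (is.null(v)) {
              if (port$required && t == 1L) {
                unbound <- c(unbound, sprintf("%s/%s", nm, d$token))
              }
              NULL
            } else {
              if (t == 1L) mark_input_bound(st, nm, d$token)
              list(type = "literal", token = d$token, value = as.character(v))
            }
          },
          value = {
            if (port$direction == "input" && t == 1L) mark_input_bound(st, nm, d$token)
            list(type = "literal", token = d$token, value = d$value)
          },
          fifo = {
            if (port$payload != "stream") {
              fbp_error("fbp_invalid_connect",
                        sprintf("opt_fifo on %s/%s requires a stream port", nm, d$token))
            }
            base <- d$basename %||% fifo_basename_for(nm, d$token)
            claim_fifo_basename(st, base)
            if (port$direction == "output") {
              claim_stream_output(st, nm, d$token)
              cid <- add_channel(st, list(
                producer = endpoint_process(nm, d$token),
                consumers = list(endpoint_external(base)),
                medium = "stream", fifo_basename = base))
              list(type = "chan_w", token = d$token, channel = cid)
            } else {
              mark_input_bound(st, nm, d$token)
              cid <- add_channel(st, list(
                producer = endpoint_external(base),
                consumers = list(endpoint_process(nm, d$token)),
                medium = "stream", fifo_basename = base))
              list(type = "chan_r", token = d$token, channel = cid)
            }
          },
          file = {
            if (port$direction != "output" || port$payload != "path") {
              fbp_error("fbp_invalid_connect",
                        sprintf("opt_file on %s/%s requires an output path port",
                                nm, d$token))
            }
            fname <- d$filename %||% default_output_filename(spec, d$token, t)
            fname <- gsub("{task}", as.character(t), fname, fixed = TRUE)
            if (t == 1L) {
              st$bound_out <- c(st$bound_out, paste(nm, d$token, sep = "\t"))
            }
            list(type = "relpath", token = d$token, rel = file.path(nm, fname))
          },
          proc_out = list(type = "pending_proc_out", token = d$token,
                          directive = d)
        )
        if (!is.null(entry)) entries[[length(entries) + 1L]] <- entry
      }
      btasks[[t]] <- entries
    }
    st$bindings[[nm]] <- btasks
  }

  # Auto-bind required output path ports that no directive filled.
  for (nm in pnames) {
    spec <- specs[[nm]]
    for (port in spec$ports) {
      key <- paste(nm, port$option_token, sep = "\t")
      if (port$direction == "output" && port$payload == "path" &&
          !key %in% st$bound_out) {
        st$bound_out <- c(st$bound_out, key)
        btasks <- st$bindings[[nm]]
        for (t in seq_len(spec$task_count)) {
          btasks[[t]][[length(btasks[[t]]) + 1L]] <- list(
            type = "relpath", token = port$option_token,
            rel = file.path(nm, default_output_filename(spec, port$option_token, t)))
        }
        st$bindings[[nm]] <- btasks
      }
    }
  }

  find_relpath <- function(btasks, token, task) {
    for (e in btasks[[task]]) {
      if (e$token == token && e$type == "relpath") return(e$rel)
    }
    NULL
  }

  # Phase B: cross-process connections (needs every producer's file
  # bindings in place, regardless of declaration order).
  for (nm in pnames) {
    spec <- specs[[nm]]
    btasks <- st$bindings[[nm]]
    for (t in seq_len(spec$task_count)) {
      for (k in seq_along(btasks[[t]])) {
        e <- btasks[[t]][[k]]
        if (e$type != "pending_proc_out") next
        d <- e$directive
        q <- d$producer
        if (!q %in% pnames) {
          fbp_error("fbp_unknown_process",
                    sprintf("process %s connects to unknown process %s", nm, q))
        }
        qspec <- specs[[q]]
        qport <- process_port(qspec, d$producer_token)
        if (is.null(qport)) {
          fbp_error("fbp_unknown_port",
                    sprintf("process %s has no port %s", q, d$producer_token))
        }
        if (qport$direction != "output") {
          fbp_error("fbp_direction_mismatch",
                    sprintf("%s/%s is not an output port", q, d$producer_token))
        }
        port <- process_port(spec, d$token)
        if (port$direction != "input") {
          fbp_error("fbp_direction_mismatch",
                    sprintf("%s/%s is not an input port", nm, d$token))
        }
        if (t == 1L) mark_input_bound(st, nm, d$token)
        if (qport$payload == "stream") {
          claim_stream_output(st, q, d$producer_token)
          if (spec$exec_class == "job_step") {
            fbp_error("fbp_invalid_connect",
                      sprintf("job step %s may not consume stream channel from %s",
                              nm, q))
          }
          base <- claim_fifo_basename(st, fifo_basename_for(q, d$producer_token))
          cid <- add_channel(st, list(
            producer = endpoint_process(q, d$producer_token),
            consumers = list(endpoint_process(nm, d$token)),
            medium = "stream", fifo_basename = base))
          btasks[[t]][[k]] <- list(type = "chan_r", token = d$token, channel = cid)
          wentry <- list(type = "chan_w", token = d$producer_token, channel = cid)
          if (q == nm) {
            btasks[[1L]][[length(btasks[[1L]]) + 1L]] <- wentry
          } else {
            qb <- st$bindings[[q]]
            qb[[1L]][[length(qb[[1L]]) + 1L]] <- wentry
            st$bindings[[q]] <- qb
          }
        } else {
          qt <- if (qspec$task_count == spec$task_count) t
                else if (qspec$task_count == 1L) 1L
                else fbp_error("fbp_invalid_connect",
                               sprintf("array size mismatch: %s (%d) vs %s (%d)",
                                       q, qspec$task_count, nm, spec$task_count))
          qbtasks <- if (q == nm) btasks else st$bindings[[q]]
          rel <- find_relpath(qbtasks, d$producer_token, qt)
          if (is.null(rel)) {
            fbp_error("fbp_unknown_port",
                      sprintf("no file binding for %s/%s", q, d$producer_token))
          }
          if (t == 1L) {
            add_channel(st, list(
              producer = endpoint_process(q, d$producer_token),
              consumers = list(endpoint_process(nm, d$token)),
              medium = "file", fifo_basename = "", rel = rel))
            if (spec$exec_class == "job_step" && qspec$exec_class == "job_step") {
              st$dep_edges <- union(st$dep_edges, paste(q, nm, sep = "\t"))
            }
          }
          btasks[[t]][[k]] <- list(type = "relpath", token = d$token, rel = rel)
        }
      }
    }
    st$bindings[[nm]] <- btasks
  }

  # Unbound required input ports (not touched by any directive).
  for (nm in pnames) {
    spec <- specs[[nm]]
    for (port in spec$ports) {
      key <- paste(nm, port$option_token, sep = "\t")
      if (port$direction == "input" && port$required && !key %in% st$bound_in) {
        unbound <- c(unbound, sprintf("%s/%s", nm, port$option_token))
      }
    }
  }
  if (length(unbound)) {
    fbp_error("fbp_unbound_input",
              sprintf("unbound required input(s): %s",
                      paste(unique(unbound), collapse = ", ")))
  }

  # Unconnected stream outputs would block their writer forever.
  for (nm in pnames) {
    for (port in specs[[nm]]$ports) {
      key <- paste(nm, port$option_token, sep = "\t")
      if (port$direction == "output" && port$payload == "stream" &&
          port$required && !key %in% st$consumed_out) {
        fbp_error("fbp_unbound_input",
                  sprintf("stream output %s/%s has no consumer (connect it or expose a FIFO)",
                          nm, port$option_token))
      }
    }
  }

  # Fail fast on command-line tokens nothing consumes.
  unknown <- setdiff(cmd_tokens, st$cmdline_used)
  if (length(unknown)) {
    fbp_error("fbp_unknown_option",
              sprintf("unknown command-line option(s): %s",
                      paste(unknown, collapse = ", ")))
  }

  # Documented options never consumed by a connection rule: warn.
  for (proc in names(program$option_docs)) {
    for (tok in names(program$option_docs[[proc]])) {
      if (!tok %in% st$cmdline_used) {
        fbp_warn("fbp_doc_mismatch",
                 sprintf("option %s documented for process %s is never consumed by a connection rule",
                         tok, proc))
      }
    }
  }

  # Cyclicity over the directed multigraph of process-port channels.
  internal <- Filter(function(ch) {
    ch$producer$kind == "process_port" &&
      any(vapply(ch$consumers, function(e) e$kind == "process_port", TRUE))
  }, st$channels)
  edges <- do.call(rbind, lapply(internal, function(ch) {
    cons <- Filter(function(e) e$kind == "process_port", ch$consumers)
    cbind(ch$producer$process, vapply(cons, function(e) e$process, ""))
  }))
  cyclic <- FALSE
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    cyclic <- !igraph::is_dag(g)
    if (cyclic) {
      sccs <- igraph::components(g, mode = "strong")
      cyc_nodes <- names(sccs$membership)[sccs$membership %in%
                                            which(sccs$csize > 1)]
      loops <- edges[edges[, 1] == edges[, 2], 1]
      cyc_nodes <- union(cyc_nodes, loops)
      bad <- cyc_nodes[vapply(cyc_nodes,
                              function(n) specs[[n]]$exec_class == "job_step", TRUE)]
      if (length(bad)) {
        fbp_error("fbp_cycle_job_step",
                  sprintf("job step(s) on a cycle: %s", paste(bad, collapse = ", ")))
      }
    }
  }

  dep_edges <- if (length(st$dep_edges)) {
    do.call(rbind, strsplit(st$dep_edges, "\t", fixed = TRUE))
  } else {
    NULL
  }

  structure(list(
    program = program,
    specs = specs,
    channels = st$channels,
    bindings = st$bindings,
    cyclic = cyclic,
    dep_edges = dep_edges,       # matrix (producer, consumer) or NULL
    cmdline = cmdline
  ), class = "fbp_network")
}

network_spec <- function(network, process) {
  s <- network$specs[[process]]
  if (is.null(s)) {
    fbp_error("fbp_unknown_process", sprintf("unknown process %s", process))
  }
  s
}

job_step_names <- function(network) {
  nms <- names(network$specs)
  nms[vapply(network$specs, function(s) s$exec_class == "job_step", TRUE)]
}

fbp_process_names <- function(network) {
  nms <- names(network$specs)
  nms[vapply(network$specs, function(s) s$exec_class == "fbp_process", TRUE)]
}

stream_channels <- function(network) {
  Filter(function(ch) ch$medium == "stream", network$channels)
}

# Weakly-connected components of processes linked by internal stream
# channels (each component is one concurrently executing pipeline).
stream_components <- function(network) {
  edges <- do.call(rbind, lapply(stream_channels(network), function(ch) {
    if (!is_internal_channel(ch)) return(NULL)
    cbind(ch$producer$process, ch$consumers[[1]]$process)
  }))
  if (is.null(edges) || !nrow(edges)) return(list())
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comps <- igraph::components(g)
  split(names(comps$membership), comps$membership)
}

#' Derive the job-step dependency graph
#'
#' Nodes are the job-step processes; an edge u -> v means v consumes a
#' file channel produced by u. The graph always admits a topological
#' order (cycles among job steps are rejected at resolve time).
#'
#' @param network A resolved network.
#' @return An \code{igraph} directed graph.
#' @export
build_dependency_graph <- function(network) {
  stopifnot(inherits(network, "fbp_network"))
  jobs <- job_step_names(network)
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(jobs)
  if (!is.null(network$dep_edges) && nrow(network$dep_edges)) {
    g <- g + igraph::edges(as.vector(t(network$dep_edges)))
  }
  g
}

# Topological order of job steps with declaration-order tie-break (Kahn).
topo_order_jobs <- function(network) {
  jobs <- job_step_names(network)
  if (!length(jobs)) return(character())
  edges <- network$dep_edges
  indeg <- stats::setNames(integer(length(jobs)), jobs)
  succ <- stats::setNames(vector("list", length(jobs)), jobs)
  if (!is.null(edges) && nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      u <- edges[r, 1]; v <- edges[r, 2]
      indeg[[v]] <- indeg[[v]] + 1L
      succ[[u]] <- c(succ[[u]], v)
    }
  }
  order <- character()
  avail <- jobs[indeg[jobs] == 0L]
  while (length(avail)) {
    u <- avail[[1]]   # jobs is in declaration order, so this tie-breaks by it
    avail <- setdiff(avail, u)
    order <- c(order, u)
    for (v in succ[[u]]) {
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) avail <- c(avail, v)
    }
    avail <- jobs[jobs %in% avail]
  }
  if (length(order) != length(jobs)) {
    fbp_error("fbp_cycle_job_step", "cycle among job steps")
  }
  order
}

#' @export
print.fbp_network <- function(x, ...) {
  cat(sprintf("<fbp network %s: %d process(es), %d channel(s), %s>\n",
              x$program$module_name, length(x$specs), length(x$channels),
              if (x$cyclic) "cyclic" else "acyclic"))
  invisible(x)
}
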