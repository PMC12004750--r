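# Runtime engine: launch FBP processes simultaneously, run job steps per
# the chosen scheduler, track per-task life-cycle state on disk, support
# stop and imperative invocation.
#
# Life-cycle states and legal transitions:
#   pending -> in_progress -> completed | failed
#   any state -> stopped (via stop_run)
# Every transition is appended to __exec__/<process>.log so a crashed
# engine (or an independent R session) can recover statuses from disk.

STATUSES <- c("pending", "in_progress", "completed", "failed", "stopped")

status_log_path <- function(root, process) {
  file.path(exec_dir(root), paste0(process, ".log"))
}

append_status <- function(root, process, task, status, exit = "-") {
  line <- sprintf("%.3f\t%d\t%s\t%s", as.numeric(Sys.time()), task, status, exit)
  cat(line, "\n", sep = "", file = status_log_path(root, process), append = TRUE)
}

append_event <- function(root, ...) {
  cat(paste(..., sep = "\t"), "\n", sep = "",
      file = file.path(exec_dir(root), "events.log"), append = TRUE)
}

# Full per-task transition history, in append order.
status_history <- function(root, process) {
  lines <- read_lines_if_exists(status_log_path(root, process))
  if (!length(lines)) {
    return(data.frame(time = numeric(), task = integer(), status = character(),
                      exit = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    time = as.numeric(vapply(parts, `[[`, "", 1L)),
    task = as.integer(vapply(parts, `[[`, "", 2L)),
    status = vapply(parts, `[[`, "", 3L),
    exit = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

read_program_summary <- function(root) {
  p <- file.path(exec_dir(root), "program.json")
  if (!file.exists(p)) {
    fbp_error("fbp_not_a_run",
              sprintf("%s is not a program output directory", root))
  }
  jsonlite::read_json(p, simplifyVector = FALSE)
}

#' Query the execution status of a run
#'
#' Read-only: reflects the last persisted life-cycle transition of every
#' process task, and can be called while a run is live or from a
#' different session.
#'
#' @param root Program output directory.
#' @return A data frame with columns \code{process}, \code{task},
#'   \code{status}, \code{exit_code}.
#' @export
network_status <- function(root) {
  summ <- read_program_summary(root)
  rows <- list()
  for (p in summ$processes) {
    hist <- status_history(root, p$name)
    for (t in seq_len(p$task_count)) {
      h <- hist[hist$task == t, , drop = FALSE]
      if (nrow(h)) {
        last <- h[nrow(h), ]
        rows[[length(rows) + 1L]] <- data.frame(
          process = p$name, task = t, status = last$status,
          exit_code = last$exit, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          process = p$name, task = t, status = "pending", exit_code = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(process = character(), task = integer(),
                      status = character(), exit_code = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# ---- wrapper generation -----------------------------------------------

# Shell helper prepended to generated sh bodies so they can read their
# option values positionally ("$@" holds the resolved option list).
SH_OPT_HELPER <- paste(
  "opt() {",
  "  k=\"$1\"; shift",
  "  while [ \"$#\" -ge 2 ]; do",
  "    if [ \"$1\" = \"$k\" ]; then printf '%s\\n' \"$2\"; return 0; fi",
  "    shift 2",
  "  done",
  "  return 1",
  "}",
  sep = "\n")

resolved_args <- function(network, root, process, task, instrument = FALSE) {
  entries <- network$bindings[[process]][[task]]
  out <- character()
  for (e in entries) {
    val <- switch(e$type,
      literal = e$value,
      relpath = file.path(root, e$rel),
      chan_w = chan_write_path(root, network$channels[[e$channel]], instrument),
      chan_r = chan_read_path(root, network$channels[[e$channel]]),
      fbp_error("fbp_internal", "unresolved binding"))
    out <- c(out, e$token, val)
  }
  out
}

body_script_path <- function(root, process) {
  file.path(exec_dir(root), "scripts", paste0(process, ".body"))
}

# Write the body source (inline scripts) once per process; byte-exact.
write_body_script <- function(spec, root) {
  if (spec$body$form == "inline_script") {
    path <- body_script_path(root, spec$name)
    preamble <- if (spec$body$interpreter %in% c("sh", "bash", "dash")) {
      SH_OPT_HELPER
    } else {
      character()
    }
    writeLines(c(preamble, spec$body$text), path, sep = "\n")
    path
  } else {
    NULL
  }
}

body_command <- function(spec, root, argv) {
  argstr <- if (length(argv)) paste(vapply(argv, shquote, ""), collapse = " ") else ""
  switch(spec$body$form,
    command_text = paste(spec$body$text, argstr),
    inline_script = paste(spec$body$interpreter,
                          shquote(body_script_path(root, spec$name)), argstr),
    fbp_error("fbp_invalid_body",
              sprintf("process %s: native_callable bodies can only be run via invoke_inline",
                      spec$name)))
}

task_suffix <- function(spec, task) {
  if (spec$task_count > 1L) sprintf("_%04d", task) else ""
}

make_wrapper <- function(network, root, process, task, instrument = FALSE) {
  spec <- network_spec(network, process)
  argv <- resolved_args(network, root, process, task, instrument)
  sfx <- task_suffix(spec, task)
  outp <- file.path(root, process, paste0("stdout", sfx))
  errp <- file.path(root, process, paste0("stderr", sfx))
  logp <- status_log_path(root, process)
  pidp <- file.path(exec_dir(root), "pids", sprintf("%s.%d.pid", process, task))
  donep <- file.path(exec_dir(root), "done", sprintf("%s.%d", process, task))
  cmd <- body_command(spec, root, argv)
  script <- file.path(exec_dir(root), "scripts",
                      sprintf("run_%s%s.sh", process, sfx))
  lines <- c(
    "#!/bin/sh",
    sprintf("echo $$ > %s", shquote(pidp)),
    sprintf("export FBPR_ROOT=%s FBPR_PROCESS=%s FBPR_TASK=%d",
            shquote(root), shquote(process), task),
    sprintf("printf '%%s\\t%d\\tin_progress\\t-\\n' \"$(date +%%s.%%N)\" >> %s",
            task, shquote(logp)),
    sprintf("%s > %s 2> %s", cmd, shquote(outp), shquote(errp)),
    "rc=$?",
    "if [ $rc -eq 0 ]; then st=completed; else st=failed; fi",
    sprintf("printf '%%s\\t%d\\t%%s\\t%%s\\n' \"$(date +%%s.%%N)\" \"$st\" \"$rc\" >> %s",
            task, shquote(logp)),
    sprintf("echo $rc > %s", shquote(donep))
  )
  writeLines(lines, script)
  script
}

persist_program_summary <- function(network, root) {
  summ <- list(
    module = network$program$module_name,
    cyclic = network$cyclic,
    processes = lapply(names(network$specs), function(nm) {
      s <- network$specs[[nm]]
      list(name = nm, exec_class = s$exec_class, task_count = s$task_count)
    })
  )
  jsonlite::write_json(summ, file.path(exec_dir(root), "program.json"),
                       auto_unbox = TRUE)
}

# Save the complete resolved option list per process (one line per task),
# which also serves as the resume fingerprint.
persist_opt_lists <- function(network, root, instrument = FALSE) {
  for (nm in names(network$specs)) {
    lines <- vapply(seq_len(network$specs[[nm]]$task_count), function(t) {
      paste(resolved_args(network, root, nm, t, instrument), collapse = "\t")
    }, "")
    writeLines(lines, file.path(exec_dir(root), paste0(nm, ".opts")))
  }
}

opts_unchanged <- function(network, root, process, instrument = FALSE) {
  path <- file.path(exec_dir(root), paste0(process, ".opts"))
  if (!file.exists(path)) return(FALSE)
  old <- readLines(path, warn = FALSE)
  new <- vapply(seq_len(network$specs[[process]]$task_count), function(t) {
    paste(resolved_args(network, root, process, t, instrument), collapse = "\t")
  }, "")
  identical(old, new)
}

# ---- capacity ----------------------------------------------------------

#' Local execution capacity
#'
#' @param cpus CPU slots; defaults to the detected core count.
#' @param mem_mb Memory budget in megabytes.
#' @return A \code{local_capacity} object.
#' @export
local_capacity <- function(cpus = NULL, mem_mb = 4096) {
  if (is.null(cpus)) {
    cpus <- tryCatch(parallel::detectCores(), error = function(e) 2L)
    if (is.na(cpus)) cpus <- 2L
  }
  structure(list(cpus = as.numeric(cpus), mem_mb = as.numeric(mem_mb)),
            class = "fbp_capacity")
}

# ---- execution ---------------------------------------------------------

file_channel_producers <- function(network) {
  # consumer process -> character vector of producer processes (file channels)
  out <- list()
  for (ch in network$channels) {
    if (ch$medium != "file" || ch$producer$kind != "process_port") next
    for (cons in ch$consumers) {
      if (cons$kind != "process_port") next
      out[[cons$process]] <- union(out[[cons$process]], ch$producer$process)
    }
  }
  out
}

transitive_dependents <- function(network, roots) {
  edges <- network$dep_edges
  prods <- file_channel_producers(network)
  # invert: producer -> consumers
  succ <- list()
  for (cons in names(prods)) {
    for (p in prods[[cons]]) succ[[p]] <- union(succ[[p]], cons)
  }
  seen <- character()
  frontier <- roots
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(p) succ[[p]])))
    nxt <- setdiff(nxt, c(seen, roots))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Execute a resolved network
#'
#' Materializes the output tree, writes both DOT graphs, spawns every FBP
#' process before any job step begins, runs job steps under the selected
#' scheduler, and persists every life-cycle transition under
#' \code{__exec__}.
#'
#' With \code{scheduler = "dynamic"} job steps are activated reactively:
#' a task starts only after all its file-channel producers have
#' completed, bounded by \code{capacity}. With \code{scheduler =
#' "static"} the network must consist of job steps only; the dependency
#' graph is compiled into a submission plan (one array job per process)
#' and submitted in a single pass to \code{backend} (the built-in local
#' allocator by default, or a recording mock).
#'
#' Resume semantics: a process whose tasks all completed in a previous
#' run and whose resolved option list is unchanged is skipped; changed
#' options reset it to pending.
#'
#' @param network A resolved network.
#' @param root Output directory.
#' @param scheduler \code{"dynamic"} or \code{"static"}.
#' @param backend A batch backend (static scheduling only); see
#'   \code{\link{mock_backend}}.
#' @param capacity A \code{\link{local_capacity}}.
#' @param wait Block until the run finishes? With \code{FALSE} the
#'   processes are left running (stop them with \code{\link{stop_run}}).
#' @param timeout Overall wall-clock limit in seconds; on expiry the run
#'   is stopped and reported \code{stopped}.
#' @param deadlock_timeout Seconds without any observable progress after
#'   which a live cyclic (or partially failed) network is diagnosed as
#'   deadlocked and failed.
#' @param instrument Instrument internal stream channels (see
#'   \code{\link{materialize}}).
#' @return A run report (\code{fbp_run_report}).
#' @export
execute <- function(network, root,
                    scheduler = c("dynamic", "static"),
                    backend = NULL,
                    capacity = local_capacity(),
                    wait = TRUE,
                    timeout = 600,
                    deadlock_timeout = getOption("fbpr.deadlock_timeout", 30),
                    instrument = FALSE) {
  stopifnot(inherits(network, "fbp_network"))
  scheduler <- match.arg(scheduler)
  fbp <- fbp_process_names(network)
  jobs <- job_step_names(network)

  if (scheduler == "static" && length(fbp)) {
    fbp_error("fbp_static_fbp",
              sprintf("static scheduling covers job steps only; FBP process(es): %s",
                      paste(fbp, collapse = ", ")))
  }

  # Resume: completed processes with unchanged option lists are skipped.
  skip <- character()
  if (dir.exists(exec_dir(root))) {
    for (nm in names(network$specs)) {
      hist <- status_history(root, nm)
      n <- network$specs[[nm]]$task_count
      done_ok <- all(vapply(seq_len(n), function(t) {
        h <- hist[hist$task == t, , drop = FALSE]
        nrow(h) > 0 && h$status[nrow(h)] == "completed"
      }, TRUE))
      if (done_ok && opts_unchanged(network, root, nm, instrument)) {
        skip <- c(skip, nm)
      }
    }
    # Stream-connected FBP processes form one concurrent pipeline and can
    # only resume as a unit: if any member of a weakly-connected stream
    # component must re-run, the whole component re-runs.
    if (length(skip)) {
      for (cmp in stream_components(network)) {
        if (any(!cmp %in% skip)) skip <- setdiff(skip, cmp)
      }
    }
  }

  materialize(network, root, instrument = instrument)
  write_graphs(network, root)
  unlink(file.path(exec_dir(root), "stopflag"))
  persist_program_summary(network, root)

  active <- setdiff(names(network$specs), skip)
  # reset logs of active processes; keep completed (skipped) histories
  for (nm in active) {
    unlink(status_log_path(root, nm))
    unlink(file.path(exec_dir(root), "done",
                     sprintf("%s.%d", nm, seq_len(network$specs[[nm]]$task_count))))
  }
  persist_opt_lists(network, root, instrument)
  for (nm in active) {
    write_body_script(network$specs[[nm]], root)
    for (t in seq_len(network$specs[[nm]]$task_count)) {
      append_status(root, nm, t, "pending")
    }
  }

  if (scheduler == "static") {
    plan <- build_plan(network)
    write_plan(plan, root)
    if (is.null(backend)) {
      backend <- local_backend(network, root, capacity, skip = skip,
                               instrument = instrument)
    }
    submit_all(plan, backend)
    return(run_report(root))
  }

  # dynamic: relays first, then every FBP process, then reactive job steps
  relay_pids <- if (instrument) spawn_instrument_relays(network, root) else integer()
  if (length(relay_pids)) {
    writeLines(as.character(relay_pids),
               file.path(exec_dir(root), "pids", "relays.pid"))
  }
  for (nm in setdiff(fbp, skip)) {
    wrapper <- make_wrapper(network, root, nm, 1L, instrument)
    pid <- spawn_script(wrapper)
    append_event(root, "spawn", nm, 1L)
    if (is.na(pid)) {
      append_status(root, nm, 1L, "failed", "127")
      cat("127", file = file.path(exec_dir(root), "done", paste0(nm, ".1")))
    }
  }

  if (!wait) {
    return(invisible(structure(list(root = root, detached = TRUE),
                               class = "fbp_run_handle")))
  }
  run_loop(network, root, capacity, timeout, deadlock_timeout, instrument,
           skip = skip)
  run_report(root)
}

# Reactive wait loop: activates ready job-step tasks, serves computation
# requests from running processes, watches for deadlock and timeout.
run_loop <- function(network, root, capacity, timeout, deadlock_timeout,
                     instrument, skip = character()) {
  jobs <- setdiff(job_step_names(network), skip)
  prods <- file_channel_producers(network)
  done_dir <- file.path(exec_dir(root), "done")

  task_key <- function(p, t) sprintf("%s.%d", p, t)
  all_tasks <- list()
  for (nm in setdiff(names(network$specs), skip)) {
    for (t in seq_len(network$specs[[nm]]$task_count)) {
      all_tasks[[task_key(nm, t)]] <- list(process = nm, task = t)
    }
  }
  started <- character()   # keys of spawned tasks (fbp already spawned)
  for (nm in setdiff(fbp_process_names(network), skip)) {
    started <- c(started, task_key(nm, 1L))
  }
  cancelled <- character()
  running_jobs <- list()   # key -> resources

  process_completed <- function(nm) {
    if (nm %in% skip) return(TRUE)
    n <- network$specs[[nm]]$task_count
    all(file.exists(file.path(done_dir, task_key(nm, seq_len(n)))))  &&
      all(vapply(seq_len(n), function(t) {
        identical(readLines(file.path(done_dir, task_key(nm, t)), warn = FALSE)[1], "0")
      }, TRUE))
  }
  any_failed_tasks <- function() {
    fins <- list.files(done_dir)
    failed <- character()
    for (f in fins) {
      rc <- readLines(file.path(done_dir, f), warn = FALSE)[1]
      if (!identical(rc, "0")) {
        failed <- c(failed, sub("\\.[0-9]+$", "", f))
      }
    }
    unique(failed)
  }

  deadline <- Sys.time() + timeout
  last_progress <- Sys.time()
  last_sig <- ""

  repeat {
    if (file.exists(file.path(exec_dir(root), "stopflag"))) break

    done_files <- list.files(done_dir)
    # cancel transitive dependents of failures; independent branches go on
    failed_procs <- any_failed_tasks()
    if (length(failed_procs)) {
      deps <- transitive_dependents(network, failed_procs)
      for (d in setdiff(deps, c(cancelled, skip))) {
        for (t in seq_len(network$specs[[d]]$task_count)) {
          k <- task_key(d, t)
          if (!k %in% started) {
            append_status(root, d, t, "stopped")
            append_event(root, "cancel", d, t)
          }
        }
        cancelled <- c(cancelled, d)
      }
    }

    # reactive activation of ready job-step tasks under capacity
    ready <- list()
    for (nm in setdiff(jobs, cancelled)) {
      producers <- prods[[nm]] %||% character()
      if (!all(vapply(producers, process_completed, TRUE))) next
      for (t in seq_len(network$specs[[nm]]$task_count)) {
        k <- task_key(nm, t)
        if (k %in% started) next
        ready[[length(ready) + 1L]] <- list(
          id = k, process = nm, task = t,
          cpus = network$specs[[nm]]$resources$cpus,
          mem_mb = network$specs[[nm]]$resources$mem_mb)
      }
    }
    running_jobs <- running_jobs[!names(running_jobs) %in% done_files]
    used_cpus <- sum(vapply(running_jobs, function(r) r$cpus, 0))
    used_mem <- sum(vapply(running_jobs, function(r) r$mem_mb, 0))
    avail <- local_capacity(max(0, capacity$cpus - used_cpus),
                            max(0, capacity$mem_mb - used_mem))
    if (length(ready)) {
      sel <- allocate_local(ready, avail, total = capacity)
      for (task in attr(sel, "infeasible") %||% list()) {
        append_status(root, task$process, task$task, "failed", "oversize")
        cat("1", file = file.path(done_dir, task$id))
        started <- c(started, task$id)
      }
      for (task in sel) {
        wrapper <- make_wrapper(network, root, task$process, task$task, instrument)
        spawn_script(wrapper)
        append_event(root, "spawn", task$process, task$task)
        started <- c(started, task$id)
        running_jobs[[task$id]] <- list(cpus = task$cpus, mem_mb = task$mem_mb)
      }
    }

    serve_computation_requests(root, capacity)

    done_files <- list.files(done_dir)
    cancelled_keys <- unlist(lapply(cancelled, function(d) {
      task_key(d, seq_len(network$specs[[d]]$task_count))
    }))
    if (all(names(all_tasks) %in% c(done_files, cancelled_keys)) &&
        !computations_pending(root)) {
      break
    }

    # progress signature: completions plus bytes produced anywhere visible
    sig <- paste(length(done_files),
                 sum(file.size(list.files(root, recursive = TRUE,
                                          full.names = TRUE)) , na.rm = TRUE),
                 sep = ":")
    now <- Sys.time()
    if (!identical(sig, last_sig)) {
      last_sig <- sig
      last_progress <- now
    } else if (as.numeric(now - last_progress, units = "secs") > deadlock_timeout) {
      diag <- sprintf("no progress for %gs; diagnosing deadlock", deadlock_timeout)
      writeLines(diag, file.path(exec_dir(root), "deadlock"))
      stop_run(root, .mark = "failed")
      break
    }
    if (now > deadline) {
      stop_run(root)
      break
    }
    Sys.sleep(0.02)
  }
  invisible(NULL)
}

#' Stop a running program
#'
#' Terminates every live process tree of the run (grace period with
#' SIGTERM, then SIGKILL), persists \code{stopped} for every task not in
#' a terminal state, and removes the exposed FIFOs. Best-effort and
#' idempotent: stopping a finished run changes nothing.
#'
#' @param root Program output directory.
#' @param grace Seconds between SIGTERM and SIGKILL.
#' @param .mark Internal: status to record for interrupted tasks.
#' @return A run report.
#' @export
stop_run <- function(root, grace = 0.3, .mark = "stopped") {
  summ <- read_program_summary(root)
  file.create(file.path(exec_dir(root), "stopflag"))
  piddir <- file.path(exec_dir(root), "pids")
  pidfiles <- list.files(piddir, full.names = TRUE)
  pids <- suppressWarnings(as.integer(unlist(lapply(pidfiles, readLines, warn = FALSE))))
  pids <- pids[!is.na(pids)]
  live <- pids[vapply(pids, pid_alive, TRUE)]
  if (length(live)) {
    for (p in live) kill_group(p, "TERM")
    Sys.sleep(grace)
    for (p in live) if (pid_alive(p)) kill_group(p, "KILL")
  }
  # record interruption for every non-terminal task
  for (p in summ$processes) {
    hist <- status_history(root, p$name)
    for (t in seq_len(p$task_count)) {
      h <- hist[hist$task == t, , drop = FALSE]
      last <- if (nrow(h)) h$status[nrow(h)] else "pending"
      if (!last %in% c("completed", "failed", "stopped")) {
        append_status(root, p$name, t, .mark)
      }
    }
  }
  unlink(list.files(fifos_dir(root), full.names = TRUE))
  run_report(root)
}

run_report <- function(root) {
  states <- network_status(root)
  overall <- if (all(states$status == "completed")) {
    "completed"
  } else if (any(states$status == "failed")) {
    "failed"
  } else if (any(states$status == "stopped")) {
    "stopped"
  } else {
    "in_progress"
  }
  structure(list(root = root, states = states, overall = overall),
            class = "fbp_run_report")
}

#' @export
print.fbp_run_report <- function(x, ...) {
  cat(sprintf("<fbp run %s: %s>\n", x$root, x$overall))
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' Exit code of a run report
#'
#' 0 completed, 1 failed, 2 stopped (3 is reserved for usage errors).
#' @param report A run report.
#' @return Integer exit code.
#' @export
report_exit_code <- function(report) {
  switch(report$overall, completed = 0L, failed = 1L, stopped = 2L,
         in_progress = 0L, 1L)
}

#' Invoke a single process imperatively
#'
#' Runs the process body synchronously with the caller-supplied option
#' bindings, bypassing schedulers and channels. No execution state is
#' recorded: imperative calls are the caller's responsibility.
#'
#' @param network A resolved network (or any network containing the
#'   process; only the process spec is used).
#' @param process Process name.
#' @param args Character vector of option/value pairs; every required
#'   port of the process must be present.
#' @return List with \code{exit_code}, \code{stdout}, \code{stderr}.
#' @export
invoke_inline <- function(network, process, args = character()) {
  spec <- network_spec(network, process)
  for (port in spec$ports) {
    if (port$required && is_not_found(read_opt_value(args, port$option_token))) {
      fbp_error("fbp_unbound_input",
                sprintf("imperative call to %s: required option %s missing",
                        process, port$option_token))
    }
  }
  if (spec$body$form == "native_callable") {
    res <- spec$body$fun(args)
    return(list(exit_code = 0L, stdout = as.character(res), stderr = character()))
  }
  tmp <- tempfile("fbpr_inline_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  dir.create(file.path(tmp, "__exec__", "scripts"), recursive = TRUE)
  write_body_script(spec, tmp)
  cmd <- body_command(spec, tmp, args)
  outp <- file.path(tmp, "stdout"); errp <- file.path(tmp, "stderr")
  rc <- system2("sh", c("-c", shquote(sprintf("%s > %s 2> %s", cmd,
                                              shquote(outp), shquote(errp)))))
  list(exit_code = as.integer(rc),
       stdout = read_lines_if_exists(outp),
       stderr = read_lines_if_exists(errp))
}
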