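# Dynamic scheduler: reactive activation of job steps (the run_loop in
# engine.R) plus an API letting a running stateful process submit further
# computations at runtime. Requests are exchanged through plain files under
# __computations__/ so that a process body written in any language -- or an
# R body using this API directly -- can submit work that the engine's
# allocator executes, while the owner keeps its internal state and awaits
# the result.

requests_dir <- function(root) file.path(computations_dir(root), "requests")

next_owner_seq <- function(root, owner) {
  # one submitting owner process at a time per name; no lock needed
  seqfile <- file.path(computations_dir(root), paste0(owner, ".seq"))
  n <- if (file.exists(seqfile)) as.integer(readLines(seqfile, warn = FALSE)[1]) else 0L
  writeLines(as.character(n + 1L), seqfile)
  n + 1L
}

#' Run a network reactively
#'
#' Convenience wrapper for \code{\link{execute}} with the dynamic
#' scheduler: each job step starts only after all of its file-channel
#' producers completed; independent steps overlap up to the capacity
#' limit.
#'
#' @inheritParams execute
#' @param ... Passed on to \code{\link{execute}}.
#' @return A run report.
#' @export
run_reactive <- function(network, root, ...) {
  execute(network, root, scheduler = "dynamic", ...)
}

#' Submit a computation from a running stateful process
#'
#' Queues a shell command for execution by the engine's local allocator.
#' The owner keeps running (and keeps its internal state) and can await
#' the result; an arbitrary number of submissions is allowed. Each
#' computation runs under \code{__computations__/<owner>_<seq>/} with its
#' stdout, stderr and exit code captured.
#'
#' @param root Program output directory of the live run.
#' @param command Shell command text to execute.
#' @param cpus,mem_mb Resource demand. A demand exceeding the engine's
#'   total capacity fails the handle immediately.
#' @param owner Name of the submitting process (defaults to the
#'   \code{FBPR_PROCESS} environment variable set for process bodies).
#' @return A computation handle (serializable list).
#' @export
submit_computation <- function(root, command, cpus = 1, mem_mb = 128,
                               owner = Sys.getenv("FBPR_PROCESS", "external")) {
  if (file.exists(file.path(exec_dir(root), "stopflag"))) {
    fbp_error("fbp_stopped", "run has been stopped; submission rejected")
  }
  mkdirp(requests_dir(root))
  id <- sprintf("%s_%06d", owner, next_owner_seq(root, owner))
  req <- list(id = id, owner = owner, command = command,
              cpus = cpus, mem_mb = mem_mb)
  tmp <- file.path(requests_dir(root), paste0(id, ".tmp"))
  jsonlite::write_json(req, tmp, auto_unbox = TRUE)
  file.rename(tmp, file.path(requests_dir(root), paste0(id, ".json")))
  structure(list(id = id, root = root, owner = owner),
            class = "fbp_computation_handle")
}

computation_dir <- function(handle) {
  file.path(computations_dir(handle$root), handle$id)
}

#' @rdname submit_computation
#' @param handle A computation handle.
#' @export
computation_state <- function(handle) {
  stopifnot(inherits(handle, "fbp_computation_handle"))
  d <- computation_dir(handle)
  donef <- file.path(d, "done")
  if (file.exists(donef)) {
    rc <- readLines(donef, warn = FALSE)[1]
    if (identical(rc, "0")) "done" else "failed"
  } else if (dir.exists(d)) {
    "running"
  } else {
    "queued"
  }
}

#' @rdname submit_computation
#' @param timeout Seconds to wait for completion.
#' @return \code{await_computation} returns a list with \code{state},
#'   \code{exit_code} and the captured \code{stdout} lines.
#' @export
await_computation <- function(handle, timeout = 120) {
  ok <- wait_until(function() computation_state(handle) %in% c("done", "failed"),
                   timeout)
  state <- computation_state(handle)
  d <- computation_dir(handle)
  rc <- if (file.exists(file.path(d, "done"))) {
    as.integer(readLines(file.path(d, "done"), warn = FALSE)[1])
  } else {
    NA_integer_
  }
  list(state = if (ok) state else "running", exit_code = rc,
       stdout = read_lines_if_exists(file.path(d, "stdout")))
}

computations_pending <- function(root) {
  rd <- requests_dir(root)
  cd <- computations_dir(root)
  if (dir.exists(rd) && length(list.files(rd, pattern = "\\.json$"))) return(TRUE)
  if (!dir.exists(cd)) return(FALSE)
  dirs <- list.dirs(cd, recursive = FALSE)
  dirs <- dirs[basename(dirs) != "requests"]
  any(!file.exists(file.path(dirs, "done")))
}

# Engine-side server: pick up queued requests and run them under the
# allocator. Called from the reactive wait loop; also usable directly.
serve_computation_requests <- function(root, capacity) {
  rd <- requests_dir(root)
  if (!dir.exists(rd)) return(invisible(0L))
  reqs <- sort(list.files(rd, pattern = "\\.json$", full.names = TRUE))
  if (!length(reqs)) return(invisible(0L))
  cd <- computations_dir(root)
  mkdirp(file.path(exec_dir(root), "pids"))
  running <- Filter(function(d) {
    basename(d) != "requests" && !file.exists(file.path(d, "done"))
  }, list.dirs(cd, recursive = FALSE))
  used <- length(running)  # 1 cpu per running computation floor
  launched <- 0L
  for (rf in reqs) {
    req <- jsonlite::read_json(rf, simplifyVector = TRUE)
    if (req$cpus > capacity$cpus || req$mem_mb > capacity$mem_mb) {
      d <- mkdirp(file.path(cd, req$id))
      writeLines("resource demand exceeds capacity", file.path(d, "stderr"))
      writeLines("-1", file.path(d, "done"))
      unlink(rf)
      next
    }
    if (used + req$cpus > capacity$cpus) break
    d <- mkdirp(file.path(cd, req$id))
    script <- file.path(d, "run.sh")
    writeLines(c(
      "#!/bin/sh",
      sprintf("echo $$ > %s", shquote(file.path(exec_dir(root), "pids",
                                                paste0("comp_", req$id, ".pid")))),
      sprintf("{ %s ; } > %s 2> %s", req$command,
              shquote(file.path(d, "stdout")), shquote(file.path(d, "stderr"))),
      sprintf("echo $? > %s", shquote(file.path(d, "done")))
    ), script)
    unlink(rf)
    spawn_script(script)
    used <- used + req$cpus
    launched <- launched + 1L
  }
  invisible(launched)
}

#' Serve queued computations until none remain
#'
#' Standalone driver for the computation queue, useful when no engine
#' wait loop is running (e.g. stress tests or externally submitted
#' work).
#'
#' @param root Program output directory.
#' @param capacity A \code{\link{local_capacity}}.
#' @param timeout Seconds before giving up.
#' @return Invisibly, TRUE when the queue drained.
#' @export
drain_computations <- function(root, capacity = local_capacity(),
                               timeout = 120) {
  ok <- wait_until(function() {
    serve_computation_requests(root, capacity)
    !computations_pending(root)
  }, timeout, interval = 0.03)
  invisible(ok)
}
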