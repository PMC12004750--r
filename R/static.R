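# Static scheduler: compile the job-step dependency graph into a minimal
# submission plan -- exactly one array job per process template, regardless
# of array size -- and submit every job in a single pass with pre-resolved
# afterok dependencies. This single-pass submission is the mechanism behind
# near-zero engine resource consumption: after submit_all returns, the
# engine performs no scheduling work until completion callbacks.

#' Build a submission plan from a resolved network
#'
#' One job per job-step process template (the array size is the task
#' count); plan order is a topological order of the dependency graph with
#' declaration order as tie-break; \code{depends_on} edges equal the
#' dependency-graph edges. Deterministic.
#'
#' @param network A resolved network consisting of job steps only.
#' @return An \code{fbp_submission_plan}.
#' @export
build_plan <- function(network) {
  stopifnot(inherits(network, "fbp_network"))
  fbp <- fbp_process_names(network)
  if (length(fbp)) {
    fbp_error("fbp_static_fbp",
              sprintf("static plans cover job steps only; FBP process(es): %s",
                      paste(fbp, collapse = ", ")))
  }
  order <- topo_order_jobs(network)
  edges <- network$dep_edges
  jobs <- lapply(order, function(nm) {
    spec <- network$specs[[nm]]
    deps <- character()
    if (!is.null(edges) && nrow(edges)) {
      deps <- unique(edges[edges[, 2] == nm, 1])
      deps <- order[order %in% deps]   # deterministic order
    }
    list(job_key = nm, array_size = spec$task_count,
         resources = spec$resources, depends_on = deps,
         dependency_type = "afterok")
  })
  structure(list(jobs = jobs), class = "fbp_submission_plan")
}

#' Write the plan dump under the output tree
#'
#' A stable structured-text file \code{__exec__/plan} listing jobs, array
#' sizes, resources and dependency edges.
#'
#' @param plan A submission plan.
#' @param root Output directory.
#' @return Invisibly, the plan file path.
#' @export
write_plan <- function(plan, root) {
  mkdirp(exec_dir(root))
  lines <- c("# fbpr submission plan v1")
  for (j in plan$jobs) {
    lines <- c(lines, sprintf(
      "job %s array=%d cpus=%g mem_mb=%g time_min=%g depends=%s",
      j$job_key, j$array_size, j$resources$cpus, j$resources$mem_mb,
      j$resources$time_min,
      if (length(j$depends_on)) {
        paste(paste0(j$depends_on, ":", j$dependency_type), collapse = ",")
      } else ""))
  }
  path <- file.path(exec_dir(root), "plan")
  writeLines(lines, path)
  invisible(path)
}

read_plan <- function(root) {
  readLines(file.path(exec_dir(root), "plan"), warn = FALSE)
}

#' Submit every job of a plan in one pass
#'
#' Each submission carries its already-resolved dependency ids
#' (afterok). If the backend rejects a job, previously submitted jobs
#' are cancelled and the error is re-raised.
#'
#' @param plan A submission plan.
#' @param backend A batch backend: a list with \code{submit(job)},
#'   \code{cancel(id)}, \code{poll(id)}.
#' @return Named character vector mapping job keys to backend ids.
#' @export
submit_all <- function(plan, backend) {
  stopifnot(inherits(plan, "fbp_submission_plan"))
  ids <- character()
  for (j in plan$jobs) {
    j$depends_on_ids <- unname(ids[j$depends_on])
    id <- tryCatch(backend$submit(j), error = function(e) e)
    if (inherits(id, "error")) {
      for (done in rev(ids)) backend$cancel(done)
      fbp_error("fbp_backend_rejection",
                sprintf("backend rejected job %s: %s; %d prior submission(s) cancelled",
                        j$job_key, conditionMessage(id), length(ids)))
    }
    ids[[j$job_key]] <- id
  }
  ids
}

#' Recording mock batch backend
#'
#' Logs every call (submit with its dependency list, cancel, poll) and
#' completes jobs immediately. Backend ids are sequential integers as
#' strings, for reproducible assertions. Jobs whose key is listed in
#' \code{fail_jobs} are rejected at submission.
#'
#' @param fail_jobs Job keys to reject.
#' @return A backend object; inspect its calls with
#'   \code{\link{backend_log}}.
#' @export
mock_backend <- function(fail_jobs = character()) {
  env <- new.env(parent = emptyenv())
  env$log <- list()
  env$next_id <- 1L
  record <- function(entry) env$log[[length(env$log) + 1L]] <- entry
  backend <- list(
    kind = "mock",
    env = env,
    submit = function(job) {
      if (job$job_key %in% fail_jobs) {
        stop(sprintf("job %s rejected by mock backend", job$job_key))
      }
      id <- as.character(env$next_id)
      env$next_id <- env$next_id + 1L
      record(list(op = "submit", job_key = job$job_key, id = id,
                  array_size = job$array_size,
                  depends_on_ids = job$depends_on_ids,
                  dependency_type = job$dependency_type))
      id
    },
    cancel = function(id) record(list(op = "cancel", id = id)),
    poll = function(id) {
      record(list(op = "poll", id = id))
      "done"
    }
  )
  class(backend) <- "fbp_backend"
  backend
}

#' @rdname mock_backend
#' @param backend A mock backend.
#' @export
backend_log <- function(backend) backend$env$log

# Built-in local backend: submitting a job executes its array tasks under
# the capacity-bounded allocator. Because submit_all submits in
# topological order and each job runs to completion inside submit, the
# pre-resolved afterok dependencies are honoured.
local_backend <- function(network, root, capacity, skip = character(),
                          instrument = FALSE) {
  env <- new.env(parent = emptyenv())
  env$log <- list()
  env$next_id <- 1L
  backend <- list(
    kind = "local",
    env = env,
    submit = function(job) {
      id <- as.character(env$next_id)
      env$next_id <- env$next_id + 1L
      env$log[[length(env$log) + 1L]] <-
        list(op = "submit", job_key = job$job_key, id = id,
             array_size = job$array_size, depends_on_ids = job$depends_on_ids)
      if (!job$job_key %in% skip) {
        run_array_local(network, root, job$job_key, capacity, instrument)
      }
      id
    },
    cancel = function(id) invisible(NULL),
    poll = function(id) "done"
  )
  class(backend) <- "fbp_backend"
  backend
}

run_array_local <- function(network, root, process, capacity, instrument = FALSE) {
  spec <- network_spec(network, process)
  done_dir <- file.path(exec_dir(root), "done")
  pending <- lapply(seq_len(spec$task_count), function(t) {
    list(id = sprintf("%s.%d", process, t), process = process, task = t,
         cpus = spec$resources$cpus, mem_mb = spec$resources$mem_mb)
  })
  running <- list()
  while (length(pending) || length(running)) {
    done <- list.files(done_dir)
    running <- running[!names(running) %in% done]
    used_cpus <- sum(vapply(running, function(r) r$cpus, 0))
    used_mem <- sum(vapply(running, function(r) r$mem_mb, 0))
    avail <- local_capacity(max(0, capacity$cpus - used_cpus),
                            max(0, capacity$mem_mb - used_mem))
    sel <- allocate_local(pending, avail, total = capacity)
    for (task in attr(sel, "infeasible") %||% list()) {
      append_status(root, task$process, task$task, "failed", "oversize")
      cat("1", file = file.path(done_dir, task$id))
      pending <- Filter(function(x) x$id != task$id, pending)
    }
    for (task in sel) {
      wrapper <- make_wrapper(network, root, task$process, task$task, instrument)
      spawn_script(wrapper)
      append_event(root, "spawn", task$process, task$task)
      running[[task$id]] <- list(cpus = task$cpus, mem_mb = task$mem_mb)
      pending <- Filter(function(x) x$id != task$id, pending)
    }
    if (length(running)) Sys.sleep(0.01)
  }
  invisible(NULL)
}

#' Capacity-bounded local allocation (knapsack heuristic)
#'
#' Selects a feasible subset of the pending tasks: greedy in input order
#' with first-fit on the two-dimensional (cpus, mem_mb) constraint. The
#' selection is maximal: no unselected feasible task fits in the
#' remaining capacity. Tasks whose single-task demand exceeds the total
#' capacity are returned in the \code{"infeasible"} attribute so the
#' caller can fail them immediately. Deterministic given identical input
#' order.
#'
#' @param pending List of tasks, each with \code{cpus} and \code{mem_mb}
#'   (and arbitrary identifying fields).
#' @param capacity A \code{\link{local_capacity}}; selected demands never
#'   exceed it.
#' @param total The total machine capacity used for the infeasibility
#'   check (defaults to \code{capacity}; pass it separately when
#'   \code{capacity} is the remaining headroom of a partially loaded
#'   machine).
#' @return The selected subset (a list), with attribute
#'   \code{"infeasible"}.
#' @export
allocate_local <- function(pending, capacity, total = capacity) {
  sel <- list()
  infeasible <- list()
  cpus_left <- capacity$cpus
  mem_left <- capacity$mem_mb
  for (task in pending) {
    if (task$cpus > total$cpus || task$mem_mb > total$mem_mb) {
      infeasible[[length(infeasible) + 1L]] <- task
      next
    }
    if (task$cpus <= cpus_left && task$mem_mb <= mem_left) {
      sel[[length(sel) + 1L]] <- task
      cpus_left <- cpus_left - task$cpus
      mem_left <- mem_left - task$mem_mb
    }
  }
  attr(sel, "infeasible") <- infeasible
  sel
}
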