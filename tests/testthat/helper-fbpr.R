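# Shared test helpers: temporary run roots, FIFO writers that cannot hang
# the test process, and status-log legality checks.

local_run_root <- function(env = parent.frame()) {
  root <- tempfile("fbpr_test_")
  withr::defer({
    try(suppressWarnings(stop_run(root)), silent = TRUE)
    unlink(root, recursive = TRUE)
  }, envir = env)
  root
}

# Write one line to a FIFO from a subprocess with a hard timeout, so a
# missing reader can never hang the suite. Returns TRUE on delivery.
fifo_write <- function(path, value, timeout = 10) {
  rc <- system(sprintf("timeout %d sh -c 'echo %s > %s'",
                       as.integer(timeout), shQuote(as.character(value)),
                       shQuote(path)))
  rc == 0L
}

# Read all lines from a FIFO via a subprocess with a timeout.
fifo_read_all <- function(path, timeout = 10) {
  out <- tempfile()
  system(sprintf("timeout %d sh -c 'cat %s > %s'", as.integer(timeout),
                 shQuote(path), shQuote(out)))
  if (file.exists(out)) readLines(out, warn = FALSE) else character()
}

# Spawn a shell loop in its own session; returns the PID. Killed via defer.
bg_shell <- function(script_text, env = parent.frame()) {
  script <- tempfile(fileext = ".sh")
  writeLines(script_text, script)
  pid <- fbpr:::spawn_script(script)
  withr::defer(fbpr:::kill_group(pid, "KILL"), envir = env)
  pid
}

wait_for <- function(predicate, timeout = 15, interval = 0.05) {
  fbpr:::wait_until(predicate, timeout, interval)
}

# Every task's transition sequence must be legal: ranks never decrease,
# at most one terminal state, and in_progress only after pending.
status_rank <- c(pending = 1L, in_progress = 2L,
                 completed = 3L, failed = 3L, stopped = 3L)

expect_legal_history <- function(root, process) {
  hist <- fbpr:::status_history(root, process)
  for (t in unique(hist$task)) {
    seqs <- hist$status[hist$task == t]
    ranks <- status_rank[seqs]
    expect_false(anyNA(ranks), label = sprintf("%s/%d unknown status", process, t))
    expect_true(all(diff(ranks) >= 0),
                label = sprintf("%s task %d went backwards: %s", process, t,
                                paste(seqs, collapse = " -> ")))
    expect_lte(sum(ranks == 3L), 1L)
  }
  invisible(hist)
}

# Brute-force directed-cycle oracle on a small edge list (node names).
brute_force_cyclic <- function(edges) {
  if (!nrow(edges)) return(FALSE)
  succ <- split(edges[, 2], edges[, 1])
  nodes <- unique(c(edges[, 1], edges[, 2]))
  reach <- function(from, target, seen = character()) {
    if (from %in% seen) return(FALSE)
    for (nx in succ[[from]] %||% character()) {
      if (nx == target || reach(nx, target, c(seen, from))) return(TRUE)
    }
    FALSE
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  any(vapply(nodes, function(n) reach(n, n), TRUE))
}

# Exhaustive-enumeration oracle of all topological orders of a small DAG.
all_topo_orders <- function(nodes, edges) {
  res <- list()
  recurse <- function(order, remaining) {
    if (!length(remaining)) {
      res[[length(res) + 1L]] <<- order
      return(invisible(NULL))
    }
    for (n in remaining) {
      preds <- edges[edges[, 2] == n, 1]
      if (all(preds %in% order)) {
        recurse(c(order, n), setdiff(remaining, n))
      }
    }
  }
  recurse(character(), nodes)
  res
}

# Tiny two-process stream program used by generic engine tests.
two_proc_stream_program <- function(producer_lines = c("a", "b", "c")) {
  prog <- program_spec("pair")
  src <- process_spec("src", fbpr:::sh_body(paste(
    'out=$(opt -out "$@")',
    sprintf("{ %s; } > \"$out\"",
            paste(sprintf("echo %s", producer_lines), collapse = "; ")),
    sep = "\n")),
    ports = list(port_spec("-out", "stream")),
    connect = list())
  sink <- process_spec("sink", fbpr:::sh_body(paste(
    'in=$(opt -in "$@")',
    'cat "$in"',
    sep = "\n")),
    ports = list(port_spec("-in", "stream")),
    connect = list(opt_from_proc_out("-in", "src", "-out")))
  register_process(register_process(prog, src), sink)
}
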