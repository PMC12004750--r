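test_that("telegram runs all four processes concurrently to completion", {
  root <- local_run_root()
  inp <- withr::local_tempfile(lines = c("the quick brown fox",
                                         "jumps over the lazy dog"))
  net <- resolve(example_program("telegram"), c("-f", inp, "-l", "10"))
  rep <- execute(net, root, timeout = 30)
  expect_identical(rep$overall, "completed")
  expect_identical(nrow(rep$states), 4L)
  expect_true(all(rep$states$status == "completed"))
  expect_identical(readLines(file.path(root, "wseq", "result.txt")),
                   telegram_reflow(decompose_lines(readLines(inp)), 10))
  for (p in names(net$specs)) expect_legal_history(root, p)
})

test_that("an empty program reports completed with zero states", {
  root <- local_run_root()
  rep <- execute(resolve(program_spec("empty")), root, timeout = 10)
  expect_identical(rep$overall, "completed")
  expect_identical(nrow(rep$states), 0L)
})

test_that("status is read-only, live-queriable and requires a run tree", {
  expect_error(network_status(tempfile()), class = "fbp_not_a_run")
  root <- local_run_root()
  execute(resolve(example_program("stream_echo")), root, wait = FALSE)
  expect_true(wait_for(function() {
    any(network_status(root)$status == "in_progress")
  }))
  st <- network_status(root)
  expect_identical(st$process, "stream_echo")
  stop_run(root)
  expect_identical(network_status(root)$status, "stopped")
})

test_that("stop terminates live trees, is idempotent, and survives double stop", {
  root <- local_run_root()
  execute(resolve(example_program("stream_echo")), root, wait = FALSE)
  Sys.sleep(0.2)
  pidfile <- list.files(file.path(root, "__exec__", "pids"), full.names = TRUE)
  pid <- as.integer(readLines(pidfile[1], warn = FALSE)[1])
  r1 <- stop_run(root)
  expect_identical(r1$overall, "stopped")
  expect_true(wait_for(function() !fbpr:::pid_alive(pid), 10))
  expect_length(list.files(fbpr:::fifos_dir(root)), 0L)
  r2 <- stop_run(root)
  expect_identical(r1$states, r2$states)
})

test_that("a kill -9'd process body is recorded failed; dependents are cancelled", {
  root <- local_run_root()
  prog <- program_spec("faulty")
  slow <- process_spec("slow", fbpr:::sh_body(paste(
    'outf=$(opt -outf "$@")', "sleep 30", 'echo done > "$outf"', sep = "\n")),
    ports = list(port_spec("-outf", "path")))
  dep <- process_spec("dep", fbpr:::sh_body(paste(
    'inf=$(opt -inf "$@")', 'cat "$inf"', sep = "\n")),
    ports = list(port_spec("-inf", "path"), port_spec("-outf", "path")),
    connect = list(opt_from_proc_out("-inf", "slow", "-outf")))
  prog <- register_process(register_process(prog, slow), dep)
  net <- resolve(prog)
  # a watcher SIGKILLs the slow body (the wrapper's child) once it has a PID,
  # leaving the wrapper alive to record the failure
  pidfile <- file.path(root, "__exec__", "pids", "slow.1.pid")
  bg_shell(sprintf(paste(
    "while [ ! -s %s ]; do sleep 0.05; done",
    "sleep 0.3",
    "p=$(cat %s)",
    'pkill -KILL -P "$p"', sep = "\n"),
    shQuote(pidfile), shQuote(pidfile)))
  rep <- execute(net, root, timeout = 30, deadlock_timeout = 20)
  expect_identical(rep$overall, "failed")
  st <- rep$states
  expect_identical(st$status[st$process == "slow"], "failed")
  expect_identical(st$status[st$process == "dep"], "stopped")
})

test_that("imperative invocation runs bodies synchronously without state records", {
  net <- resolve(example_program("telegram"), c("-f", "x", "-l", "10"))
  inp <- withr::local_tempfile(lines = c("alpha beta", "gamma"))
  out <- withr::local_tempfile()
  res <- invoke_inline(net, "decomposer", c("-inf", inp, "-outf", out))
  expect_identical(res$exit_code, 0L)
  expect_identical(readLines(out), c("alpha", "beta", "gamma"))
  err <- tryCatch(invoke_inline(net, "decomposer", c("-inf", inp)),
                  error = function(e) e)
  expect_s3_class(err, "fbp_unbound_input")
  expect_match(conditionMessage(err), "-outf")
})

test_that("network and imperative executions of telegram are byte-identical", {
  root <- local_run_root()
  inp <- withr::local_tempfile(
    lines = c("lorem ipsum dolor sit amet", "consectetur adipiscing elit"))
  net <- resolve(example_program("telegram"), c("-f", inp, "-l", "14"))
  rep <- execute(net, root, timeout = 30)
  expect_identical(rep$overall, "completed")
  t1 <- tempfile(); t2 <- tempfile(); t3 <- tempfile(); t4 <- tempfile()
  withr::defer(unlink(c(t1, t2, t3, t4)))
  invoke_inline(net, "rseq", c("-f", inp, "-outf", t1))
  invoke_inline(net, "decomposer", c("-inf", t1, "-outf", t2))
  invoke_inline(net, "recomposer", c("-inf", t2, "-l", "14", "-outf", t3))
  invoke_inline(net, "wseq", c("-inf", t3, "-outf", t4))
  expect_identical(readLines(t4),
                   readLines(file.path(root, "wseq", "result.txt")))
})

test_that("completed runs resume as no-ops; changed options reset work", {
  root <- local_run_root()
  inp <- withr::local_tempfile(lines = "resume test words here")
  net <- resolve(example_program("telegram"), c("-f", inp, "-l", "8"))
  execute(net, root, timeout = 30)
  spawns <- function() {
    ev <- readLines(file.path(root, "__exec__", "events.log"), warn = FALSE)
    sum(grepl("^spawn", ev))
  }
  n1 <- spawns()
  rep2 <- execute(net, root, timeout = 30)
  expect_identical(rep2$overall, "completed")
  expect_identical(spawns(), n1)          # resume: no work performed
  # changed resolved options reset the affected processes to run again
  net3 <- resolve(example_program("telegram"), c("-f", inp, "-l", "12"))
  rep3 <- execute(net3, root, timeout = 30)
  expect_identical(rep3$overall, "completed")
  expect_gt(spawns(), n1)
  expect_identical(readLines(file.path(root, "wseq", "result.txt")),
                   telegram_reflow(decompose_lines(readLines(inp)), 12))
})

test_that("cyclic networks that starve are failed with a deadlock diagnosis", {
  root <- local_run_root()
  prog <- program_spec("deadlock_demo")
  mk <- function(name, other) {
    process_spec(name, fbpr:::sh_body(paste(
      'in=$(opt -in "$@")', 'out=$(opt -out "$@")',
      'exec 3< "$in"',      # both sides open read first: guaranteed starvation
      'exec 4> "$out"', sep = "\n")),
      ports = list(port_spec("-in", "stream"), port_spec("-out", "stream")),
      connect = list(opt_from_proc_out("-in", other, "-out")))
  }
  prog <- register_process(prog, mk("proc_a", "proc_b"))
  prog <- register_process(prog, mk("proc_b", "proc_a"))
  net <- resolve(prog)
  expect_true(net$cyclic)
  rep <- execute(net, root, timeout = 60, deadlock_timeout = 2)
  expect_identical(rep$overall, "failed")
  expect_true(file.exists(file.path(root, "__exec__", "deadlock")))
})

test_that("run reports map to the documented exit codes", {
  expect_identical(report_exit_code(structure(list(overall = "completed"),
                                             class = "fbp_run_report")), 0L)
  expect_identical(report_exit_code(structure(list(overall = "failed"),
                                             class = "fbp_run_report")), 1L)
  expect_identical(report_exit_code(structure(list(overall = "stopped"),
                                             class = "fbp_run_report")), 2L)
})
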