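test_that("plan size is invariant in the array size: always one job per template", {
  for (n in c(1L, 10L, 100L)) {
    plan <- build_plan(resolve(build_host_workflow(n)))
    expect_length(plan$jobs, 2L)
    expect_identical(plan$jobs[[1]]$job_key, "host1")
    expect_identical(plan$jobs[[1]]$array_size, n)
    expect_identical(plan$jobs[[2]]$depends_on, "host1")
    expect_identical(plan$jobs[[2]]$dependency_type, "afterok")
  }
  p1 <- build_plan(resolve(build_host_process(1L)))
  expect_length(p1$jobs, 1L)
  expect_length(p1$jobs[[1]]$depends_on, 0L)
})

test_that("plans order jobs topologically and mirror the dependency graph", {
  # diamond A->{B,C}->D
  mk <- function(name, producers, extra_port = FALSE) {
    ports <- list(port_spec("-outf", "path"))
    conn <- list()
    if (length(producers) >= 1) {
      ports <- c(list(port_spec("-inf", "path", required = FALSE)), ports)
      conn <- c(conn, list(opt_from_proc_out("-inf", producers[1], "-outf")))
    }
    if (length(producers) >= 2) {
      ports <- c(list(port_spec("-inf2", "path", required = FALSE)), ports)
      conn <- c(conn, list(opt_from_proc_out("-inf2", producers[2], "-outf")))
    }
    process_spec(name, fbpr:::sh_body("true"), ports = ports, connect = conn)
  }
  prog <- program_spec("diamond")
  for (spec in list(mk("D0", character()), mk("B", "D0"), mk("C", "D0"),
                    mk("D", c("B", "C")))) {
    prog <- register_process(prog, spec)
  }
  plan <- build_plan(resolve(prog))
  keys <- vapply(plan$jobs, function(j) j$job_key, "")
  expect_length(keys, 4L)
  expect_identical(keys[1], "D0")
  expect_identical(keys[4], "D")
  deps <- lapply(plan$jobs, function(j) j$depends_on)
  names(deps) <- keys
  expect_identical(deps$B, "D0")
  expect_identical(deps$C, "D0")
  expect_setequal(deps$D, c("B", "C"))
  # FBP processes are rejected from static plans
  expect_error(build_plan(resolve(example_program("counter"), c("-inn", "1"))),
               class = "fbp_static_fbp")
})

test_that("submit_all is a single pass carrying pre-resolved dependency ids", {
  plan <- build_plan(resolve(build_host_workflow(100L)))
  b <- mock_backend()
  ids <- submit_all(plan, b)
  log <- backend_log(b)
  expect_length(log, 2L)                      # exactly 2 submissions
  expect_identical(log[[1]]$op, "submit")
  expect_identical(log[[2]]$depends_on_ids, log[[1]]$id)
  expect_equal(sum(vapply(log, function(e) e$array_size, 0)), 200)
  expect_identical(unname(ids), c("1", "2"))
  # empty plan: zero submit calls
  b2 <- mock_backend()
  submit_all(build_plan(resolve(program_spec("empty"))), b2)
  expect_length(backend_log(b2), 0L)
})

test_that("a backend rejection aborts the plan and cancels prior submissions", {
  prog <- program_spec("chain")
  mk <- function(name, prev) {
    ports <- list(port_spec("-outf", "path"))
    conn <- list()
    if (nzchar(prev)) {
      ports <- c(list(port_spec("-inf", "path", required = FALSE)), ports)
      conn <- list(opt_from_proc_out("-inf", prev, "-outf"))
    }
    process_spec(name, fbpr:::sh_body("true"), ports = ports, connect = conn)
  }
  prog <- register_process(prog, mk("j1", ""))
  prog <- register_process(prog, mk("j2", "j1"))
  prog <- register_process(prog, mk("j3", "j2"))
  plan <- build_plan(resolve(prog))
  b <- mock_backend(fail_jobs = "j2")
  expect_error(submit_all(plan, b), class = "fbp_backend_rejection")
  log <- backend_log(b)
  ops <- vapply(log, function(e) e$op, "")
  expect_identical(ops, c("submit", "cancel"))  # j1 submitted then cancelled
  expect_identical(log[[2]]$id, log[[1]]$id)
})

test_that("engine quiescence: no scheduler activity after the submission pass", {
  root <- local_run_root()
  net <- resolve(build_host_workflow(50L))
  b <- mock_backend()
  execute(net, root, scheduler = "static", backend = b, timeout = 30)
  log <- backend_log(b)
  expect_length(log, 2L)
  expect_true(all(vapply(log, function(e) e$op, "") == "submit"))
  expect_identical(sum(vapply(log, function(e) e$op == "poll", TRUE)), 0L)
  # plan dump is the stable acceptance surface
  plan_lines <- readLines(file.path(root, "__exec__", "plan"))
  expect_length(grep("^job ", plan_lines), 2L)
  expect_match(plan_lines[grep("^job host2", plan_lines)], "depends=host1:afterok")
})

test_that("static local execution honours dependencies and matches reactive runs", {
  root_s <- local_run_root()
  root_d <- local_run_root()
  rep_s <- execute(resolve(build_host_workflow(4L)), root_s,
                   scheduler = "static", timeout = 60)
  rep_d <- execute(resolve(build_host_workflow(4L)), root_d,
                   scheduler = "dynamic", timeout = 60)
  expect_identical(rep_s$overall, "completed")
  expect_identical(rep_d$overall, "completed")
  arts <- function(root) {
    fs <- sort(list.files(root, pattern = "^host[12]_.*\\.txt$",
                          recursive = TRUE))
    stats::setNames(lapply(file.path(root, fs), readLines), fs)
  }
  expect_identical(arts(root_s), arts(root_d))
  # every host2 task started after host1 completed (afterok soundness)
  h1 <- fbpr:::status_history(root_s, "host1")
  h2 <- fbpr:::status_history(root_s, "host2")
  expect_gte(min(h2$time[h2$status == "in_progress"]),
             max(h1$time[h1$status == "completed"]))
  # static scheduling refuses FBP processes
  expect_error(execute(resolve(example_program("stream_echo")), tempfile(),
                       scheduler = "static"),
               class = "fbp_static_fbp")
})

test_that("the local allocator is feasible, maximal, deterministic and close to optimal", {
  cap <- local_capacity(3, 4096)
  tasks <- list(list(id = "a", cpus = 2, mem_mb = 1024),
                list(id = "b", cpus = 1, mem_mb = 3072),
                list(id = "c", cpus = 1, mem_mb = 1024))
  sel <- allocate_local(tasks, cap)
  ids <- vapply(sel, function(t) t$id, "")
  expect_identical(ids, c("a", "b"))   # first-fit: a+b exactly fill (3cpu, 4GB)
  # trivial greedy by order
  t3 <- lapply(1:3, function(i) list(id = i, cpus = 1, mem_mb = 1))
  expect_length(allocate_local(t3, local_capacity(2, 10)), 2L)
  expect_length(allocate_local(list(), cap), 0L)
  # oversize demand flagged infeasible immediately
  big <- allocate_local(list(list(id = "x", cpus = 99, mem_mb = 1)), cap)
  expect_length(big, 0L)
  expect_length(attr(big, "infeasible"), 1L)

  # randomized instances vs an exhaustive subset oracle (n <= 12)
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    tasks <- lapply(seq_len(n), function(i) {
      list(id = i, cpus = sample(1:4, 1), mem_mb = sample(c(256, 512, 1024, 2048), 1))
    })
    cap <- local_capacity(sample(2:6, 1), sample(c(1024, 2048, 4096), 1))
    sel <- allocate_local(tasks, cap)
    used_c <- sum(vapply(sel, function(t) t$cpus, 0))
    used_m <- sum(vapply(sel, function(t) t$mem_mb, 0))
    expect_lte(used_c, cap$cpus)
    expect_lte(used_m, cap$mem_mb)
    # maximality: no unselected feasible task still fits
    sel_ids <- vapply(sel, function(t) t$id, 0)
    for (t in tasks) {
      if (t$id %in% sel_ids) next
      if (t$cpus > cap$cpus || t$mem_mb > cap$mem_mb) next
      expect_false(t$cpus <= cap$cpus - used_c && t$mem_mb <= cap$mem_mb - used_m)
    }
    # exhaustive oracle: maximum feasible subset size bounds the greedy count
    best <- 0L
    for (mask in 0:(2^n - 1)) {
      sub <- tasks[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      if (sum(vapply(sub, function(t) t$cpus, 0)) <= cap$cpus &&
          sum(vapply(sub, function(t) t$mem_mb, 0)) <= cap$mem_mb) {
        best <- max(best, length(sub))
      }
    }
    expect_lte(length(sel), best)
    expect_gte(length(sel), 1L * (best > 0))
    # determinism
    expect_identical(allocate_local(tasks, cap), sel)
  }
})
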