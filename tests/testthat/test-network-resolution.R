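telegram_net <- function() {
  resolve(example_program("telegram"), c("-f", "input.txt", "-l", "10"))
}

test_that("telegram resolves to a 4-process chain of 3 stream channels", {
  net <- telegram_net()
  expect_length(net$specs, 4L)
  streams <- Filter(function(ch) ch$medium == "stream", net$channels)
  expect_length(streams, 3L)
  expect_false(net$cyclic)
  chain <- vapply(streams, function(ch) {
    paste(ch$producer$process, ch$consumers[[1]]$process, sep = ">")
  }, "")
  expect_setequal(chain, c("rseq>decomposer", "decomposer>recomposer",
                           "recomposer>wseq"))
  # all processes stream-connected are FBP processes
  expect_setequal(fbpr:::fbp_process_names(net),
                  c("rseq", "decomposer", "recomposer", "wseq"))
})

test_that("connection errors are specific: direction, unknown names, double binds", {
  base <- function() {
    prog <- program_spec("m")
    a <- process_spec("a", fbpr:::sh_body("true"),
                      ports = list(port_spec("-out", "stream")))
    prog <- register_process(prog, a)
    prog
  }
  mk_b <- function(connect) {
    process_spec("b", fbpr:::sh_body("true"),
                 ports = list(port_spec("-in", "stream"),
                              port_spec("-in2", "stream", required = FALSE)),
                 connect = connect)
  }
  # input-to-input connection
  expect_error(
    resolve(register_process(base(), mk_b(list(opt_from_proc_out("-in", "b", "-in2"))))),
    class = "fbp_direction_mismatch")
  # unknown producer process
  expect_error(
    resolve(register_process(base(), mk_b(list(opt_from_proc_out("-in", "zz", "-out"))))),
    class = "fbp_unknown_process")
  # unknown producer port
  expect_error(
    resolve(register_process(base(), mk_b(list(opt_from_proc_out("-in", "a", "-outx"))))),
    class = "fbp_unknown_port")
  # single-producer rule: one input bound twice
  expect_error(
    resolve(register_process(base(), mk_b(list(
      opt_from_proc_out("-in", "a", "-out"),
      opt_from_proc_out("-in", "a", "-out"))))),
    class = "fbp_port_already_bound")
  # an output stream consumed twice
  prog <- base()
  prog <- register_process(prog, mk_b(list(opt_from_proc_out("-in", "a", "-out"))))
  c_spec <- process_spec("c", fbpr:::sh_body("true"),
                         ports = list(port_spec("-in", "stream")),
                         connect = list(opt_from_proc_out("-in", "a", "-out")))
  expect_error(resolve(register_process(prog, c_spec)),
               class = "fbp_port_already_bound")
})

test_that("cyclic networks are detected and job steps may not cycle", {
  mw <- resolve(example_program("master_worker"),
                c("-invalue", "0", "-inn", "10", "-inthreshold", "5"))
  expect_true(mw$cyclic)
  expect_length(mw$channels, 2L)

  # job steps in a file-channel cycle are rejected
  prog <- program_spec("jcycle")
  a <- process_spec("a", fbpr:::sh_body("true"),
                    ports = list(port_spec("-inf", "path", required = FALSE),
                                 port_spec("-outf", "path")),
                    connect = list(opt_from_proc_out("-inf", "b", "-outf")))
  b <- process_spec("b", fbpr:::sh_body("true"),
                    ports = list(port_spec("-inf", "path", required = FALSE),
                                 port_spec("-outf", "path")),
                    connect = list(opt_from_proc_out("-inf", "a", "-outf")))
  expect_error(resolve(register_process(register_process(prog, a), b)),
               class = "fbp_cycle_job_step")
})

test_that("cyclicity agrees with a brute-force oracle on random small networks", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    nodes <- sprintf("p%d", seq_len(n))
    # random partial port matching: each node has one optional stream input
    # and one stream output consumed at most once
    producer_of <- sample(c(NA_integer_, seq_len(n)), n, replace = TRUE)
    used <- logical(n)
    for (i in seq_len(n)) {       # enforce single consumer per output
      j <- producer_of[i]
      if (!is.na(j) && used[j]) producer_of[i] <- NA_integer_
      if (!is.na(producer_of[i])) used[producer_of[i]] <- TRUE
    }
    prog <- program_spec("rand")
    for (i in seq_len(n)) {
      conn <- list()
      if (!is.na(producer_of[i])) {
        conn <- list(opt_from_proc_out("-in", nodes[producer_of[i]], "-out"))
      }
      prog <- register_process(prog, process_spec(
        nodes[i], fbpr:::sh_body("true"),
        ports = list(port_spec("-in", "stream", required = FALSE),
                     port_spec("-out", "stream", required = FALSE)),
        connect = conn))
    }
    net <- resolve(prog)
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (is.na(producer_of[i])) NULL else cbind(nodes[producer_of[i]], nodes[i])
    }))
    if (is.null(edges)) edges <- matrix(character(), ncol = 2)
    expect_identical(net$cyclic, brute_force_cyclic(edges),
                     label = sprintf("rep %d", rep))
  }
})

test_that("FIFO exposure derives conventional names and rejects collisions", {
  trig <- resolve(example_program("master_worker_trigger"), c("-inn", "10"))
  ext <- vapply(Filter(function(ch) !fbpr:::is_internal_channel(ch),
                       fbpr:::stream_channels(trig)),
                function(ch) ch$fifo_basename, "")
  expect_setequal(ext, c("master_trigger", "worker_threshold"))
  cnt <- resolve(example_program("counter"), c("-inn", "3"))
  expect_true("counter_out" %in% vapply(fbpr:::stream_channels(cnt),
                                        function(ch) ch$fifo_basename, ""))
  echo <- resolve(example_program("stream_echo"))
  expect_true("stream_echo_in" %in% vapply(fbpr:::stream_channels(echo),
                                           function(ch) ch$fifo_basename, ""))
  # collision: two ports deriving the same basename
  prog <- register_process(program_spec("m"), process_spec(
    "p", fbpr:::sh_body("true"),
    ports = list(port_spec("-inx", "stream"), port_spec("-x", "stream")),
    connect = list(opt_fifo("-inx"), opt_fifo("-x"))))
  expect_error(resolve(prog), class = "fbp_fifo_collision")
})

test_that("missing or unknown command-line options fail fast with names", {
  err <- tryCatch(resolve(example_program("telegram"), c("-l", "10")),
                  error = function(e) e)
  expect_s3_class(err, "fbp_unbound_input")
  expect_match(conditionMessage(err), "rseq/-f")
  expect_error(resolve(example_program("telegram"),
                       c("-f", "x", "-l", "10", "--bogus", "1")),
               class = "fbp_unknown_option")
  expect_error(resolve(example_program("telegram"), c("-f")),
               class = "fbp_malformed_args")
})

test_that("dependency graph edges and topological orders match the oracle", {
  hw <- resolve(build_host_workflow(5))
  g <- build_dependency_graph(hw)
  expect_identical(sort(igraph::V(g)$name), c("host1", "host2"))
  expect_identical(igraph::as_edgelist(g), matrix(c("host1", "host2"), ncol = 2))

  # single process: one node, no edges
  hp <- resolve(build_host_process(3))
  g1 <- build_dependency_graph(hp)
  expect_equal(igraph::vcount(g1), 1)
  expect_equal(igraph::ecount(g1), 0)

  # diamond A->B, A->C, B->D, C->D against the enumeration oracle
  mk <- function(name, producers) {
    conn <- lapply(producers, function(p) opt_from_proc_out("-inf", p, "-outf"))
    ports <- list(port_spec("-outf", "path"))
    if (length(producers)) {
      ports <- c(list(port_spec("-inf", "path", required = FALSE)), ports)
    }
    process_spec(name, fbpr:::sh_body("true"), ports = ports,
                 connect = if (length(conn) > 1) conn[1] else conn)
  }
  # note: -inf can only bind once; D consumes B via -inf and C via -inf2
  prog <- program_spec("diamond")
  prog <- register_process(prog, mk("A", character()))
  prog <- register_process(prog, mk("B", "A"))
  prog <- register_process(prog, mk("C", "A"))
  d <- process_spec("D", fbpr:::sh_body("true"),
                    ports = list(port_spec("-inf", "path", required = FALSE),
                                 port_spec("-inf2", "path", required = FALSE),
                                 port_spec("-outf", "path")),
                    connect = list(opt_from_proc_out("-inf", "B", "-outf"),
                                   opt_from_proc_out("-inf2", "C", "-outf")))
  prog <- register_process(prog, d)
  net <- resolve(prog)
  edges <- net$dep_edges
  expect_setequal(paste(edges[, 1], edges[, 2]),
                  c("A B", "A C", "B D", "C D"))
  orders <- all_topo_orders(c("A", "B", "C", "D"), edges)
  expect_length(orders, 2L)   # ABCD and ACBD
  for (o in orders) {
    expect_identical(o[1], "A")
    expect_identical(o[4], "D")
  }
  expect_true(paste(fbpr:::topo_order_jobs(net), collapse = "") %in%
                vapply(orders, paste, "", collapse = ""))
})

test_that("DOT export is byte-deterministic and structurally faithful", {
  n1 <- telegram_net()
  n2 <- telegram_net()
  expect_identical(export_graph(n1, "process"), export_graph(n2, "process"))
  dot <- export_graph(n1, "process")
  expect_identical(length(gregexpr("shape=box", dot)[[1]]), 4L)
  # empty program: header and footer only
  empty <- resolve(program_spec("empty"))
  lines <- strsplit(export_graph(empty, "process"), "\n")[[1]]
  expect_length(lines, 3L)
  # master-worker contains a 2-cycle
  mw <- resolve(example_program("master_worker"),
                c("-invalue", "0", "-inn", "1", "-inthreshold", "1"))
  dmw <- export_graph(mw, "process")
  expect_match(dmw, '"master" -> "worker"', fixed = TRUE)
  expect_match(dmw, '"worker" -> "master"', fixed = TRUE)
  # dependency DOT mirrors the dependency graph
  ddep <- export_graph(resolve(build_host_workflow(2)), "dependency")
  expect_match(ddep, '"host1" -> "host2"', fixed = TRUE)
})

test_that("reconfiguring one process's rule only changes incident channels", {
  prog1 <- example_program("telegram")
  chans <- function(p) {
    net <- suppressWarnings(resolve(p, c("-f", "x", "-l", "10")))
    vapply(net$channels, function(ch) {
      paste(ch$producer$process, ch$producer$external_name,
            ch$consumers[[1]]$process, ch$consumers[[1]]$external_name,
            ch$medium)
    }, "")
  }
  # replace wseq's connection rule: expose its input as an external FIFO
  prog2 <- example_program("telegram")
  idx <- which(fbpr:::process_names(prog2) == "wseq")
  prog2$processes[[idx]]$connect <- list(opt_fifo("-inf"),
                                         opt_file("-outf", "result.txt"))
  # recomposer's output now needs an external consumer too
  ridx <- which(fbpr:::process_names(prog2) == "recomposer")
  prog2$processes[[ridx]]$connect <-
    c(prog2$processes[[ridx]]$connect, list(opt_fifo("-outf")))
  c1 <- chans(prog1)
  c2 <- chans(prog2)
  not_incident <- function(x) !grepl("wseq|recomposer", x)
  expect_identical(c1[not_incident(c1)], c2[not_incident(c2)])
  expect_false(identical(c1, c2))
})
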