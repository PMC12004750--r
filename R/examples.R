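# Bundled example gallery: the programs used throughout the test suite.
# All bodies are POSIX sh inline scripts (the `opt` helper reading option
# values from "$@" is prepended automatically), except the dynamic
# master-worker variant whose worker is an Rscript body exercising the
# runtime computation-submission API.

#' Build a bundled example program
#'
#' Available examples:
#' \describe{
#'   \item{\code{telegram}}{four concurrently streaming processes
#'     (\code{rseq -> decomposer -> recomposer -> wseq}) reflowing a text
#'     file into lines of at most \code{-l} characters.}
#'   \item{\code{master_worker}}{a cyclic two-process network with a
#'     stateful worker (see \code{\link{master_worker_oracle}}).}
#'   \item{\code{master_worker_trigger}}{the interactive variant: the
#'     master's initial value arrives through the exposed FIFO
#'     \code{master_trigger} (one episode per write) and the worker reads
#'     its threshold from \code{worker_threshold} before every cycle.}
#'   \item{\code{master_worker_dynamic}}{the worker delegates each
#'     transformation to a runtime-submitted computation
#'     (\code{\link{submit_computation}}) while keeping its cumulative
#'     state in memory.}
#'   \item{\code{counter}}{one process counting 0..n to the exposed FIFO
#'     \code{counter_out}.}
#'   \item{\code{stream_echo}}{one process copying the exposed FIFO
#'     \code{stream_echo_in} to its standard output.}
#'   \item{\code{host_process}, \code{host_workflow}}{one- and two-step
#'     job-step arrays (each task runs \code{hostname}), the second step
#'     depending on the first; the static-scheduling benchmark shape.}
#' }
#'
#' @param name Example name.
#' @param n_tasks Array size for the host examples.
#' @return A \code{\link{program_spec}}.
#' @export
example_program <- function(name, n_tasks = 1L) {
  switch(name,
    telegram = telegram_program(),
    master_worker = master_worker_program(),
    master_worker_trigger = master_worker_trigger_program(),
    master_worker_dynamic = master_worker_dynamic_program(),
    counter = counter_program(),
    stream_echo = stream_echo_program(),
    host_process = build_host_process(n_tasks),
    host_workflow = build_host_workflow(n_tasks),
    fbp_error("fbp_unknown_example",
              sprintf("unknown example %s; available: %s", name,
                      paste(example_names(), collapse = ", "))))
}

#' @rdname example_program
#' @export
example_names <- function() {
  c("telegram", "master_worker", "master_worker_trigger",
    "master_worker_dynamic", "counter", "stream_echo",
    "host_process", "host_workflow")
}

# ---- Telegram ----------------------------------------------------------

telegram_program <- function() {
  prog <- program_spec("telegram")

  rseq <- process_spec("rseq", sh_body(paste(
    'f=$(opt -f "$@")',
    'outf=$(opt -outf "$@")',
    'cat "$f" > "$outf"',
    sep = "\n")),
    ports = list(
      port_spec("-f", "path", doc = "input text file", value_kind = "path"),
      port_spec("-outf", "stream", doc = "line stream")),
    connect = list(opt_cmdline("-f")))

  decomposer <- process_spec("decomposer", sh_body(paste(
    'inf=$(opt -inf "$@")',
    'outf=$(opt -outf "$@")',
    "awk '{for (i = 1; i <= NF; i++) print $i}' \"$inf\" > \"$outf\"",
    sep = "\n")),
    ports = list(
      port_spec("-inf", "stream", doc = "line stream"),
      port_spec("-outf", "stream", doc = "word stream")),
    connect = list(opt_from_proc_out("-inf", "rseq", "-outf")))

  recomposer <- process_spec("recomposer", sh_body(paste(
    'inf=$(opt -inf "$@")',
    'l=$(opt -l "$@")',
    'outf=$(opt -outf "$@")',
    'awk -v L="$l" \'',
    "{ w = $0",
    "  if (length(w) > L) exit 1",
    "  if (len == 0) { line = w; len = length(w) }",
    "  else if (len + 1 + length(w) <= L) { line = line \" \" w; len += 1 + length(w) }",
    "  else { print line; line = w; len = length(w) }",
    "}",
    "END { if (len > 0) print line }' \"$inf\" > \"$outf\"",
    sep = "\n")),
    ports = list(
      port_spec("-inf", "stream", doc = "word stream"),
      port_spec("-l", "value", doc = "maximum line length in characters",
                value_kind = "int"),
      port_spec("-outf", "stream", doc = "reflowed line stream")),
    connect = list(opt_from_proc_out("-inf", "decomposer", "-outf"),
                   opt_cmdline("-l")))

  wseq <- process_spec("wseq", sh_body(paste(
    'inf=$(opt -inf "$@")',
    'outf=$(opt -outf "$@")',
    'cat "$inf" > "$outf"',
    sep = "\n")),
    ports = list(
      port_spec("-inf", "stream", doc = "reflowed line stream"),
      port_spec("-outf", "path", doc = "result file", value_kind = "path")),
    connect = list(opt_from_proc_out("-inf", "recomposer", "-outf"),
                   opt_file("-outf", "result.txt")))

  prog <- register_process(prog, rseq)
  prog <- register_process(prog, decomposer)
  prog <- register_process(prog, recomposer)
  prog <- register_process(prog, wseq)
  prog <- document_option(prog, "rseq", "-f", "path", "input file to be processed")
  prog <- document_option(prog, "recomposer", "-l", "int",
                          "maximum line length in characters")
  prog
}

# ---- master-worker (cyclic, stateful) ---------------------------------

master_body <- function() sh_body(paste(
  'v=$(opt -invalue "$@")',
  'n=$(opt -inn "$@")',
  'in=$(opt -in "$@")',
  'out=$(opt -out "$@")',
  'exec 3> "$out"',
  'exec 4< "$in"',
  "cycles=0",
  "while :; do",
  "  printf '%s\\n' \"$v\" >&3",
  "  if ! read -r r <&4; then break; fi",
  "  cycles=$((cycles + 1))",
  '  if [ "$r" -gt "$n" ]; then break; fi',
  "  v=$r",
  "done",
  "exec 3>&-",
  "printf '%s %s\\n' \"$r\" \"$cycles\"",
  sep = "\n"))

worker_body <- function() sh_body(paste(
  't=$(opt -inthreshold "$@")',
  'in=$(opt -in "$@")',
  'out=$(opt -out "$@")',
  'exec 3< "$in"',
  'exec 4> "$out"',
  "cum=0",
  "while read -r v <&3; do",
  '  if [ "$cum" -le "$t" ]; then inc=1; else inc=2; fi',
  "  o=$((v + inc))",
  "  cum=$((cum + o))",
  "  printf '%s\\n' \"$o\" >&4",
  "done",
  "exec 4>&-",
  "printf '%s\\n' \"$cum\"",
  sep = "\n"))

master_worker_program <- function() {
  prog <- program_spec("master_worker")
  master <- process_spec("master", master_body(),
    ports = list(
      port_spec("-invalue", "value", doc = "initial value", value_kind = "int"),
      port_spec("-inn", "value", doc = "stop bound", value_kind = "int"),
      port_spec("-in", "stream", doc = "transformed values from worker"),
      port_spec("-out", "stream", doc = "values to worker")),
    connect = list(opt_cmdline("-invalue"), opt_cmdline("-inn"),
                   opt_from_proc_out("-in", "worker", "-out")))
  worker <- process_spec("worker", worker_body(),
    ports = list(
      port_spec("-inthreshold", "value", doc = "threshold", value_kind = "int"),
      port_spec("-in", "stream", doc = "values from master"),
      port_spec("-out", "stream", doc = "transformed values to master")),
    connect = list(opt_cmdline("-inthreshold"),
                   opt_from_proc_out("-in", "master", "-out")))
  prog <- register_process(prog, master)
  prog <- register_process(prog, worker)
  prog <- document_option(prog, "master", "-invalue", "int", "initial value")
  prog <- document_option(prog, "master", "-inn", "int",
                          "stop once the received value exceeds this")
  prog <- document_option(prog, "worker", "-inthreshold", "int",
                          "cumulative-value threshold switching +1 to +2")
  prog
}

# Interactive variant: the initial value arrives through the exposed FIFO
# master_trigger (one full episode per write) and the worker reads its
# threshold from worker_threshold before every cycle. Both processes run
# until the program is stopped; the worker prints the episode's cumulative
# value after each episode (the total resets per episode).
master_worker_trigger_program <- function() {
  prog <- program_spec("master_worker_trigger")
  master <- process_spec("master", sh_body(paste(
    'trig=$(opt -intrigger "$@")',
    'n=$(opt -inn "$@")',
    'in=$(opt -in "$@")',
    'out=$(opt -out "$@")',
    "while :; do",
    '  if ! read -r v < "$trig"; then continue; fi',
    '  [ -n "$v" ] || continue',
    '  exec 3> "$out"',
    '  exec 4< "$in"',
    "  while :; do",
    "    printf '%s\\n' \"$v\" >&3",
    "    if ! read -r r <&4; then break; fi",
    '    if [ "$r" -gt "$n" ]; then break; fi',
    "    v=$r",
    "  done",
    "  exec 3>&-",
    "  exec 4<&-",
    "done",
    sep = "\n")),
    ports = list(
      port_spec("-intrigger", "stream", doc = "episode trigger values"),
      port_spec("-inn", "value", doc = "stop bound", value_kind = "int"),
      port_spec("-in", "stream", doc = "transformed values from worker"),
      port_spec("-out", "stream", doc = "values to worker")),
    connect = list(opt_fifo("-intrigger", basename = "master_trigger"),
                   opt_cmdline("-inn"),
                   opt_from_proc_out("-in", "worker", "-out")))
  # Threshold protocol: keep the FIFO open and read one line per cycle;
  # on end-of-stream close and block reopening until the next writer
  # connects. One-shot writers (echo) pair 1:1 with cycles; a long-lived
  # writer (e.g. a bridged counter) is consumed line by line.
  worker <- process_spec("worker", sh_body(paste(
    'tf=$(opt -inthreshold "$@")',
    'in=$(opt -in "$@")',
    'out=$(opt -out "$@")',
    "tfopen=",
    "t_read() {",
    "  while :; do",
    '    if [ -z "$tfopen" ]; then exec 5< "$tf"; tfopen=1; fi',
    "    if read -r t <&5; then return 0; fi",
    "    exec 5<&-; tfopen=",
    "  done",
    "}",
    "while :; do",
    '  exec 3< "$in"',
    '  exec 4> "$out"',
    "  cum=0",
    "  got=0",
    "  while read -r v <&3; do",
    "    got=1",
    "    t_read",
    '    if [ "$cum" -le "$t" ]; then inc=1; else inc=2; fi',
    "    o=$((v + inc))",
    "    cum=$((cum + o))",
    "    printf '%s\\n' \"$o\" >&4",
    "  done",
    "  exec 3<&-",
    "  exec 4>&-",
    '  [ "$got" -eq 1 ] && printf \'%s\\n\' "$cum"',
    "done",
    sep = "\n")),
    ports = list(
      port_spec("-inthreshold", "stream", doc = "per-cycle threshold values"),
      port_spec("-in", "stream", doc = "values from master"),
      port_spec("-out", "stream", doc = "transformed values to master")),
    connect = list(opt_fifo("-inthreshold", basename = "worker_threshold"),
                   opt_from_proc_out("-in", "master", "-out")))
  prog <- register_process(prog, master)
  prog <- register_process(prog, worker)
  prog <- document_option(prog, "master", "-inn", "int",
                          "stop once the received value exceeds this")
  prog
}

# Dynamic-scheduling variant: the worker is an Rscript body that submits
# each transformation as a runtime computation served by the engine's
# allocator, keeping its cumulative state in an ordinary R variable.
master_worker_dynamic_program <- function() {
  prog <- program_spec("master_worker_dynamic")
  master <- process_spec("master", master_body(),
    ports = list(
      port_spec("-invalue", "value", doc = "initial value", value_kind = "int"),
      port_spec("-inn", "value", doc = "stop bound", value_kind = "int"),
      port_spec("-in", "stream", doc = "transformed values from worker"),
      port_spec("-out", "stream", doc = "values to worker")),
    connect = list(opt_cmdline("-invalue"), opt_cmdline("-inn"),
                   opt_from_proc_out("-in", "worker", "-out")))
  worker_r <- paste(
    "args <- commandArgs(trailingOnly = TRUE)",
    "opt <- function(k) args[[match(k, args) + 1L]]",
    "suppressMessages(library(fbpr))",
    "root <- Sys.getenv('FBPR_ROOT')",
    "threshold <- as.numeric(opt('-inthreshold'))",
    "inp <- file(opt('-in'), 'r')",
    "outp <- file(opt('-out'), 'w')",
    "cum <- 0",
    "repeat {",
    "  v <- readLines(inp, n = 1L)",
    "  if (!length(v)) break",
    "  v <- as.numeric(v)",
    "  inc <- if (cum <= threshold) 1 else 2",
    "  h <- submit_computation(root, sprintf('echo $((%d + %d))', v, inc))",
    "  res <- await_computation(h)",
    "  o <- as.numeric(res$stdout[[1]])",
    "  cum <- cum + o",
    "  writeLines(as.character(o), outp)",
    "  flush(outp)",
    "}",
    "close(inp); close(outp)",
    "cat(cum, sep = '\\n')",
    sep = "\n")
  worker <- process_spec("worker",
    body_spec(text = worker_r, form = "inline_script", interpreter = "Rscript"),
    ports = list(
      port_spec("-inthreshold", "value", doc = "threshold", value_kind = "int"),
      port_spec("-in", "stream", doc = "values from master"),
      port_spec("-out", "stream", doc = "transformed values to master")),
    connect = list(opt_cmdline("-inthreshold"),
                   opt_from_proc_out("-in", "master", "-out")))
  prog <- register_process(prog, master)
  prog <- register_process(prog, worker)
  prog <- document_option(prog, "master", "-invalue", "int", "initial value")
  prog <- document_option(prog, "master", "-inn", "int", "stop bound")
  prog <- document_option(prog, "worker", "-inthreshold", "int", "threshold")
  prog
}

# ---- counter / stream_echo (runtime piping) ---------------------------

counter_program <- function() {
  prog <- program_spec("counter")
  counter <- process_spec("counter", sh_body(paste(
    'n=$(opt -inn "$@")',
    'out=$(opt -out "$@")',
    'case "$n" in ""|-*) echo "counter: n must be >= 0" >&2; exit 1;; esac',
    "i=0",
    '{ while [ "$i" -le "$n" ]; do printf \'%s\\n\' "$i"; i=$((i + 1)); done; } > "$out"',
    sep = "\n")),
    ports = list(
      port_spec("-inn", "value", doc = "count upper bound (inclusive)",
                value_kind = "int"),
      port_spec("-out", "stream", doc = "count stream")),
    connect = list(opt_cmdline("-inn"), opt_fifo("-out")))
  prog <- register_process(prog, counter)
  document_option(prog, "counter", "-inn", "int", "count upper bound (inclusive)")
}

stream_echo_program <- function() {
  prog <- program_spec("stream_echo")
  echo <- process_spec("stream_echo", sh_body(paste(
    'in=$(opt -in "$@")',
    'cat "$in"',
    sep = "\n")),
    ports = list(port_spec("-in", "stream", doc = "stream to echo")),
    connect = list(opt_fifo("-in")))
  register_process(prog, echo)
}

# ---- host examples (static-scheduling benchmark shape) ----------------

host1_spec <- function(n_tasks) {
  process_spec("host1", sh_body(paste(
    'outf=$(opt -outf "$@")',
    'hostname > "$outf"',
    sep = "\n")),
    ports = list(port_spec("-outf", "path", doc = "hostname record",
                           value_kind = "path")),
    generate = function(t) {
      list(opt_file("-outf", sprintf("host1_%04d.txt", t)))
    },
    task_count = n_tasks, exec_class = "job_step")
}

#' @rdname example_program
#' @export
build_host_process <- function(n_tasks = 1L) {
  stopifnot(is_count(n_tasks))
  register_process(program_spec("host_process"), host1_spec(n_tasks))
}

#' @rdname example_program
#' @export
build_host_workflow <- function(n_tasks = 1L) {
  stopifnot(is_count(n_tasks))
  prog <- program_spec("host_workflow")
  prog <- register_process(prog, host1_spec(n_tasks))
  host2 <- process_spec("host2", sh_body(paste(
    'inf=$(opt -inf "$@")',
    'outf=$(opt -outf "$@")',
    'cat "$inf" > /dev/null || exit 1',
    'hostname > "$outf"',
    sep = "\n")),
    ports = list(
      port_spec("-inf", "path", doc = "upstream hostname record",
                value_kind = "path"),
      port_spec("-outf", "path", doc = "hostname record", value_kind = "path")),
    generate = function(t) {
      list(opt_from_proc_out("-inf", "host1", "-outf"),
           opt_file("-outf", sprintf("host2_%04d.txt", t)))
    },
    task_count = n_tasks, exec_class = "job_step")
  register_process(prog, host2)
}
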