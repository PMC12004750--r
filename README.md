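# fbpr

A flow-based programming (FBP) workflow engine for R. Programs are
networks of port-addressed processes that communicate over UNIX named
pipes (FIFOs) or regular files. Long-lived **stateful processes in
control of their own life cycle** make cyclic, interactive,
trigger-driven and runtime-piped workflows expressible — things the
standard acyclic-dataflow workflow managers cannot do — while a
**static scheduler** compiles acyclic job-step networks into minimal
array-job submission plans (one array job per process template,
submitted in a single pass with pre-resolved `afterok` dependencies)
for near-zero scheduling overhead at large task counts.

Who it is for: anyone orchestrating many command-line tasks —
bioinformatics pipelines being the motivating case — who needs cycles
with memory (optimization loops, convergence checks), live interaction
with a running workflow, or tens of thousands of small tasks submitted
as two jobs instead of twenty thousand.

## The model in brief

* A **port** is a command-option token; tokens starting with `-out` /
  `--out` are output ports, all others input ports.
* **FBP processes** all start with the program, hold state, and stream
  newline-delimited records through FIFOs; the network may contain
  cycles.
* **Job steps** are stateless, communicate through files, activate
  reactively when their producers complete, and may be arrays of
  `task_count` tasks.
* Each process owns its **connection rule** — directives saying where
  every option comes from (`opt_cmdline`, `opt_from_proc_out`,
  `opt_fifo`, `opt_file`, `opt_value`) — so rewiring a network means
  overriding one process's rule.
* `resolve()` compiles a program into a network (channels, cyclicity,
  dependency DAG); `execute()` runs it; `__fifos__/` under the output
  directory exposes every pipe for interaction and runtime piping.

## Worked example

The classic streaming text-reflow network: `rseq` reads a file line by
line, `decomposer` splits lines into words, `recomposer` greedily packs
words into lines of at most `-l` characters, `wseq` writes the result —
four processes running concurrently, connected by three FIFOs.

```r
library(fbpr)

writeLines(c("the quick brown fox", "jumps over the lazy dog"), "in.txt")
net <- resolve(example_program("telegram"), c("-f", "in.txt", "-l", "10"))
net
#> <fbp network telegram: 4 process(es), 3 channel(s), acyclic>

rep <- execute(net, "out")
rep
#> <fbp run out: completed>
#>     process task    status exit_code
#>        rseq    1 completed         0
#>  decomposer    1 completed         0
#>  recomposer    1 completed         0
#>        wseq    1 completed         0

readLines("out/wseq/result.txt")
#> [1] "the quick"  "brown fox"  "jumps over" "the lazy"   "dog"
```

Every line is at most 10 characters and maximal (the next word would
not fit); `telegram_reflow(decompose_lines(...), 10)` is the sequential
oracle the tests compare against.

A cyclic, stateful network — the master sends a value, the stateful
worker adds 1 or 2 depending on its running total versus a threshold
and sends it back, until the master receives a value above its bound:

```r
net <- resolve(example_program("master_worker"),
               c("-invalue", "0", "-inn", "10", "-inthreshold", "5"))
execute(net, "mw")
readLines("mw/worker/stdout")   # worker's cumulative total
#> [1] "38"
master_worker_oracle(0, 5, 10)$worker_cum
#> [1] 38
```

Static scheduling: a 10 000-task two-step workflow compiles to exactly
two array-job submissions, the second depending on the first:

```r
plan <- build_plan(resolve(build_host_workflow(10000)))
b <- mock_backend()
submit_all(plan, b)
length(backend_log(b))
#> [1] 2
```

## Command line

```sh
exec/fbpr exec telegram --outdir out -f in.txt -l 10
exec/fbpr status --outdir out --porcelain
exec/fbpr stop --outdir out
exec/fbpr graphs master_worker --outdir g -invalue 0 -inn 5 -inthreshold 2
```

`exec` writes the output tree (`<process>/`, `__exec__/`, `__fifos__/`,
`__graphs__/` with `process.dot` and `dependency.dot`). Exit codes: 0
completed, 1 failed, 2 stopped, 3 usage error.

Interact with a live run through its pipes — e.g. start
`master_worker_trigger` detached, then `echo 0 > out/__fifos__/master_trigger`
starts an episode and each `echo t > out/__fifos__/worker_threshold`
sets the threshold for exactly one cycle. `bridge()` connects the pipes
of two independently launched programs (runtime piping).

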