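---
title: "Flow-based workflows with stateful processes: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-based workflows with stateful processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbpr)
```

## The execution model

Most workflow managers follow the standard dataflow paradigm: stateless
steps arranged in a directed acyclic graph, each activated when its
input files exist. That model cannot express iteration with memory: a
step re-run in a loop starts from scratch every time, so cyclic
workflows, interactive parameter changes and incremental scheduling
decisions all require external state plumbing.

`fbpr` implements the flow-based programming (FBP) alternative. A
program is a network of *processes* addressed by *ports*. A port is a
command-option token; tokens beginning with `-out` or `--out` are output
ports, all others input ports. Two execution classes coexist:

* **FBP processes** start together when the program starts, control
  their own life cycle, and may hold arbitrary internal state. They
  exchange newline-delimited records over UNIX named pipes (FIFOs).
  Because each process decides when to read, write and terminate, the
  network graph may contain cycles.
* **Job steps** are stateless, communicate through regular files, are
  activated reactively once their producers complete, and may be
  *arrays*: one template expanded into `task_count` indexed tasks.

A process body is ordinary command text or an inline script with a
declared interpreter; the engine passes the resolved option list as
command arguments and the script source byte-exact (no escaping), so
bodies can be written in any language.

### Network resolution

Each process owns its connection rule -- a list of directives (or a
generator called once per array task) stating where each option comes
from: the command line (`opt_cmdline`), another process's output port
(`opt_from_proc_out`), an exposed FIFO (`opt_fifo`), an output file
(`opt_file`), or a literal (`opt_value`). Keeping connections a
property of the process (rather than a central wiring table) means a
network can be reconfigured by overriding a single process's rule; a
test asserts this locality property structurally.

`resolve()` drains every rule, enforces the single-producer rule (no
input port bound twice, no stream output consumed twice), binds
command-line values fail-fast (unknown tokens are errors), classifies
cyclicity by cycle detection over the channel graph, and derives the
job-step dependency DAG. Job steps may not sit on a cycle and may not
consume stream channels; both are resolve-time errors.

### Channels and the output tree

A run lives in one output directory: a subdirectory per process plus
`__exec__` (life-cycle logs, submission plan, event log), `__fifos__`
(every named pipe), and `__graphs__` (DOT exports of the process and
dependency graphs). Every pipe is created *before* any process is
spawned, which removes the FIFO open race. Exposed pipes are the
interactivity surface: an external writer can feed a running program
(`master_trigger`, `worker_threshold` in the bundled examples) and
`bridge()` connects the pipes of two independently launched programs at
runtime ("runtime piping").

FIFO basenames follow one fixed derivation: lowercase the option token,
strip leading dashes and a leading `in`/`out` prefix (plus separator);
when stripping would leave nothing, the dash-stripped token itself is
used. This reproduces the conventional names `counter_out`,
`stream_echo_in`, `master_trigger`, `worker_threshold`; collisions are
errors rather than silently suffixed.

### Interactive pipe semantics

Whether an interactive input pipe is one-shot or re-openable is not
fixed by the FBP model. `fbpr`'s bundled interactive example keeps the
pipe open, reads one record per cycle, and on end-of-stream closes and
blocks reopening until the next writer connects. The consequence is
exact pairing: a one-shot writer (`echo v > pipe`) feeds exactly one
cycle, while a long-lived writer (a bridged counter) is consumed one
record per cycle in order. This is what makes the interactivity tests
deterministic.

## Scheduling

**Static.** For pure job-step networks, `build_plan()` compiles the
dependency DAG into one array job per process template -- the plan size
is independent of the array size -- ordered topologically with
declaration order as the tie-break. `submit_all()` submits every job in
a single pass, each carrying its pre-resolved all-success (`afterok`)
dependency ids. After that pass the engine does nothing until
completion: the recording mock backend verifies zero further calls.
This single-pass property is the mechanism behind near-zero scheduler
resource consumption at large task counts.

**Dynamic.** The reactive scheduler activates each job-step task when
all its file-channel producers have completed, bounded by a local
capacity. Running stateful processes can additionally submit
computations at runtime (`submit_computation()`): requests are queued as
plain files under `__computations__/`, served by the engine's
allocator, and awaited by the owner while it keeps its in-memory state.
The request protocol is deliberately file-based so bodies in any
language can use it.

**Local allocation.** Choosing which pending tasks to start under a
(cpus, memory) capacity is a knapsack-type problem. The engine uses a
greedy first-fit heuristic in declaration order: deterministic, maximal
(no unselected feasible task fits in the remainder), and compared --
not asserted equal -- against an exhaustive-subset oracle in the tests.
Optimality is explicitly not a goal; predictability is.

## Life-cycle state

Every task moves `pending -> in_progress -> completed | failed`, with
`stopped` reachable from any non-terminal state via `stop_run()`. Every
transition is appended to a per-process log under `__exec__`, so a
crashed engine or a separate session recovers the truth from disk
(`network_status()` is read-only). A failed producer cancels its
transitive dependents; independent branches continue. Re-executing over
a finished tree skips processes whose resolved option lists are
unchanged -- at process granularity for job steps, and at
pipeline-component granularity for stream-connected FBP processes,
which must resume as a unit because they execute concurrently.

Cyclic networks can starve (for example when every process is blocked
on a pipe open). The engine runs a watchdog: if no completion and no
byte of observable output changes for `deadlock_timeout` seconds
(default 30), the run is failed with a deadlock diagnosis written under
`__exec__`. This is a liveness heuristic, not a proof of deadlock; the
interval trades detection latency against tolerance for genuinely slow
bodies.

## The example gallery and what green tests establish

The bundled examples are executable specifications, each paired with a
pure sequential oracle:

* `telegram` -- reflow text into lines of at most `-l` characters
  through four concurrently streaming processes; oracle
  `telegram_reflow()` + `decompose_lines()`.
* `master_worker` -- a two-process cycle with a stateful worker: +1
  while the worker's running total is at or below the threshold, else
  +2, until the master receives a value above its bound; oracle
  `master_worker_oracle()`. The engine is checked against the oracle on
  the exhaustive grid v0 in 0..3, threshold in 0..10, bound in 1..20
  (880 runs).
* `master_worker_trigger` -- the interactive variant (episodes started
  by FIFO writes, threshold read per cycle from a FIFO).
* `master_worker_dynamic` -- the worker delegates each transformation
  to a runtime-submitted computation while accumulating in memory.
* `counter` / `stream_echo` -- the runtime-piping pair.
* `host_process` / `host_workflow` -- one- and two-step job-step
  arrays, each task running `hostname`; the static-scheduling benchmark
  shape whose plan must always contain exactly two jobs.

These examples exercise every engine path but are deliberately small
and textual. Green tests establish the correctness of the coordination
machinery -- resolution, channel materialization, life-cycle tracking,
both schedulers, interactivity and runtime piping -- at desk scale.
They do not establish performance claims on real clusters: external
batch systems are represented by a recording mock behind the
`BatchBackend` contract, single-host pipes replace distributed
channels, and wall-clock comparisons against other workflow engines are
out of scope.

## Numerical and design choices

Several behaviours are fixed here because the FBP model alone does not
determine them:

* `read_opt_value()` returns the **first** occurrence of a duplicated
  option (shell-like precedence) and a distinguished `NOT_FOUND` value
  rather than an error for absent tokens.
* The worker's threshold comparison uses the cumulative value **before**
  adding the current result; the counter's range is **inclusive** of its
  bound; `decompose_lines()` collapses whitespace runs. The oracles and
  the engine bodies share these choices, so the equivalence tests are
  insensitive to the convention picked.
* The master-worker trigger variant resets the worker's running total
  at each episode, so every episode is independently checkable against
  the oracle; statefulness across submissions is demonstrated by the
  dynamic variant instead.
* Record framing is newline-delimited bytes; end-of-stream is pipe EOF
  (all writers closed), with no in-band sentinel.
* Eager connection rules (`connect`) are evaluated once per process;
  generator rules (`generate`) once per task index -- the chosen
  interpretation of the eager-versus-generator split, enabling
  per-task option lists for arrays.
* Array task indexing is 1-based in R idiom; file channels between
  equal-sized arrays pair task-wise, and a size-1 producer fans out to
  every consumer task. Other size combinations are errors.
* Pipes are created with owner-only permissions (override via
  `options(fbpr.fifo_mode = ...)`).
* Program definition files are versioned JSON; only declarative
  connection rules serialize (function rules and native R bodies are
  in-memory constructs and refuse serialization loudly).

## Known limitations

* Single-host channels only: no sockets, no distributed state.
* The detached (`wait = FALSE`) mode leaves scheduling of job steps to
  a subsequent blocking call; detached runs are meant for long-lived
  interactive FBP programs.
* The deadlock watchdog can mislabel a network whose every process is
  legitimately silent for longer than the timeout.
* `stop_run()` is best-effort: it signals recorded process groups and
  cannot reach processes that have re-parented outside them.
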