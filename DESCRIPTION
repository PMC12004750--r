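Package: fbpr
Title: Flow-Based Programming Workflow Engine with Stateful Processes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A workflow engine built on the flow-based programming (FBP)
    paradigm. Programs are networks of port-addressed processes that
    communicate over UNIX named pipes (FIFOs) or regular files. Long-lived
    stateful processes in control of their own life cycle enable cyclic,
    interactive, trigger-driven, and runtime-piped workflows; a static
    scheduler compiles acyclic job-step networks into minimal array-job
    submission plans (one array per process template), while a dynamic
    scheduler activates work reactively as inputs become available.
    Includes a command-line front end for executing programs, querying
    status, stopping runs, and exporting process and dependency graphs
    in DOT format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
OS_type: unix
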