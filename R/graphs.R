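# DOT export of the process and dependency graphs. Output is
# byte-deterministic for a given network: nodes follow declaration order,
# edges follow channel creation order, and the style table is fixed.

dot_style <- list(
  process_node = "shape=box, style=rounded",
  job_node     = "shape=box",
  external     = "shape=plaintext",
  stream_edge  = "style=solid",
  file_edge    = "style=dashed",
  dep_edge     = "style=solid"
)

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a network graph in DOT format
#'
#' Two graph kinds exist: \code{"process"} draws one node per process and
#' one edge per channel (labelled with the port tokens; stream channels
#' solid, file channels dashed; external endpoints as plaintext nodes),
#' and \code{"dependency"} mirrors \code{\link{build_dependency_graph}}.
#'
#' @param network A resolved network.
#' @param kind \code{"process"} or \code{"dependency"}.
#' @return A single string of DOT text.
#' @export
export_graph <- function(network, kind = c("process", "dependency")) {
  stopifnot(inherits(network, "fbp_network"))
  kind <- match.arg(kind)
  lines <- c(sprintf("digraph %s {", kind), "  rankdir=LR;")
  if (kind == "process") {
    for (nm in names(network$specs)) {
      style <- if (network$specs[[nm]]$exec_class == "fbp_process") {
        dot_style$process_node
      } else {
        dot_style$job_node
      }
      lines <- c(lines, sprintf("  %s [%s];", dot_quote(nm), style))
    }
    ext_seen <- character()
    for (ch in network$channels) {
      eps <- c(list(ch$producer), ch$consumers)
      for (e in eps) {
        if (e$kind == "external" && !e$external_name %in% ext_seen) {
          ext_seen <- c(ext_seen, e$external_name)
          lines <- c(lines, sprintf("  %s [%s, label=%s];",
                                    dot_quote(paste0("ext:", e$external_name)),
                                    dot_style$external,
                                    dot_quote(e$external_name)))
        }
      }
    }
    for (ch in network$channels) {
      src <- if (ch$producer$kind == "external") {
        paste0("ext:", ch$producer$external_name)
      } else {
        ch$producer$process
      }
      style <- if (ch$medium == "stream") dot_style$stream_edge else dot_style$file_edge
      for (cons in ch$consumers) {
        dst <- if (cons$kind == "external") {
          paste0("ext:", cons$external_name)
        } else {
          cons$process
        }
        lab <- paste0(
          if (ch$producer$kind == "process_port") ch$producer$option_token else "",
          " -> ",
          if (cons$kind == "process_port") cons$option_token else "")
        lines <- c(lines, sprintf("  %s -> %s [label=%s, %s];",
                                  dot_quote(src), dot_quote(dst),
                                  dot_quote(trimws(lab)), style))
      }
    }
  } else {
    jobs <- job_step_names(network)
    for (nm in jobs) {
      lines <- c(lines, sprintf("  %s [%s];", dot_quote(nm), dot_style$job_node))
    }
    if (!is.null(network$dep_edges) && nrow(network$dep_edges)) {
      for (r in seq_len(nrow(network$dep_edges))) {
        lines <- c(lines, sprintf("  %s -> %s [%s];",
                                  dot_quote(network$dep_edges[r, 1]),
                                  dot_quote(network$dep_edges[r, 2]),
                                  dot_style$dep_edge))
      }
    }
  }
  lines <- c(lines, "}")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write both DOT graphs under an output tree
#'
#' Writes \code{__graphs__/process.dot} and
#' \code{__graphs__/dependency.dot} under \code{root}.
#'
#' @param network A resolved network.
#' @param root Program output directory.
#' @return Invisibly, the two file paths.
#' @export
write_graphs <- function(network, root) {
  gdir <- mkdirp(file.path(root, "__graphs__"))
  paths <- c(file.path(gdir, "process.dot"), file.path(gdir, "dependency.dot"))
  writeLines(export_graph(network, "process"), paths[1], sep = "")
  writeLines(export_graph(network, "dependency"), paths[2], sep = "")
  invisible(paths)
}
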