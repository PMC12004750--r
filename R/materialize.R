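# Channel layer: materialize a resolved network on disk (output tree +
# FIFOs), expose FIFOs for external access, and bridge FIFOs across
# independently running programs.

exec_dir <- function(root) file.path(root, "__exec__")
fifos_dir <- function(root) file.path(root, "__fifos__")
graphs_dir <- function(root) file.path(root, "__graphs__")
computations_dir <- function(root) file.path(root, "__computations__")

#' Path of an exposed FIFO
#'
#' @param root Program output directory.
#' @param basename FIFO basename, e.g. \code{"counter_out"}.
#' @return The filesystem path under \code{__fifos__/}.
#' @export
fifo_path <- function(root, basename) file.path(fifos_dir(root), basename)

is_internal_channel <- function(ch) {
  ch$producer$kind == "process_port" &&
    all(vapply(ch$consumers, function(e) e$kind == "process_port", TRUE))
}

mkfifo_at <- function(path) {
  mode <- getOption("fbpr.fifo_mode", "600")  # owner-only by default
  if (file.exists(path)) unlink(path)
  rc <- system2("mkfifo", c("-m", mode, shquote(path)), stdout = FALSE,
                stderr = FALSE)
  if (rc != 0L) {
    fbp_error("fbp_materialize_error", sprintf("mkfifo failed for %s", path))
  }
  invisible(path)
}

# Producer- and consumer-side paths of a stream channel. Uninstrumented
# channels use one pipe; instrumented internal channels are split into a
# producer pipe (.w), a middle pipe (.m) and the canonical consumer pipe,
# with two tee relays logging every record that traverses the channel.
chan_write_path <- function(root, ch, instrument = FALSE) {
  base <- fifo_path(root, ch$fifo_basename)
  if (instrument && is_internal_channel(ch)) paste0(base, ".w") else base
}

chan_read_path <- function(root, ch) fifo_path(root, ch$fifo_basename)

#' Materialize a resolved network under an output directory
#'
#' Creates the output tree (one directory per process plus
#' \code{__exec__}, \code{__fifos__} and \code{__graphs__}) and one named
#' pipe per stream channel under \code{__fifos__/}. Every pipe exists
#' before any process is spawned, which prevents the FIFO open race.
#' Re-materializing over an existing tree from the same network removes
#' stale pipes and recreates them (idempotent).
#'
#' @param network A resolved network.
#' @param root Output directory (created if needed).
#' @param instrument Logical; when TRUE, internal stream channels are
#'   split through record-logging relays (used by the stream-conservation
#'   tests).
#' @return Invisibly, a list describing the output tree.
#' @export
materialize <- function(network, root, instrument = FALSE) {
  stopifnot(inherits(network, "fbp_network"))
  mkdirp(root)
  if (!dir.exists(root) || file.access(root, 2) != 0L) {
    fbp_error("fbp_materialize_error", sprintf("root %s is not writable", root))
  }
  for (nm in names(network$specs)) mkdirp(file.path(root, nm))
  mkdirp(exec_dir(root))
  mkdirp(file.path(exec_dir(root), "pids"))
  mkdirp(file.path(exec_dir(root), "done"))
  mkdirp(file.path(exec_dir(root), "scripts"))
  mkdirp(fifos_dir(root))
  mkdirp(graphs_dir(root))

  # stale pipes from a previous run are removed and recreated
  old <- list.files(fifos_dir(root), full.names = TRUE)
  unlink(old)

  for (ch in stream_channels(network)) {
    mkfifo_at(fifo_path(root, ch$fifo_basename))
    if (instrument && is_internal_channel(ch)) {
      mkfifo_at(paste0(fifo_path(root, ch$fifo_basename), ".w"))
      mkfifo_at(paste0(fifo_path(root, ch$fifo_basename), ".m"))
    }
  }
  invisible(list(
    root = root, exec_dir = exec_dir(root), fifos_dir = fifos_dir(root),
    graphs_dir = graphs_dir(root),
    process_dirs = file.path(root, names(network$specs))
  ))
}

# Spawn the tee relays of instrumented channels; returns PIDs.
spawn_instrument_relays <- function(network, root) {
  sdir <- mkdirp(file.path(exec_dir(root), "streams"))
  pids <- integer()
  for (ch in stream_channels(network)) {
    if (!is_internal_channel(ch)) next
    base <- ch$fifo_basename
    a <- paste0(fifo_path(root, base), ".w")
    b <- paste0(fifo_path(root, base), ".m")
    cc <- fifo_path(root, base)
    wlog <- file.path(sdir, paste0(base, ".wlog"))
    rlog <- file.path(sdir, paste0(base, ".rlog"))
    s1 <- file.path(exec_dir(root), "scripts", paste0("relay_w_", base, ".sh"))
    s2 <- file.path(exec_dir(root), "scripts", paste0("relay_r_", base, ".sh"))
    writeLines(sprintf("tee %s < %s > %s", shquote(wlog), shquote(a), shquote(b)), s1)
    writeLines(sprintf("tee %s < %s > %s", shquote(rlog), shquote(b), shquote(cc)), s2)
    pids <- c(pids, spawn_script(s1), spawn_script(s2))
  }
  pids
}

#' Open an exposed FIFO from outside the program
#'
#' Returns a connection on the named pipe, honouring OS pipe semantics:
#' opening for read blocks until a writer exists and vice versa, so call
#' this only when the counterpart process is (or will be) live, or from a
#' helper subprocess.
#'
#' @param root Program output directory.
#' @param fifo_basename Basename under \code{__fifos__/}.
#' @param mode \code{"read"} or \code{"write"}.
#' @return An open connection (close it with \code{close()}).
#' @export
open_external <- function(root, fifo_basename, mode = c("read", "write")) {
  mode <- match.arg(mode)
  path <- fifo_path(root, fifo_basename)
  if (!file.exists(path)) {
    avail <- sort(list.files(fifos_dir(root)))
    fbp_error("fbp_unknown_fifo",
              sprintf("no FIFO named %s; available: %s", fifo_basename,
                      if (length(avail)) paste(avail, collapse = ", ") else "(none)"))
  }
  fifo(path, open = if (mode == "read") "r" else "w", blocking = TRUE)
}

#' Bridge two exposed FIFOs at runtime (runtime piping)
#'
#' Starts a relay copying records from the producer-side pipe of one
#' program to the consumer-side pipe of another until end-of-stream,
#' which is then propagated. This connects two independently launched
#' programs without rebuilding either.
#'
#' @param root_a Output directory of the producing program.
#' @param fifo_out Producer-side FIFO basename (e.g. \code{"counter_out"}).
#' @param root_b Output directory of the consuming program.
#' @param fifo_in Consumer-side FIFO basename (e.g. \code{"stream_echo_in"}).
#' @return A bridge handle; stop it early with \code{\link{stop_bridge}}.
#' @export
bridge <- function(root_a, fifo_out, root_b, fifo_in) {
  src <- fifo_path(root_a, fifo_out)
  dst <- fifo_path(root_b, fifo_in)
  for (p in c(src, dst)) {
    if (!file.exists(p)) {
      fbp_error("fbp_unknown_fifo", sprintf("no such FIFO: %s", p))
    }
  }
  script <- tempfile("fbpr_bridge_", fileext = ".sh")
  writeLines(sprintf("cat %s > %s", shquote(src), shquote(dst)), script)
  pid <- spawn_script(script)
  structure(list(pid = pid, src = src, dst = dst, script = script),
            class = "fbp_bridge")
}

#' @rdname bridge
#' @param handle A bridge handle.
#' @export
stop_bridge <- function(handle) {
  stopifnot(inherits(handle, "fbp_bridge"))
  kill_group(handle$pid, "TERM")
  invisible(NULL)
}

#' @rdname bridge
#' @param timeout Seconds to wait.
#' @export
wait_bridge <- function(handle, timeout = 30) {
  stopifnot(inherits(handle, "fbp_bridge"))
  wait_until(function() !pid_alive(handle$pid), timeout)
}
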