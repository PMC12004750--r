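# Internal helpers shared across the package.

fbp_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fbp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

fbp_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "fbp_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Valid process / module identifier: gets embedded in file and FIFO names.
is_identifier <- function(x) {
  is_string(x) && grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
}

shquote <- function(x) {
  # POSIX single-quote escaping; robust for arbitrary argument strings.
  paste0("'", gsub("'", "'\\\\''", x), "'")
}

# Spawn a detached shell running `script_path` with arguments, in its own
# session (process group) so a whole process tree can be signalled at once.
# Returns the PID of the spawned leader.
spawn_script <- function(script_path, args = character()) {
  argstr <- if (length(args)) paste(vapply(args, shquote, ""), collapse = " ") else ""
  cmd <- sprintf("setsid sh %s %s </dev/null >/dev/null 2>&1 & echo $!",
                 shquote(script_path), argstr)
  pid <- suppressWarnings(system(cmd, intern = TRUE))
  as.integer(pid[1])
}

pid_alive <- function(pid) {
  if (is.na(pid)) return(FALSE)
  system2("kill", c("-0", as.character(pid)), stdout = FALSE, stderr = FALSE) == 0L
}

# Signal the process group led by `pid` (falls back to the single PID).
kill_group <- function(pid, signal = "TERM") {
  if (is.na(pid)) return(invisible(FALSE))
  ok <- system2("kill", c(paste0("-", signal), paste0("-", pid)),
                stdout = FALSE, stderr = FALSE) == 0L
  if (!ok) {
    ok <- system2("kill", c(paste0("-", signal), as.character(pid)),
                  stdout = FALSE, stderr = FALSE) == 0L
  }
  invisible(ok)
}

wait_until <- function(predicate, timeout, interval = 0.02) {
  deadline <- Sys.time() + timeout
  while (Sys.time() < deadline) {
    if (isTRUE(predicate())) return(TRUE)
    Sys.sleep(interval)
  }
  isTRUE(predicate())
}

read_lines_if_exists <- function(path) {
  if (file.exists(path)) readLines(path, warn = FALSE) else character()
}

mkdirp <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE, showWarnings = FALSE)
  invisible(path)
}
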