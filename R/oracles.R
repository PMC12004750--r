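# Pure reference semantics of the bundled example programs. These
# functions are sequential, single-threaded specifications; the test
# suite uses them as ground truth for the concurrent engine runs.

#' Greedy line reflow (the Telegram computation)
#'
#' Packs words into lines of at most \code{limit} characters: words are
#' joined by single spaces; a word is appended to the current line iff
#' the resulting length stays within the limit, else a new line starts.
#' Every output line is non-empty and maximal (the first word of the
#' next line would not have fit).
#'
#' @param words Character vector of words (no internal whitespace).
#' @param limit Maximum line length in characters; no word may exceed it.
#' @return Character vector of packed lines.
#' @examples
#' telegram_reflow(c("the", "quick", "brown", "fox", "jumps"), 10)
#' @export
telegram_reflow <- function(words, limit) {
  words <- as.character(words)
  if (!length(words)) return(character())
  if (any(nchar(words) > limit)) {
    fbp_error("fbp_word_too_long",
              sprintf("word longer than the line limit %d: %s", limit,
                      words[which(nchar(words) > limit)[1]]))
  }
  lines <- character()
  line <- ""
  len <- 0L
  for (w in words) {
    if (len == 0L) {
      line <- w; len <- nchar(w)
    } else if (len + 1L + nchar(w) <= limit) {
      line <- paste(line, w); len <- len + 1L + nchar(w)
    } else {
      lines <- c(lines, line)
      line <- w; len <- nchar(w)
    }
  }
  c(lines, line)
}

#' Split lines into a word stream
#'
#' Whitespace-delimited tokenisation with order preserved; runs of
#' whitespace collapse and empty tokens are dropped.
#'
#' @param lines Character vector of text lines.
#' @return Character vector of words.
#' @export
decompose_lines <- function(lines) {
  words <- unlist(strsplit(lines, "[ \t]+"))
  words[nzchar(words)] %||% character()
}

#' Sequential oracle for the cyclic master-worker program
#'
#' Simulates the message cycle: the master sends a value; the worker adds
#' 1 when its cumulative total (before this cycle's update) is at most
#' the threshold, else 2, accumulates the transformed value, and returns
#' it; the master stops once the returned value exceeds \code{n_stop}.
#'
#' @param v0 Initial value sent by the master.
#' @param threshold Worker threshold; a vector is read one element per
#'   cycle (last element recycled), modelling interactive threshold
#'   updates.
#' @param n_stop The master stops when it receives a value greater than
#'   this.
#' @return List with \code{final_value} (last value the master
#'   received), \code{worker_cum} (the worker's printed cumulative
#'   total) and \code{n_cycles}.
#' @examples
#' master_worker_oracle(0, -1, 0)  # final_value 2, worker_cum 2, 1 cycle
#' @export
master_worker_oracle <- function(v0, threshold, n_stop) {
  cum <- 0
  v <- v0
  cycles <- 0L
  repeat {
    t <- threshold[min(cycles + 1L, length(threshold))]
    inc <- if (cum <= t) 1 else 2
    out <- v + inc
    cum <- cum + out
    cycles <- cycles + 1L
    if (out > n_stop) {
      return(list(final_value = out, worker_cum = cum, n_cycles = cycles))
    }
    v <- out
  }
}

#' Reference output of the counter process
#'
#' @param n Upper bound; the count runs from 0 to \code{n} inclusive.
#' @return Character vector \code{"0" ... "n"}, one record per element.
#' @export
counter_stream <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    fbp_error("fbp_bad_input", "counter bound must be >= 0")
  }
  as.character(0:floor(n))
}
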