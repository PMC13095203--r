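# Classed error conditions so callers can distinguish failure modes with
# tryCatch(..., clearseq_duplicate_identifier = ...) rather than matching
# on message text.

cs_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(paste0("clearseq_", class), "clearseq_error")))
}

cs_assert <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) cs_stop(class, fmt, ...)
  invisible(TRUE)
}

# Run code with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
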