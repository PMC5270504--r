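# internal helpers

# evaluate `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop_invalid(sprintf("'%s' must be numeric and non-missing", name))
  lo_ok <- if (open_lo) all(x > 0) else all(x >= 0)
  hi_ok <- if (open_hi) all(x < 1) else all(x <= 1)
  if (!lo_ok || !hi_ok)
    stop_invalid(sprintf("'%s' must lie in %s0, 1%s", name,
                         if (open_lo) "(" else "[", if (open_hi) ")" else "]"))
  invisible(x)
}
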