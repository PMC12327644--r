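# input validation helpers and seed plumbing shared across modules

assert_scalar_in <- function(x, lo, hi, name, open = c(TRUE, TRUE)) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open[1]) x > lo else x >= lo) && (if (open[2]) x < hi else x <= hi)
  if (!ok) {
    bounds <- paste0(if (open[1]) "(" else "[", lo, ", ", hi, if (open[2]) ")" else "]")
    abort(sprintf("`%s` must be a single number in %s, got %s", name, bounds,
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)))
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

#' Derive named reproducible sub-seeds from one master seed
#'
#' All randomness in a pipeline run flows from one master seed through named
#' substreams, so that any stage can be re-run in isolation.
#'
#' @param seed master seed (single integer) or `NULL` to leave the RNG alone.
#' @param names character vector of substream names.
#' @return named integer vector of seeds (or `NULL` if `seed` is `NULL`).
#' @export
seed_streams <- function(seed, names) {
  if (is.null(seed)) return(NULL)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
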