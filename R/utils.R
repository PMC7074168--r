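#' @importFrom methods as is
#' @importFrom stats rnorm runif rbinom var sd cor model.matrix optimize
#' @importFrom utils read.table write.table head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib wintergwas, .registration = TRUE
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_fraction <- function(x, lo = 0, hi = 1, open_lo = TRUE, open_hi = TRUE) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x))) return(FALSE)
  lo_ok <- if (open_lo) x > lo else x >= lo
  hi_ok <- if (open_hi) x < hi else x <= hi
  lo_ok && hi_ok
}

# deterministic RNG scoping: run `expr` under `seed` without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
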