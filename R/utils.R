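#' @useDynLib methven, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cor.test pnorm pt quantile rbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table head combn
NULL

# Run code with a private RNG state: the caller's .Random.seed is untouched
# and `seed` fully determines the result.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

msg <- function(...) message("[methven] ", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
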