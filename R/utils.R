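#' @useDynLib sleepstager, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif rpois sd
#' @importFrom utils read.csv write.csv
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals never
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package fans out from one configured seed through
#' named substreams, so that e.g. splitting and weight initialization are
#' independently reproducible.
#'
#' @param seed master integer seed.
#' @param name substream name.
#' @param index optional integer index (e.g. epoch number) folded in.
#' @return an integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  val <- (as.double(seed) %% 2147483647) * 48271 + h * 69621 +
    (as.double(index) %% 2147483647) * 16807
  as.integer(val %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

msg <- function(...) message("[sleepstager] ", sprintf(...))
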