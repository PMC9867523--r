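#' @useDynLib smartchair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois sd median mad kmeans cov dist quantile
#' @importFrom utils read.csv write.csv head tail
NULL

# INFO-level logging for pipeline stages; silent unless
# options(smartchair.verbose = TRUE).
sc_log <- function(...) {
  if (isTRUE(getOption("smartchair.verbose", FALSE))) {
    message("[smartchair] ", sprintf(...))
  }
  invisible(NULL)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_sc <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
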